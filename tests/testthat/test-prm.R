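test_that("tryptic digestion honors K/R cleavage, the KP rule and missed cleavages", {
  d0 <- digest_tryptic("MKAAGR", max_missed = 0)
  expect_equal(d0$peptide, c("MK", "AAGR"))
  # no cleavage before proline
  expect_equal(digest_tryptic("AKPR", max_missed = 0)$peptide, "AKPR")
  # 0-, 1- and 2-missed forms all emitted
  d2 <- digest_tryptic("AAKBBKCCKDD", max_missed = 2)
  expect_true(all(c("AAK", "AAKBBK", "AAKBBKCCK", "BBKCCKDD") %in%
                    d2$peptide))
  expect_equal(sort(unique(d2$missed_cleavages)), 0:2)
})

test_that("0-missed peptides re-concatenate to the protein sequence", {
  set.seed(17)
  for (rep in 1:20) {
    s <- paste(sample(c("A", "G", "K", "R", "P", "L", "S", "T"),
                      sample(20:60, 1), replace = TRUE), collapse = "")
    d <- digest_tryptic(s, max_missed = 0)
    expect_equal(paste(d$peptide, collapse = ""), s)
  }
})

test_that("monoisotopic masses follow the residue table and label additivity", {
  expect_equal(mono_mass("G"), 57.02146 + 18.010565)
  lab <- label_scheme()
  pep <- "INQLISETEAVVTNELEDGDR"
  expect_equal(mono_mass(pep, label = lab, heavy = TRUE) - mono_mass(pep),
               10.00827)
  # modification deltas are strictly additive
  ox <- data.frame(position = 1L, name = "Oxidation", delta = 15.994)
  expect_equal(mono_mass("MAAAK", ox) - mono_mass("MAAAK"), 15.994)
  expect_error(mono_mass("AXZ"), "unknown residue")
})

test_that("fragment m/z follows the b/y conventions and label locality", {
  # y1 of any peptide ending in R
  expect_equal(fragment_mz("AAGR", "y", 1), 156.10111 + 18.010565 + 1.007276,
               tolerance = 1e-9)
  lab <- label_scheme()
  expect_equal(fragment_mz("AAGR", "y", 1, label = lab, heavy = TRUE) -
                 fragment_mz("AAGR", "y", 1), 10.00827)
  # b-ions never span the labeled C-terminal residue
  expect_equal(fragment_mz("AAGR", "b", 3, label = lab, heavy = TRUE),
               fragment_mz("AAGR", "b", 3))
  expect_error(fragment_mz("AAGR", "y", 4), "ordinal")
})

test_that("b/y fragment masses are complementary to the precursor", {
  set.seed(23)
  for (rep in 1:20) {
    pep <- paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                        sample(6:15, 1), replace = TRUE), collapse = "")
    n <- nchar(pep)
    k <- sample(seq_len(n - 1), 1)
    bk <- fragment_mz(pep, "b", k)
    ynk <- fragment_mz(pep, "y", n - k)
    expect_equal(bk + ynk, mono_mass(pep) + 2 * 1.007276, tolerance = 1e-4)
  }
})

test_that("XIC extraction respects the ppm window and trapezoid integral", {
  sc <- function(t, mz, i) list(title = "", scan_time = t, precursor_mz = 500,
                                mz = mz, intensity = i)
  # boundary inside: 2 ppm off at 3 ppm tolerance
  spectra <- list(sc(1, 500.0000, 10), sc(2, 500.0000, 10))
  expect_equal(extract_xic(spectra, 500.0010, ppm = 3)$area, 10)
  # boundary outside: 20 ppm off
  expect_equal(extract_xic(spectra, 500.0100, ppm = 3)$area, 0)
  # two identical scans dt apart integrate to I * dt
  spectra <- list(sc(5, 400, 7), sc(8, 400, 7))
  expect_equal(extract_xic(spectra, 400, ppm = 3)$area, 7 * 3)
  # retention-time window restricts the trace
  spectra <- list(sc(1, 400, 5), sc(2, 400, 5), sc(50, 400, 100))
  expect_equal(extract_xic(spectra, 400, 3, rt_window = c(0, 10))$area, 5)
  # empty spectra give an empty trace
  expect_equal(extract_xic(list(), 400, 3)$area, 0)
})

test_that("XIC extraction equals the per-scan linear-search oracle", {
  cfg <- simulation_config(seed = 31)
  spectra <- generate_prm_run(cfg, "AAGLLGNVTR", "KRAS")
  tr <- predict_transitions("AAGLLGNVTR")
  for (mz in c(tr$mz_light[2:4], tr$mz_heavy[2:4])) {
    expect_equal(extract_xic(spectra, mz, 3)$area,
                 oracle_xic_area(spectra, mz, 3))
  }
})

test_that("PRM ratio recovers proportional constructions and fails without standard", {
  pep <- "AAGLLGNVTR"
  tr <- predict_transitions(pep)
  times <- seq(0, 10, by = 1)
  mk_run <- function(ratio, scale = 1) lapply(times, function(t) {
    g <- exp(-(t - 5)^2 / 4)
    list(title = "", scan_time = t, precursor_mz = 500,
         mz = c(tr$mz_heavy, tr$mz_light),
         intensity = scale * c(rep(100 * g, nrow(tr)),
                               rep(100 * ratio * g, nrow(tr))))
  })
  r <- prm_ratio(mk_run(0.5), pep)
  expect_equal(r$ratio, 0.5, tolerance = 1e-12)
  expect_equal(sum(r$transitions$used), 5L)
  # light channel absent: ratio 0
  expect_equal(prm_ratio(mk_run(0), pep)$ratio, 0)
  # uniform intensity rescaling cancels in the normalized ratio
  expect_equal(prm_ratio(mk_run(0.5, scale = 37), pep)$ratio, 0.5,
               tolerance = 1e-12)
  # heavy internal standard missing is an error
  empty <- lapply(times, function(t)
    list(title = "", scan_time = t, precursor_mz = 500,
         mz = numeric(), intensity = numeric()))
  expect_error(prm_ratio(empty, pep), "heavy internal standard")
})
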