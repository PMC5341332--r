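test_that("sequon check implements NxS/T with optional proline exclusion", {
  expect_true(check_sequon("AANGTAA", 3))
  expect_true(check_sequon("AANGSAA", 3))
  expect_false(check_sequon("AANGGAA", 3))
  # proline at x allowed by default, excluded by flag
  expect_true(check_sequon("AANPSAA", 3))
  expect_false(check_sequon("AANPSAA", 3, exclude_proline = TRUE))
  # N as last or penultimate residue can never be a sequon
  expect_false(check_sequon("AAN", 3))
  expect_false(check_sequon("AANS", 3))
  # contract violations
  expect_error(check_sequon("AAA", 2), "not 'N'")
  expect_error(check_sequon("AAN", 9), "out of range")
})

test_that("deamidation sites map onto protein coordinates with sequon status", {
  db <- data.frame(accession = c("P1", "P2"), gene_symbol = NA,
                   sequence = c("MKLNGSR", "MKLNGGR"), is_decoy = FALSE,
                   stringsAsFactors = FALSE)
  psm <- make_psms("LNGSR", "P1", modifications = "2:Deamidated:0.984")
  ev <- map_deamidation_sites(psm, db)
  expect_equal(ev$protein_position, 4L)
  expect_equal(ev$motif_window, "NGS")
  expect_true(ev$sequon_valid)

  psm2 <- make_psms("LNGGR", "P2", modifications = "2:Deamidated:0.984")
  ev2 <- map_deamidation_sites(psm2, db)
  expect_false(ev2$sequon_valid)

  # delta outside the matching tolerance emits nothing
  psm3 <- make_psms("LNGSR", "P1", modifications = "2:Deamidated:0.5")
  expect_equal(nrow(map_deamidation_sites(psm3, db)), 0L)
  # deamidation on a non-N residue emits nothing
  psm4 <- make_psms("LNGSR", "P1", modifications = "1:Deamidated:0.984")
  expect_equal(nrow(map_deamidation_sites(psm4, db)), 0L)
  # claimed protein without the peptide is a mapping error
  psm5 <- make_psms("ANGTK", "P1", modifications = "2:Deamidated:0.984")
  expect_error(map_deamidation_sites(psm5, db), "P1")
})

test_that("parsimony grouping covers shared peptides with minimal leads", {
  # p2 shared: B's evidence is subsumed by A
  psms <- make_psms(c("PEPA", "PEPB"), c("A", "A;B"))
  g <- group_proteins(psms)
  expect_equal(nrow(g), 1L)
  expect_equal(g$lead_accession, "A")
  expect_equal(g$members, "B")
  expect_equal(g$n_psms, 2L)

  # disjoint evidence keeps two groups
  g2 <- group_proteins(make_psms(c("PEPA", "PEPB"), c("A", "B")))
  expect_equal(sort(g2$lead_accession), c("A", "B"))

  # ties broken lexicographically by accession
  g3 <- group_proteins(make_psms("PEPA", "B;A"))
  expect_equal(g3$lead_accession, "A")
  expect_equal(g3$members, "B")

  expect_equal(nrow(group_proteins(make_psms(character(), character()))), 0L)
})

test_that("greedy grouping attains the brute-force minimal cover on small instances", {
  set.seed(11)
  for (rep in 1:25) {
    n_acc <- sample(2:5, 1)
    n_pep <- sample(2:6, 1)
    accs <- LETTERS[seq_len(n_acc)]
    pep_accs <- lapply(seq_len(n_pep), function(i)
      sort(sample(accs, sample(seq_len(n_acc), 1))))
    names(pep_accs) <- paste0("PEP", seq_len(n_pep))
    psms <- make_psms(names(pep_accs),
                      vapply(pep_accs, paste, "", collapse = ";"))
    g <- group_proteins(psms)
    # greedy set cover is within the ln(n)+1 guarantee of the optimum, and
    # on these tiny instances it should be optimal or off by at most one
    expect_lte(nrow(g), oracle_min_cover_size(pep_accs) + 1L)
    # every PSM assigned exactly once
    expect_equal(sum(g$n_psms), nrow(psms))
  }
})

test_that("adding a peptide-to-protein edge never increases the group count", {
  set.seed(13)
  for (rep in 1:20) {
    n_acc <- sample(3:6, 1)
    accs <- LETTERS[seq_len(n_acc)]
    n_pep <- sample(3:8, 1)
    pep_accs <- lapply(seq_len(n_pep), function(i)
      sort(sample(accs, sample(seq_len(n_acc - 1), 1))))
    peptides <- paste0("PEP", seq_len(n_pep))
    base <- make_psms(peptides, vapply(pep_accs, paste, "", collapse = ";"))
    n0 <- nrow(group_proteins(base))
    # add one random missing edge
    i <- sample(n_pep, 1)
    missing <- setdiff(accs, pep_accs[[i]])
    if (length(missing) == 0) next
    pep_accs[[i]] <- sort(c(pep_accs[[i]], sample(missing, 1)))
    more <- make_psms(peptides, vapply(pep_accs, paste, "", collapse = ";"))
    expect_lte(nrow(group_proteins(more)), n0)
  }
})

test_that("CSC arm enforces FDR, sequon and minimum-PSM gates in order", {
  db <- data.frame(
    accession = c("P1", "P2", "P3", "DECOY_P1"), gene_symbol = NA,
    sequence = c("MKLNGSR", "MKLNGGR", "AAKNVTR", "RSGNLKM"),
    is_decoy = c(FALSE, FALSE, FALSE, TRUE), stringsAsFactors = FALSE)
  psms <- rbind(
    make_psms("LNGSR", "P1", modifications = "2:Deamidated:0.984",
              q_value = 0.001),
    make_psms("LNGSR", "P1", modifications = "2:Deamidated:0.984",
              q_value = 0.001),
    # valid score, deamidation outside a sequon: dropped by the sequon gate
    make_psms("LNGGR", "P2", modifications = "2:Deamidated:0.984",
              q_value = 0.001),
    # single-PSM protein: dropped by the min-PSM gate
    make_psms("NVTR", "P3", modifications = "1:Deamidated:0.984",
              q_value = 0.001),
    # fails the FDR gate
    make_psms("LNGSR", "P1", modifications = "2:Deamidated:0.984",
              q_value = 0.5),
    # decoys never surface
    make_psms("SGNLK", "DECOY_P1", q_value = 0.001, is_decoy = TRUE))
  out <- csc_glycoproteome(psms, db)
  expect_named(out, "KRAS")
  expect_equal(out$KRAS$lead_accession, "P1")
  expect_equal(out$KRAS$n_psms, 2L)
  expect_equal(out$KRAS$glycosites, "P1:N4")
  stages <- attr(out, "stages")
  expect_equal(stages$input, 6L)
  expect_equal(stages$fdr_pass, 4L)
  expect_equal(stages$sequon_pass, 3L)
})

test_that("reported glycosites re-check against the database", {
  cfg <- simulation_config(seed = 5, n_proteins = 60, n_true_up = 5,
                           n_true_unique = 5)
  sim <- generate_proteome(cfg)
  tabs <- generate_psm_tables(cfg, sim)
  out <- csc_glycoproteome(tabs$csc, sim$proteins)
  db <- sim$proteins
  for (cond in names(out)) {
    sites <- unlist(strsplit(out[[cond]]$glycosites, ";"))
    sites <- sites[nzchar(sites)]
    expect_gt(length(sites), 0)
    for (s in sites) {
      acc <- sub(":N[0-9]+$", "", s)
      pos <- as.integer(sub("^.*:N", "", s))
      seqc <- db$sequence[db$accession == acc]
      expect_equal(substr(seqc, pos, pos), "N")
      expect_true(check_sequon(seqc, pos))
    }
  }
})
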