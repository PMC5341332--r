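test_that("overlap percentages reproduce at printed precision", {
  expect_equal(percent_overlap(145, 148), 98)
  expect_equal(percent_overlap(118, 122), 97)
  expect_equal(percent_overlap(1338, 4869, 1), 27.5)
  expect_equal(percent_overlap(0, 50), 0)
  expect_error(percent_overlap(1, 0), ">= 1")
  # half-up, not banker's rounding
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(30.25, 1), 30.3)
})

test_that("overlap and its complement add to 100 up to one ulp of rounding", {
  set.seed(8)
  for (rep in 1:50) {
    n <- sample(10:5000, 1)
    a <- sample(0:n, 1)
    s <- percent_overlap(a, n, 1) + percent_overlap(n - a, n, 1)
    expect_lte(abs(s - 100), 0.1)
  }
})

test_that("fold enrichment and its reported integer fold behave", {
  expect_equal(fold_enrichment(0.303, 0.02), 15.15)
  expect_equal(fold_label(fold_enrichment(0.303, 0.02)), 15L)
  expect_equal(fold_enrichment(0.0997, 0.02), 4.985)
  expect_equal(fold_label(fold_enrichment(0.0997, 0.02)), 5L)
  expect_equal(fold_enrichment(0.3, 0.3), 1)
  expect_error(fold_enrichment(0.5, 0), "> 0")
})

test_that("pathway coverage counts hits and rounds to integer percent", {
  pw <- annotation_set("RAS2", sprintf("P%03d", 1:227))
  cov <- pathway_coverage(sprintf("P%03d", 1:158), pw)
  expect_equal(cov$n_hit, 158L)
  expect_equal(cov$percent, 70)
  expect_equal(pathway_coverage("X1", pw), list(n_hit = 0L, percent = 0))
  full <- pathway_coverage(c(pw$accessions, "EXTRA"), pw)
  expect_equal(full, list(n_hit = 227L, percent = 100))
})

make_diff_row <- function(accession, class, count_kras, count_ev, q) {
  data.frame(accession = accession, count_kras = count_kras,
             count_ev = count_ev, p_value = q, q_value = q,
             log2_fold = log2((count_kras + 0.5) / (count_ev + 0.5)),
             class = class, stringsAsFactors = FALSE)
}

test_that("non-redundant merge applies provenance and the demotion rule", {
  # CSC-unique, absent from SGM: passes through with CSC provenance
  csc <- make_diff_row("A", "UNIQUE_KRAS", 6, 0, 0.001)
  m <- merge_nonredundant(csc, NULL)
  expect_equal(m$class, "UNIQUE_KRAS")
  expect_equal(m$platforms, "CSC")

  # CSC-unique but detected in EV on SGM where it is significant: demoted
  sgm <- make_diff_row("A", "UP_KRAS", 20, 4, 0.001)
  m2 <- merge_nonredundant(csc, sgm)
  expect_equal(m2$class, "UP_KRAS")
  expect_equal(m2$platforms, "CSC;SGM")

  # strongly supported CSC-unique conflicting with shared SGM evidence is
  # demoted, not dropped: its own binomial call is significant
  sgm_ns <- make_diff_row("A", "SHARED", 8, 7, 0.9)
  expect_equal(merge_nonredundant(csc, sgm_ns)$class, "UP_KRAS")
  # a weakly supported unique call (non-significant q) conflicting with
  # shared evidence is dropped
  csc_weak <- make_diff_row("A", "UNIQUE_KRAS", 3, 0, 0.3)
  expect_equal(nrow(merge_nonredundant(csc_weak, sgm_ns)), 0L)

  # upregulated on both platforms: a single deduplicated entry
  m3 <- merge_nonredundant(make_diff_row("B", "UP_KRAS", 20, 4, 0.01),
                           make_diff_row("B", "UP_KRAS", 30, 6, 0.01))
  expect_equal(nrow(m3), 1L)
  expect_equal(m3$platforms, "CSC;SGM")

  # isoforms collapse to the canonical accession
  m4 <- merge_nonredundant(make_diff_row("P100-2", "UP_KRAS", 20, 4, 0.01),
                           make_diff_row("P100", "UP_KRAS", 25, 5, 0.01))
  expect_equal(m4$accession, "P100")
  expect_equal(nrow(m4), 1L)
})

test_that("merge matches rule-based enumeration of all cross-platform cases", {
  # independent restatement of the contract, evaluated per accession:
  # keep iff classed UNIQUE_KRAS/UP_KRAS somewhere; UNIQUE only if EV count
  # is 0 everywhere measured; else UP if significant anywhere; else drop
  oracle_class <- function(rows, alpha = 0.05) {
    if (!any(rows$class %in% c("UNIQUE_KRAS", "UP_KRAS"))) return(NA)
    if (any(rows$class == "UNIQUE_KRAS") && all(rows$count_ev == 0))
      return("UNIQUE_KRAS")
    if (any(rows$class == "UP_KRAS" |
              (rows$q_value <= alpha & rows$log2_fold > 0)))
      return("UP_KRAS")
    NA
  }
  cases <- list(
    UNIQUE_KRAS = list(class = "UNIQUE_KRAS", a = 6, b = 0, q = 0.2),
    UP_KRAS = list(class = "UP_KRAS", a = 20, b = 4, q = 0.001),
    SHARED = list(class = "SHARED", a = 8, b = 7, q = 0.9),
    ABSENT = NULL)
  for (cs in names(cases)) {
    for (sg in names(cases)) {
      if (cs == "ABSENT" && sg == "ABSENT") next
      mk <- function(x) if (is.null(cases[[x]])) NULL else
        make_diff_row("ACC", cases[[x]]$class, cases[[x]]$a, cases[[x]]$b,
                      cases[[x]]$q)
      got <- merge_nonredundant(mk(cs), mk(sg))
      rows <- rbind(mk(cs), mk(sg))
      want <- oracle_class(rows)
      if (is.na(want)) {
        expect_equal(nrow(got), 0L, info = paste(cs, sg))
      } else {
        expect_equal(got$class, want, info = paste(cs, sg))
      }
    }
  }
})

test_that("annotation flags and per-class CSPA fractions are computed", {
  csc <- rbind(make_diff_row(sprintf("U%02d", 1:5), "UNIQUE_KRAS", 6, 0, 0.01),
               make_diff_row(sprintf("P%02d", 1:4), "UP_KRAS", 20, 4, 0.01))
  ann <- list(cspa = annotation_set("CSPA", c("U01", "U02", "P01")),
              cd = annotation_set("CD", "U01", baseline_fraction = 0.02),
              pathway = annotation_set("RAS2", c("P01", "P02")))
  map <- merge_nonredundant(csc, NULL, annotations = ann)
  expect_equal(sum(map$in_cspa), 3L)
  expect_equal(sum(map$is_cd), 1L)
  expect_equal(sum(map$in_pathway), 2L)
  fr <- glyco_fraction_of_map(map)
  expect_equal(fr$UNIQUE_KRAS$n_total, 5L)
  expect_equal(fr$UNIQUE_KRAS$percent, 40)
  expect_equal(fr$UP_KRAS$percent, 25)
  # the printed 45.6% regenerates from its stored counts
  expect_equal(enrichment_report(89, 195)$percent, 45.6)
})
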