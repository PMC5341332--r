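# Independent oracles and tiny fixture builders used across the suite.

# Brute-force target-decoy q-values: enumerate every score threshold,
# compute FDR(t) = #decoys>=t / max(1, #targets>=t), and take for each PSM
# the minimum FDR over thresholds at or below its score.
oracle_qvalues <- function(score, is_decoy) {
  thr <- unique(score)
  fdr_at <- vapply(thr, function(t)
    sum(is_decoy & score >= t) / max(1, sum(!is_decoy & score >= t)), 0)
  vapply(score, function(s) min(fdr_at[thr <= s]), 0)
}

# Exhaustive minimum-likelihood two-sided exact binomial p-value.
oracle_binomial <- function(a, b, Na, Nb) {
  n <- a + b
  if (n == 0) return(1)
  p0 <- Na / (Na + Nb)
  pk <- dbinom(0:n, n, p0)
  min(1, sum(pk[pk <= pk[a + 1] * (1 + 1e-7)]))
}

# Hand-applied BH step-up.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- pmin(1, p[o] * m / seq_len(m))
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Per-scan linear-search XIC oracle.
oracle_xic_area <- function(spectra, target, ppm) {
  tol <- target * ppm * 1e-6
  t <- vapply(spectra, `[[`, 0, "scan_time")
  y <- vapply(spectra, function(sc) {
    s <- 0
    for (j in seq_along(sc$mz))
      if (abs(sc$mz[j] - target) <= tol) s <- s + sc$intensity[j]
    s
  }, 0)
  if (length(t) < 2) return(0)
  sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)
}

# Minimal PSM frame builder.
make_psms <- function(peptide, proteins, condition = "KRAS",
                      modifications = "", score = 10, q_value = 0,
                      is_decoy = FALSE, replicate = "r1", charge = 2L) {
  n <- length(peptide)
  data.frame(peptide = peptide, modifications = rep_len(modifications, n),
             proteins = proteins, score = rep_len(score, n),
             charge = rep_len(charge, n), condition = rep_len(condition, n),
             replicate = rep_len(replicate, n),
             q_value = rep_len(q_value, n),
             is_decoy = rep_len(is_decoy, n), stringsAsFactors = FALSE)
}

# Brute-force minimal set cover over a peptide -> accessions instance,
# by exhaustive subset enumeration (instances are tiny).
oracle_min_cover_size <- function(pep_accs) {
  accs <- sort(unique(unlist(pep_accs)))
  peps <- names(pep_accs)
  for (k in seq_along(accs)) {
    subsets <- combn(accs, k, simplify = FALSE)
    for (s in subsets) {
      covered <- vapply(peps, function(p) any(pep_accs[[p]] %in% s),
                        logical(1))
      if (all(covered)) return(k)
    }
  }
  length(accs)
}
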