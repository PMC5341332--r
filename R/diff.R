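#' Differential-test parameters
#'
#' @param alpha_fdr BH FDR threshold for calling a protein significantly
#'   up- or down-regulated (default 0.05).
#' @param pseudocount Pseudocount added to both counts for the log2 fold
#'   estimate only; it never enters the test (default 0.5).
#' @param min_psm_unique Minimum PSMs in the detecting condition for a
#'   protein absent from the other condition to be called condition-unique
#'   (default 2, mirroring the single-PSM exclusion).
#' @return A list of class `diff_params`.
#' @export
diff_params <- function(alpha_fdr = 0.05, pseudocount = 0.5,
                        min_psm_unique = 2L) {
  stopifnot(alpha_fdr > 0, alpha_fdr < 1, pseudocount > 0,
            min_psm_unique >= 1)
  structure(list(alpha_fdr = alpha_fdr, pseudocount = pseudocount,
                 min_psm_unique = as.integer(min_psm_unique)),
            class = "diff_params")
}

#' Build a per-protein spectral-count table
#'
#' Takes the grouped identifications (or any per-accession count frame) of the
#' two conditions and assembles the union of accessions, with zero counts for
#' accessions absent from one condition. Library sizes (total retained PSMs
#' per condition) are recorded as attributes and used as the null weights of
#' the binomial test.
#'
#' @param kras,ev data.frames with an accession column (`lead_accession` or
#'   `accession`) and `n_psms`, e.g. one element of [csc_glycoproteome()]
#'   output.
#' @return A data.frame of class `count_table` with columns `accession`,
#'   `count_kras`, `count_ev`, and attributes `library_kras`, `library_ev`.
#' @export
build_count_table <- function(kras, ev) {
  get <- function(df, who) {
    acc_col <- intersect(c("lead_accession", "accession"), names(df))[1]
    if (is.na(acc_col) || !"n_psms" %in% names(df))
      stop("count input for ", who,
           " needs an accession column and n_psms", call. = FALSE)
    acc <- df[[acc_col]]
    if (anyDuplicated(acc))
      stop("duplicate accession rows in ", who,
           " counts: protein grouping must precede counting", call. = FALSE)
    stats::setNames(as.integer(df$n_psms), acc)
  }
  a <- get(kras, "KRAS")
  b <- get(ev, "EV")
  if (sum(a) == 0L || sum(b) == 0L)
    stop("a condition has zero total PSMs", call. = FALSE)
  accs <- sort(union(names(a), names(b)))
  out <- data.frame(
    accession = accs,
    count_kras = ifelse(is.na(a[accs]), 0L, a[accs]),
    count_ev = ifelse(is.na(b[accs]), 0L, b[accs]),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, library_kras = sum(a), library_ev = sum(b),
            class = c("count_table", "data.frame"))
}

#' Exact binomial spectral-count test
#'
#' Under the null of no differential abundance, the `a` PSMs observed in KRas
#' out of `n = a + b` total for a protein are Binomial(n, p0) with
#' `p0 = Na / (Na + Nb)` given library sizes `Na`, `Nb`. The two-sided p-value
#' is the minimum-likelihood rule: the sum of all outcome probabilities not
#' exceeding that of the observed count. `a + b = 0` is defined as p = 1 (no
#' evidence).
#'
#' @param a,b Per-protein PSM counts in KRas and EV (vectorized).
#' @param Na,Nb Library sizes (total retained PSMs) per condition.
#' @return Vector of p-values in (0, 1].
#' @examples
#' binomial_test(12, 2, 1000, 1000)
#' @export
binomial_test <- function(a, b, Na, Nb) {
  stopifnot(Na > 0, Nb > 0, all(a >= 0), all(b >= 0))
  p0 <- Na / (Na + Nb)
  n <- a + b
  mapply(function(ai, ni) {
    if (ni == 0L) return(1)
    stats::binom.test(ai, ni, p = p0)$p.value
  }, a, n)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH adjustment: `q_i = min_{j: p_j >= p_i} m * p_j / rank_j`,
#' capped at 1, order-preserving with the input.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "BH")
}

#' Spectral-counting differential surface analysis
#'
#' The central comparative step: fits the exact binomial spectral-count model
#' to a two-condition count table and classifies every protein as
#' condition-unique (subtractive proteomics: detected with at least
#' `min_psm_unique` PSMs in one condition and zero in the other),
#' significantly up-regulated in either direction (BH q below `alpha_fdr`
#' among proteins detected in both conditions, direction by fold sign), or
#' shared. The log2 fold estimate is library-size-normalized and
#' pseudocount-stabilized:
#' `log2((a + c)/Na) - log2((b + c)/Nb)`.
#'
#' @param table A [build_count_table()] result (or any data.frame with
#'   `accession`, `count_kras`, `count_ev` plus `library_*` attributes or
#'   explicit `library_kras` / `library_ev` arguments).
#' @param params [diff_params()].
#' @param library_kras,library_ev Optional explicit library sizes; default to
#'   the table attributes.
#' @return An object of class `surface_diff` (a data.frame with columns
#'   `accession`, `count_kras`, `count_ev`, `p_value`, `q_value`,
#'   `log2_fold`, `class`) with the parameters and library sizes attached.
#' @examples
#' kras <- data.frame(accession = c("A", "B"), n_psms = c(20L, 5L))
#' ev <- data.frame(accession = c("B", "C"), n_psms = c(5L, 4L))
#' fit <- surface_diff(build_count_table(kras, ev))
#' summary(fit)
#' @export
surface_diff <- function(table, params = diff_params(),
                         library_kras = attr(table, "library_kras"),
                         library_ev = attr(table, "library_ev")) {
  stopifnot(is.data.frame(table),
            all(c("accession", "count_kras", "count_ev") %in% names(table)))
  if (is.null(library_kras)) library_kras <- sum(table$count_kras)
  if (is.null(library_ev)) library_ev <- sum(table$count_ev)
  a <- table$count_kras
  b <- table$count_ev
  p <- binomial_test(a, b, library_kras, library_ev)
  q <- bh_fdr(p)
  cc <- params$pseudocount
  lfc <- log2((a + cc) / library_kras) - log2((b + cc) / library_ev)
  cls <- rep("SHARED", length(a))
  cls[b == 0L & a >= params$min_psm_unique] <- "UNIQUE_KRAS"
  cls[a == 0L & b >= params$min_psm_unique] <- "UNIQUE_EV"
  both <- a > 0L & b > 0L
  cls[both & q <= params$alpha_fdr & lfc > 0] <- "UP_KRAS"
  cls[both & q <= params$alpha_fdr & lfc < 0] <- "UP_EV"
  out <- data.frame(accession = table$accession, count_kras = a,
                    count_ev = b, p_value = p, q_value = q, log2_fold = lfc,
                    class = cls, stringsAsFactors = FALSE, row.names = NULL)
  structure(out, params = params, library_kras = library_kras,
            library_ev = library_ev,
            class = c("surface_diff", "data.frame"))
}

#' @export
print.surface_diff <- function(x, ...) {
  cat("Spectral-counting differential surface analysis\n")
  cat(sprintf("  %d proteins; library sizes KRas %d, EV %d PSMs\n",
              nrow(x), attr(x, "library_kras"), attr(x, "library_ev")))
  tab <- table(factor(x$class, levels = c("UNIQUE_KRAS", "UP_KRAS", "SHARED",
                                          "UP_EV", "UNIQUE_EV")))
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
summary.surface_diff <- function(object, n = 10L, ...) {
  print(object)
  p <- attr(object, "params")
  cat(sprintf("  alpha_fdr=%.3g pseudocount=%.3g min_psm_unique=%d\n",
              p$alpha_fdr, p$pseudocount, p$min_psm_unique))
  o <- order(object$q_value, object$p_value)
  top <- utils::head(as.data.frame(object)[o, ], n)
  cat("  top proteins by q-value:\n")
  print(top, row.names = FALSE, digits = 3)
  invisible(object)
}

#' Volcano-style plot of a differential surface analysis
#'
#' @param x A `surface_diff` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.surface_diff <- function(x, ...) {
  col <- c(UNIQUE_KRAS = "firebrick", UP_KRAS = "tomato", SHARED = "grey60",
           UP_EV = "steelblue", UNIQUE_EV = "navy")[x$class]
  graphics::plot(x$log2_fold, -log10(pmax(x$p_value, 1e-300)), col = col,
                 pch = 19, cex = 0.6, xlab = "log2 fold (KRas / EV)",
                 ylab = "-log10 p", ...)
  graphics::abline(h = -log10(0.05), lty = 2, col = "grey40")
  invisible(x)
}
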