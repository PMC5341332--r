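#' Estimate peptide q-values by target-decoy competition
#'
#' For every score threshold `t`, the decoy-estimated false discovery rate is
#' `FDR(t) = #decoys with score >= t / max(1, #targets with score >= t)`.
#' A PSM's q-value is the minimum `FDR(t)` over all thresholds `t` at or below
#' its own score, i.e. the best achievable FDR at which the PSM is still
#' accepted. q-values are therefore non-increasing in score. Decoy PSMs
#' receive a q-value too (they are excluded from identification downstream,
#' not here).
#'
#' This is a deliberately plain substitute for semi-supervised re-scoring
#' (Percolator): it uses the search score as-is and competes targets against
#' decoys at every threshold.
#'
#' @param psms PSM data.frame with numeric `score` and logical `is_decoy`.
#' @return The same data.frame with `q_value` filled.
#' @examples
#' psms <- data.frame(score = c(10, 9, 8, 7, 8.5),
#'                    is_decoy = c(FALSE, FALSE, FALSE, FALSE, TRUE))
#' estimate_qvalues(psms)$q_value
#' @export
estimate_qvalues <- function(psms) {
  stopifnot(is.data.frame(psms), all(c("score", "is_decoy") %in% names(psms)),
            !anyNA(psms$score), !anyNA(psms$is_decoy))
  if (!any(!psms$is_decoy)) stop("no target PSMs", call. = FALSE)
  if (!any(psms$is_decoy)) {
    warning("no decoy PSMs: FDR is uncontrolled, all q-values set to 0")
    psms$q_value <- 0
    return(psms)
  }
  o <- order(psms$score, decreasing = TRUE)
  s <- psms$score[o]
  d <- psms$is_decoy[o]
  cum_d <- cumsum(d)
  cum_t <- cumsum(!d)
  # at a threshold equal to a tied score, all tied PSMs are included: use the
  # cumulative counts at the end of each tie block
  rl <- rle(s)
  block_end <- rep(cumsum(rl$lengths), rl$lengths)
  fdr <- cum_d[block_end] / pmax(1, cum_t[block_end])
  q <- rev(cummin(rev(fdr)))
  psms$q_value[o] <- q
  psms
}
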