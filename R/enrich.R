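#' Round half away from zero
#'
#' Reporting helper matching how overlap percentages are conventionally
#' printed (0.5 rounds up), unlike R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param decimals Number of decimals.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, decimals = 0L) {
  f <- 10^decimals
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Percentage overlap at printed precision
#'
#' @param n_annotated Number of annotated entries, `0 <= n_annotated <=
#'   n_total`.
#' @param n_total Total entries (>= 1).
#' @param decimals Decimals to round to (half-up).
#' @return `100 * n_annotated / n_total`, rounded.
#' @examples
#' percent_overlap(145, 148)      # 98
#' percent_overlap(1338, 4869, 1) # 27.5
#' @export
percent_overlap <- function(n_annotated, n_total, decimals = 0L) {
  if (any(n_total < 1)) stop("n_total must be >= 1", call. = FALSE)
  stopifnot(all(n_annotated >= 0), all(n_annotated <= n_total))
  round_half_up(100 * n_annotated / n_total, decimals)
}

#' Fold enrichment over a baseline fraction
#'
#' @param observed_fraction Observed annotated fraction in (0, 1].
#' @param baseline_fraction Whole-proteome baseline fraction in (0, 1] (e.g.
#'   0.02 for CD molecules in the human proteome).
#' @return The ratio `observed / baseline` (unrounded).
#' @seealso [fold_label()] for the reported integer fold.
#' @examples
#' fold_enrichment(0.303, 0.02)  # 15.15 -> reported "15-fold"
#' @export
fold_enrichment <- function(observed_fraction, baseline_fraction) {
  stopifnot(all(observed_fraction > 0), all(observed_fraction <= 1))
  if (any(baseline_fraction <= 0))
    stop("baseline_fraction must be > 0", call. = FALSE)
  stopifnot(all(baseline_fraction <= 1))
  observed_fraction / baseline_fraction
}

#' Reported integer fold
#'
#' @param fold Unrounded fold from [fold_enrichment()].
#' @return Nearest-integer fold (half-up), as used in prose like "15-fold".
#' @export
fold_label <- function(fold) {
  as.integer(round_half_up(fold, 0L))
}

#' Pathway coverage of an identified protein set
#'
#' @param identified Character vector of identified accessions.
#' @param pathway An [annotation_set()] of pathway members.
#' @return A list with `n_hit` (intersection size) and `percent` (integer
#'   percent of the pathway covered).
#' @examples
#' pw <- annotation_set("RAS2", paste0("P", 1:227))
#' pathway_coverage(paste0("P", 1:158), pw)
#' @export
pathway_coverage <- function(identified, pathway) {
  stopifnot(inherits(pathway, "annotation_set"))
  n_hit <- length(intersect(unique(identified), pathway$accessions))
  list(n_hit = n_hit,
       percent = percent_overlap(n_hit, length(pathway$accessions), 0L))
}

#' Enrichment report
#'
#' Stores the integer numerator/denominator alongside the printed percentage
#' so every reported value regenerates exactly.
#'
#' @param n_annotated,n_total Counts.
#' @param decimals Printed precision for the percentage.
#' @param baseline_fraction Optional baseline for fold enrichment.
#' @return List of class `enrichment_report` with `n_total`, `n_annotated`,
#'   `percent`, `baseline_fraction`, `fold` (NA without a baseline).
#' @export
enrichment_report <- function(n_annotated, n_total, decimals = 1L,
                              baseline_fraction = NULL) {
  pct <- if (n_total >= 1) percent_overlap(n_annotated, n_total, decimals)
         else NA_real_
  fold <- if (!is.null(baseline_fraction) && n_total >= 1 && n_annotated > 0)
    fold_enrichment(n_annotated / n_total, baseline_fraction)
  else NA_real_
  structure(list(n_total = n_total, n_annotated = n_annotated, percent = pct,
                 baseline_fraction = baseline_fraction, fold = fold),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf("%d of %d (%s%%)", x$n_annotated, x$n_total,
              format(x$percent)))
  if (!is.na(x$fold))
    cat(sprintf(", %d-fold over the %.3g%% baseline", fold_label(x$fold),
                100 * x$baseline_fraction))
  cat("\n")
  invisible(x)
}

# collapse isoform accessions (P12345-2) to their canonical root
canonical_accession <- function(x) sub("-[0-9]+$", "", x)

#' Merge both platforms into a non-redundant KRas surface map
#'
#' Combines the classified differential results of the CSC and SGM arms into
#' one entry per accession, keeping only proteins called `UNIQUE_KRAS` or
#' `UP_KRAS` on at least one platform. Cross-platform conflicts are resolved
#' conservatively: an accession is `UNIQUE_KRAS` only if its EV count is zero
#' on *every* platform that measured it; otherwise it is demoted to
#' `UP_KRAS` when significant in the KRas direction on either platform, and
#' dropped when not. Isoform accessions are collapsed to their canonical root
#' before merging.
#'
#' @param csc,sgm `surface_diff` objects (or data.frames with the same
#'   columns) for the CSC and SGM arm. Either may be NULL.
#' @param annotations Optional named list of [annotation_set()]s under keys
#'   `cspa`, `cd`, `pathway`, used to fill the annotation flags.
#' @param alpha_fdr Significance gate used when demoting a conflicted unique
#'   call (default 0.05).
#' @return A data.frame of surface-map entries: `accession`, `class`
#'   (`UNIQUE_KRAS` or `UP_KRAS`), `platforms` (`"CSC"`, `"SGM"` or
#'   `"CSC;SGM"`), `in_cspa`, `is_cd`, `in_pathway`.
#' @export
merge_nonredundant <- function(csc, sgm, annotations = list(),
                               alpha_fdr = 0.05) {
  prep <- function(x, platform) {
    if (is.null(x) || nrow(x) == 0L) return(NULL)
    df <- as.data.frame(x)
    df$accession <- canonical_accession(df$accession)
    if (anyDuplicated(df$accession)) {
      # isoform collapse can merge rows; keep the strongest evidence
      df <- df[order(df$accession, df$q_value), , drop = FALSE]
      df <- df[!duplicated(df$accession), , drop = FALSE]
    }
    df$platform <- platform
    df
  }
  all_res <- rbind(prep(csc, "CSC"), prep(sgm, "SGM"))
  if (is.null(all_res) || nrow(all_res) == 0L)
    return(data.frame(accession = character(), class = character(),
                      platforms = character(), in_cspa = logical(),
                      is_cd = logical(), in_pathway = logical(),
                      stringsAsFactors = FALSE))
  eligible <- unique(all_res$accession[all_res$class %in%
                                         c("UNIQUE_KRAS", "UP_KRAS")])
  rows <- lapply(sort(eligible), function(acc) {
    r <- all_res[all_res$accession == acc, , drop = FALSE]
    platforms <- paste(sort(unique(r$platform)), collapse = ";")
    ev_zero_everywhere <- all(r$count_ev == 0L)
    significant <- any(r$class == "UP_KRAS" |
                         (r$q_value <= alpha_fdr & r$log2_fold > 0))
    cls <- if (any(r$class == "UNIQUE_KRAS") && ev_zero_everywhere)
      "UNIQUE_KRAS"
    else if (significant) "UP_KRAS"
    else NA_character_
    if (is.na(cls)) return(NULL)
    data.frame(accession = acc, class = cls, platforms = platforms,
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, rows)
  if (is.null(map))
    return(data.frame(accession = character(), class = character(),
                      platforms = character(), in_cspa = logical(),
                      is_cd = logical(), in_pathway = logical(),
                      stringsAsFactors = FALSE))
  flag <- function(key) {
    ann <- annotations[[key]]
    if (is.null(ann)) rep(FALSE, nrow(map))
    else map$accession %in% canonical_accession(ann$accessions)
  }
  map$in_cspa <- flag("cspa")
  map$is_cd <- flag("cd")
  map$in_pathway <- flag("pathway")
  row.names(map) <- NULL
  map
}

#' CSPA glycoprotein fraction of the surface map, per class
#'
#' @param map [merge_nonredundant()] result.
#' @param cspa [annotation_set()] of catalogued surface glycoproteins; when
#'   NULL the map's `in_cspa` flag is used as-is.
#' @param decimals Printed precision (default 1).
#' @return Named list of [enrichment_report()]s for classes `UNIQUE_KRAS`
#'   and `UP_KRAS`; classes with no entries are omitted.
#' @export
glyco_fraction_of_map <- function(map, cspa = NULL, decimals = 1L) {
  in_cspa <- if (is.null(cspa)) map$in_cspa
  else canonical_accession(map$accession) %in%
    canonical_accession(cspa$accessions)
  out <- list()
  for (cls in c("UNIQUE_KRAS", "UP_KRAS")) {
    sel <- map$class == cls
    if (!any(sel)) next
    out[[cls]] <- enrichment_report(sum(in_cspa[sel]), sum(sel), decimals)
  }
  out
}
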