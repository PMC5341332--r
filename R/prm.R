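# monoisotopic residue masses (Da), standard 20 amino acids
RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
MASS_WATER <- 18.010565
MASS_PROTON <- 1.007276

# exact +10 shift of 13C6 15N4 arginine / +8 of 13C6 15N2 lysine
HEAVY_R_DELTA <- 10.00827
HEAVY_K_DELTA <- 8.01420

#' Heavy-isotope label scheme
#'
#' Describes a stable-isotope label applied to the C-terminal residue of the
#' heavy internal-standard peptide. Defaults to the SILAC-style pair
#' 13C6,15N4-arginine (+10.00827 Da) and 13C6,15N2-lysine (+8.01420 Da),
#' matching tryptic C-termini.
#'
#' @param labeled_residues Residues that can carry the label.
#' @param delta_per_residue Named numeric vector of label mass shifts (Da).
#' @return A list of class `label_scheme`.
#' @export
label_scheme <- function(labeled_residues = c("K", "R"),
                         delta_per_residue = c(K = HEAVY_K_DELTA,
                                               R = HEAVY_R_DELTA)) {
  stopifnot(all(labeled_residues %in% names(delta_per_residue)),
            all(delta_per_residue > 0))
  structure(list(labeled_residues = labeled_residues,
                 delta_per_residue = delta_per_residue),
            class = "label_scheme")
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K/R except when the next residue is proline (the KP
#' rule), emitting all peptides with 0 to `max_missed` missed cleavages,
#' ordered by start position.
#'
#' @param sequence Protein sequence (string) or a single-row protein
#'   data.frame with a `sequence` column.
#' @param max_missed Maximum missed cleavages (default 2).
#' @return data.frame with `peptide`, `start` (1-based), `end`,
#'   `missed_cleavages`.
#' @examples
#' digest_tryptic("MKAAGR", max_missed = 0)
#' @export
digest_tryptic <- function(sequence, max_missed = 2L) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[[1]]
  stopifnot(is.character(sequence), nchar(sequence) > 0)
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | res[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after, if (!n %in% cut_after) n)
  starts <- utils::head(bounds, -1L) + 1L
  ends <- bounds[-1L]
  out <- list()
  for (i in seq_along(starts)) {
    for (m in 0:max_missed) {
      j <- i + m
      if (j > length(ends)) break
      out[[length(out) + 1L]] <- data.frame(
        peptide = substr(sequence, starts[i], ends[j]),
        start = starts[i], end = ends[j], missed_cleavages = m,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  df <- df[order(df$start, df$end), , drop = FALSE]
  row.names(df) <- NULL
  df
}

residue_masses <- function(peptide) {
  res <- strsplit(peptide, "")[[1]]
  m <- RESIDUE_MASS[res]
  if (anyNA(m))
    stop("unknown residue '", res[is.na(m)][1], "' in peptide '", peptide,
         "'", call. = FALSE)
  unname(m)
}

#' Monoisotopic peptide mass
#'
#' Sum of monoisotopic residue masses plus water, plus any modification
#' deltas, plus the heavy-label delta when `heavy` and the C-terminal residue
#' is labeled.
#'
#' @param peptide Peptide sequence.
#' @param modifications Optional data.frame with `delta` column (positions
#'   are irrelevant for the neutral mass).
#' @param label Optional [label_scheme()].
#' @param heavy Apply the heavy label (default FALSE).
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' mono_mass("G")  # 57.02146 + water
#' mono_mass("INQLISETEAVVTNELEDGDR", label = label_scheme(), heavy = TRUE) -
#'   mono_mass("INQLISETEAVVTNELEDGDR")  # 10.00827
#' @export
mono_mass <- function(peptide, modifications = NULL, label = NULL,
                      heavy = FALSE) {
  m <- sum(residue_masses(peptide)) + MASS_WATER
  if (!is.null(modifications) && nrow(modifications) > 0)
    m <- m + sum(modifications$delta)
  if (heavy && !is.null(label)) {
    cterm <- substr(peptide, nchar(peptide), nchar(peptide))
    if (cterm %in% label$labeled_residues)
      m <- m + label$delta_per_residue[[cterm]]
  }
  m
}

#' b/y fragment ion m/z
#'
#' Singly-protonated fragment series of a linear peptide:
#' `b_k = (sum of residues 1..k + z protons) / z`,
#' `y_k = (sum of the last k residues + water + z protons) / z`.
#' The heavy label shifts only fragments containing the labeled C-terminal
#' residue: every y-ion, and b-ions only when they span the full length
#' (which the `ordinal < length` contract excludes).
#'
#' @param peptide Peptide sequence.
#' @param series `"b"` or `"y"`.
#' @param ordinal Fragment ordinal, `1 <= ordinal < nchar(peptide)`.
#' @param charge Positive integer charge (default 1).
#' @param label Optional [label_scheme()].
#' @param heavy Compute the heavy-labeled fragment (default FALSE).
#' @return m/z in Th.
#' @examples
#' fragment_mz("AAGR", "y", 1)  # 175.11895, the y1 of any ...R peptide
#' @export
fragment_mz <- function(peptide, series = c("b", "y"), ordinal, charge = 1L,
                        label = NULL, heavy = FALSE) {
  series <- match.arg(series)
  n <- nchar(peptide)
  if (ordinal < 1L || ordinal >= n)
    stop("ordinal must satisfy 1 <= ordinal < peptide length", call. = FALSE)
  stopifnot(charge >= 1L)
  rm <- residue_masses(peptide)
  if (series == "b") {
    neutral <- sum(rm[seq_len(ordinal)])
    spans_cterm <- FALSE
  } else {
    neutral <- sum(rm[(n - ordinal + 1L):n]) + MASS_WATER
    spans_cterm <- TRUE
  }
  if (heavy && !is.null(label) && spans_cterm) {
    cterm <- substr(peptide, n, n)
    if (cterm %in% label$labeled_residues)
      neutral <- neutral + label$delta_per_residue[[cterm]]
  }
  (neutral + charge * MASS_PROTON) / charge
}

#' Extract an ion chromatogram at ppm tolerance
#'
#' Per scan, sums the intensities of all peaks within
#' `|mz - target| <= target * ppm * 1e-6`, optionally restricted to a
#' retention-time window, and integrates the trace by the trapezoid rule over
#' scan time.
#'
#' @param spectra List of scans ([read_mgf()]), time-sorted.
#' @param target_mz Target m/z (Th).
#' @param ppm Mass tolerance in parts per million (default 3).
#' @param rt_window Optional `c(start, end)` in seconds.
#' @return A list of class `xic_trace`: `target_mz`, `scan_time`,
#'   `intensity`, `area`.
#' @export
extract_xic <- function(spectra, target_mz, ppm = 3, rt_window = NULL) {
  tol <- target_mz * ppm * 1e-6
  times <- vapply(spectra, `[[`, 0, "scan_time")
  keep <- rep(TRUE, length(spectra))
  if (!is.null(rt_window))
    keep <- times >= rt_window[1] & times <= rt_window[2]
  times <- times[keep]
  ints <- vapply(spectra[keep], function(sc) {
    if (length(sc$mz) == 0L) return(0)
    sum(sc$intensity[abs(sc$mz - target_mz) <= tol])
  }, 0)
  area <- if (length(times) >= 2L)
    sum(diff(times) * (utils::head(ints, -1L) + utils::tail(ints, -1L)) / 2)
  else 0
  structure(list(target_mz = target_mz, scan_time = times, intensity = ints,
                 area = area), class = "xic_trace")
}

#' Predict PRM transitions for a peptide
#'
#' Candidate singly-charged y-ion transitions (optionally b-ions) for the
#' light and heavy forms of a C-terminally labeled peptide. y-ions of a
#' tryptic peptide always contain the labeled C-terminal K/R, so every
#' light/heavy partner pair is mass-resolved; b-ions below full length never
#' carry the label and are therefore excluded by default, since their light
#' and heavy m/z coincide.
#'
#' @param peptide Peptide sequence.
#' @param label [label_scheme()].
#' @param charge Fragment charge (default 1).
#' @param include_b Include b-ions (default FALSE).
#' @return data.frame with `series`, `ordinal`, `charge`, `mz_light`,
#'   `mz_heavy`.
#' @export
predict_transitions <- function(peptide, label = label_scheme(), charge = 1L,
                                include_b = FALSE) {
  n <- nchar(peptide)
  ords <- seq_len(n - 1L)
  out <- data.frame(series = "y", ordinal = ords, charge = charge,
                    stringsAsFactors = FALSE)
  if (include_b)
    out <- rbind(out, data.frame(series = "b", ordinal = ords,
                                 charge = charge, stringsAsFactors = FALSE))
  out$mz_light <- mapply(function(s, o) fragment_mz(peptide, s, o, charge,
                                                    label, heavy = FALSE),
                         out$series, out$ordinal)
  out$mz_heavy <- mapply(function(s, o) fragment_mz(peptide, s, o, charge,
                                                    label, heavy = TRUE),
                         out$series, out$ordinal)
  row.names(out) <- NULL
  out
}

#' PRM light/heavy ratio against a heavy internal standard
#'
#' Predicts the candidate transitions of the target peptide, extracts the
#' heavy-standard XIC of each, ranks transitions by heavy area, keeps the
#' `n_transitions` most intense, extracts the light partner XICs at the same
#' ordinals, and reports the summed-area ratio
#' `sum(light areas) / sum(heavy areas)`. Ranking on the heavy channel is
#' used because the internal standard's abundance is controlled.
#'
#' @param spectra List of scans ([read_mgf()]) containing both isolation
#'   targets.
#' @param peptide Target peptide sequence (C-terminal K/R for a tryptic
#'   assay).
#' @param label [label_scheme()].
#' @param n_transitions Number of transitions quantified (default 5).
#' @param ppm XIC mass tolerance in ppm (default 3).
#' @param rt_window Optional retention-time window, seconds.
#' @param include_b Include b-ions among candidates (default FALSE; see
#'   [predict_transitions()]).
#' @return A list of class `prm_result`: `light_area`, `heavy_area`,
#'   `ratio`, and the per-transition `transitions` data.frame (with
#'   `area_light`, `area_heavy`, `used`).
#' @export
prm_ratio <- function(spectra, peptide, label = label_scheme(),
                      n_transitions = 5L, ppm = 3, rt_window = NULL,
                      include_b = FALSE) {
  tr <- predict_transitions(peptide, label, include_b = include_b)
  tr$area_heavy <- vapply(tr$mz_heavy, function(mz)
    extract_xic(spectra, mz, ppm, rt_window)$area, 0)
  tr$area_light <- vapply(tr$mz_light, function(mz)
    extract_xic(spectra, mz, ppm, rt_window)$area, 0)
  o <- order(tr$area_heavy, decreasing = TRUE)
  used <- utils::head(o, n_transitions)
  tr$used <- seq_len(nrow(tr)) %in% used
  heavy_area <- sum(tr$area_heavy[tr$used])
  light_area <- sum(tr$area_light[tr$used])
  if (heavy_area <= 0)
    stop("heavy internal standard not detected (zero heavy area)",
         call. = FALSE)
  structure(list(light_area = light_area, heavy_area = heavy_area,
                 ratio = light_area / heavy_area, transitions = tr),
            class = "prm_result")
}

#' @export
print.prm_result <- function(x, ...) {
  cat(sprintf(paste0("PRM quantitation: light/heavy ratio %.4f ",
                     "(light area %.4g, heavy area %.4g, %d transitions)\n"),
              x$ratio, x$light_area, x$heavy_area, sum(x$transitions$used)))
  invisible(x)
}
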