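AA20 <- names(RESIDUE_MASS)

#' Simulation configuration
#'
#' Defines the conditions of the emulated two-condition (KRas vs empty
#' vector) surface-proteomics experiment: proteome composition, planted
#' effect sizes, count model, decoy score separation, and PRM light/heavy
#' ratios. Identical configurations yield bit-identical outputs.
#'
#' @param seed Integer RNG seed.
#' @param n_proteins Number of target proteins in the synthetic proteome.
#' @param frac_surface Fraction of proteins residing on the cell surface.
#' @param frac_glyco Fraction of surface proteins that are N-glycosylated
#'   (carry planted sequons; detectable by the CSC arm).
#' @param frac_cd Fraction of the proteome that are CD molecules (default
#'   0.02, the whole-proteome CD baseline); CD molecules are surface
#'   proteins.
#' @param frac_cspa Coverage of surface proteins by the synthetic CSPA
#'   catalogue (default 0.9).
#' @param frac_pathway Fraction of the proteome in the synthetic pathway
#'   list (default 0.1).
#' @param n_true_up Number of planted significantly upregulated (KRas)
#'   surface proteins.
#' @param n_true_unique Number of planted KRas-unique surface proteins
#'   (absent from EV).
#' @param planted_log2_fold Planted log2 fold change of upregulated proteins
#'   (default 2, i.e. 4-fold).
#' @param mean_count Expected per-protein PSM count in the EV condition
#'   (default 30).
#' @param count_model `"poisson"` or `"negbin"`.
#' @param dispersion Negative-binomial dispersion (used when `count_model =
#'   "negbin"`; variance = mu + dispersion * mu^2).
#' @param decoy_score_shift Downward shift of the decoy score distribution
#'   relative to targets (default 3 score units, sd 1).
#' @param nonsequon_rate Fraction of CSC PSMs whose deamidation falls on a
#'   planted non-sequon asparagine (negative controls for the sequon gate;
#'   default 0.05).
#' @param prm_ratios Named light/heavy PRM ratios per condition.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_proteins = 300L,
                              frac_surface = 0.5,
                              frac_glyco = 0.6,
                              frac_cd = 0.02,
                              frac_cspa = 0.9,
                              frac_pathway = 0.1,
                              n_true_up = 20L,
                              n_true_unique = 20L,
                              planted_log2_fold = 2,
                              mean_count = 30,
                              count_model = c("poisson", "negbin"),
                              dispersion = 0.2,
                              decoy_score_shift = 3,
                              nonsequon_rate = 0.05,
                              prm_ratios = c(KRAS = 1.8, EV = 0.9)) {
  count_model <- match.arg(count_model)
  stopifnot(frac_surface >= 0, frac_surface <= 1, frac_glyco >= 0,
            frac_glyco <= 1, frac_cd >= 0, frac_cd <= 1, mean_count > 0,
            nonsequon_rate >= 0, nonsequon_rate < 1)
  if (frac_cd > frac_surface)
    stop("infeasible fractions: frac_cd > frac_surface (CD molecules are ",
         "surface proteins)", call. = FALSE)
  structure(list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
                 frac_surface = frac_surface, frac_glyco = frac_glyco,
                 frac_cd = frac_cd, frac_cspa = frac_cspa,
                 frac_pathway = frac_pathway,
                 n_true_up = as.integer(n_true_up),
                 n_true_unique = as.integer(n_true_unique),
                 planted_log2_fold = planted_log2_fold,
                 mean_count = mean_count, count_model = count_model,
                 dispersion = dispersion,
                 decoy_score_shift = decoy_score_shift,
                 nonsequon_rate = nonsequon_rate, prm_ratios = prm_ratios),
            class = "simulation_config")
}

# plant a motif window into a residue vector: NxS/T (sequon) or an
# asparagine explicitly not followed by S/T two residues later
plant_site <- function(res, pos, sequon) {
  res[pos] <- "N"
  res[pos + 1L] <- sample(setdiff(AA20, c("P", "N")), 1L)
  res[pos + 2L] <- if (sequon) sample(c("S", "T"), 1L)
  else sample(setdiff(AA20, c("S", "T", "N")), 1L)
  res
}

#' Generate a synthetic proteome with planted glycosites and annotations
#'
#' Builds random protein sequences; every glyco-flagged surface protein gets
#' 1-3 planted valid NxS/T sequons plus one planted non-sequon asparagine
#' (a negative control for the sequon filter). Reversed-sequence decoys with
#' the `DECOY_` prefix are appended. Synthetic CSPA / CD / pathway
#' annotation lists are sampled at the configured fractions, and per-protein
#' ground truth (planted class and log2 fold) is assigned.
#'
#' @param config [simulation_config()].
#' @return A list with `proteins` (data.frame incl. decoys, as
#'   [read_fasta()]), `annotations` (named list of [annotation_set()]s:
#'   `cspa`, `cd`, `pathway`), and `truth` (per-target-protein data.frame
#'   with flags, planted site positions as semicolon strings, `true_class`,
#'   `true_log2_fold`).
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  accession <- sprintf("SP%04d", seq_len(n))
  gene_symbol <- sprintf("GENE%04d", seq_len(n))
  is_surface <- seq_len(n) %in% sample(n, round(config$frac_surface * n))
  surf_idx <- which(is_surface)
  is_glyco <- logical(n)
  is_glyco[sample(surf_idx, round(config$frac_glyco * length(surf_idx)))] <-
    TRUE
  is_cd <- logical(n)
  n_cd <- min(length(surf_idx), round(config$frac_cd * n))
  if (n_cd > 0) is_cd[sample(surf_idx, n_cd)] <- TRUE
  is_cspa <- logical(n)
  is_cspa[surf_idx[stats::runif(length(surf_idx)) < config$frac_cspa]] <- TRUE
  in_pathway <- stats::runif(n) < config$frac_pathway

  sequence <- character(n)
  sequon_sites <- character(n)
  nonsequon_sites <- character(n)
  for (i in seq_len(n)) {
    len <- sample(90:160, 1L)
    res <- sample(AA20, len, replace = TRUE)
    if (is_glyco[i]) {
      k <- sample(1:3, 1L)
      # disjoint 5-residue windows keep planted sites from overlapping
      slots <- seq(5L, len - 6L, by = 5L)
      pos <- sort(sample(slots, k + 1L))
      for (p in pos[seq_len(k)]) res <- plant_site(res, p, sequon = TRUE)
      res <- plant_site(res, pos[k + 1L], sequon = FALSE)
      sequon_sites[i] <- paste(pos[seq_len(k)], collapse = ";")
      nonsequon_sites[i] <- as.character(pos[k + 1L])
    }
    sequence[i] <- paste(res, collapse = "")
  }

  # planted effects live on surface proteins (detectable by >= 1 arm)
  true_class <- rep("NULL", n)
  true_log2_fold <- rep(0, n)
  n_eff <- config$n_true_unique + config$n_true_up
  if (n_eff > length(surf_idx))
    stop("not enough surface proteins for the planted effects", call. = FALSE)
  eff <- sample(surf_idx, n_eff)
  uniq <- eff[seq_len(config$n_true_unique)]
  ups <- setdiff(eff, uniq)
  true_class[uniq] <- "UNIQUE_KRAS"
  true_class[ups] <- "UP_KRAS"
  true_log2_fold[ups] <- config$planted_log2_fold

  targets <- data.frame(accession = accession, gene_symbol = gene_symbol,
                        sequence = sequence, is_decoy = FALSE,
                        stringsAsFactors = FALSE)
  decoys <- data.frame(
    accession = paste0("DECOY_", accession), gene_symbol = NA_character_,
    sequence = vapply(sequence, function(s)
      paste(rev(strsplit(s, "")[[1]]), collapse = ""), ""),
    is_decoy = TRUE, stringsAsFactors = FALSE)
  truth <- data.frame(accession = accession, gene_symbol = gene_symbol,
                      is_surface = is_surface, is_glyco = is_glyco,
                      is_cspa = is_cspa, is_cd = is_cd,
                      in_pathway = in_pathway, sequon_sites = sequon_sites,
                      nonsequon_sites = nonsequon_sites,
                      true_class = true_class,
                      true_log2_fold = true_log2_fold,
                      stringsAsFactors = FALSE)
  annotations <- list(
    cspa = annotation_set("CSPA", accession[is_cspa]),
    cd = annotation_set("CD", accession[is_cd],
                        baseline_fraction = config$frac_cd),
    pathway = annotation_set("RAS2", accession[in_pathway]))
  list(proteins = rbind(targets, decoys), annotations = annotations,
       truth = truth)
}

draw_counts <- function(config, mu, n = length(mu)) {
  if (config$count_model == "poisson") stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / config$dispersion)
}

# pick, per planted site, the 0-missed tryptic peptide covering it
covering_peptide <- function(sequence, site) {
  d <- digest_tryptic(sequence, max_missed = 0L)
  hit <- d[d$start <= site & d$end >= site + 2L, , drop = FALSE]
  if (nrow(hit) == 0L) hit <- d[d$start <= site & d$end >= site, ,
                                drop = FALSE]
  if (nrow(hit) == 0L) return(NULL)
  hit[1L, ]
}

#' Generate scored PSM tables for both arms
#'
#' Per-protein PSM counts are drawn from the configured count model with the
#' EV mean at `mean_count` and the KRas mean scaled by the planted fold
#' (planted KRas-unique proteins have EV mean zero). The CSC arm emits only
#' glyco-surface proteins, each PSM carrying a deamidation at a planted
#' sequon (or, at `nonsequon_rate`, at the planted non-sequon asparagine);
#' the SGM arm emits all surface proteins plus a non-surface background.
#' Decoy PSMs are drawn with scores shifted down by `decoy_score_shift`.
#'
#' @param config [simulation_config()].
#' @param sim Output of [generate_proteome()].
#' @return Named list of PSM data.frames, `csc` and `sgm`.
#' @export
generate_psm_tables <- function(config, sim) {
  set.seed(config$seed + 1L)
  truth <- sim$truth
  targets <- sim$proteins[!sim$proteins$is_decoy, ]
  decoys <- sim$proteins[sim$proteins$is_decoy, ]
  replicates <- list(
    csc = c("b1t1", "b1t2", "b1t3", "b2t1", "b2t2", "b2t3"),
    sgm = c("t1", "t2"))

  # per-protein precomputed building blocks (digests are the slow part)
  csc_site_cache <- new.env(parent = emptyenv())
  sgm_pep_cache <- new.env(parent = emptyenv())
  csc_sites_for <- function(i) {
    key <- as.character(i)
    hit <- csc_site_cache[[key]]
    if (!is.null(hit)) return(hit)
    seqc <- targets$sequence[i]
    all_sites <- c(as.integer(strsplit(truth$sequon_sites[i], ";")[[1]]),
                   as.integer(truth$nonsequon_sites[i]))
    rows <- lapply(all_sites, function(site) {
      cp <- covering_peptide(seqc, site)
      if (is.null(cp)) return(NULL)
      list(peptide = cp$peptide,
           mods = sprintf("%d:Deamidated:0.984", site - cp$start + 1L))
    })
    n_good <- length(all_sites) - 1L
    hit <- list(
      pep = vapply(rows, function(r) if (is.null(r)) NA_character_ else
        r$peptide, ""),
      mods = vapply(rows, function(r) if (is.null(r)) NA_character_ else
        r$mods, ""),
      n_good = n_good)
    csc_site_cache[[key]] <- hit
    hit
  }
  sgm_peps_for <- function(i) {
    key <- as.character(i)
    hit <- sgm_pep_cache[[key]]
    if (!is.null(hit)) return(hit)
    d <- digest_tryptic(targets$sequence[i], max_missed = 0L)
    d <- d[nchar(d$peptide) >= 6L, , drop = FALSE]
    if (nrow(d) == 0L) d <- digest_tryptic(targets$sequence[i],
                                           max_missed = 1L)
    hit <- d$peptide
    sgm_pep_cache[[key]] <- hit
    hit
  }

  make_rows <- function(i, cond, count, arm) {
    if (count == 0L) return(NULL)
    if (arm == "csc") {
      sc <- csc_sites_for(i)
      good <- seq_len(sc$n_good)
      pick <- ifelse(stats::runif(count) < config$nonsequon_rate,
                     sc$n_good + 1L, sample(rep(good, 2L), count,
                                            replace = TRUE))
      keep <- !is.na(sc$pep[pick])
      if (!any(keep)) return(NULL)
      list(peptide = sc$pep[pick][keep],
           modifications = sc$mods[pick][keep],
           proteins = rep(targets$accession[i], sum(keep)))
    } else {
      peps <- sgm_peps_for(i)
      list(peptide = peps[sample(length(peps), count, replace = TRUE)],
           modifications = rep("", count),
           proteins = rep(targets$accession[i], count))
    }
  }

  build_arm <- function(arm) {
    detectable <- if (arm == "csc") which(truth$is_glyco)
    else sort(c(which(truth$is_surface),
                sample(which(!truth$is_surface),
                       round(0.3 * sum(!truth$is_surface)))))
    out <- list()
    for (i in detectable) {
      lfc <- truth$true_log2_fold[i]
      mu_ev <- if (truth$true_class[i] == "UNIQUE_KRAS") 0 else
        config$mean_count
      mu_kras <- if (truth$true_class[i] == "UNIQUE_KRAS")
        config$mean_count else config$mean_count * 2^lfc
      for (cond in CONDITIONS) {
        mu <- if (cond == "KRAS") mu_kras else mu_ev
        cnt <- if (mu == 0) 0L else draw_counts(config, mu, 1L)
        rows <- make_rows(i, cond, cnt, arm)
        if (is.null(rows)) next
        rows$condition <- rep(cond, length(rows$peptide))
        out[[length(out) + 1L]] <- rows
      }
    }
    psms <- data.frame(
      peptide = unlist(lapply(out, `[[`, "peptide")),
      modifications = unlist(lapply(out, `[[`, "modifications")),
      proteins = unlist(lapply(out, `[[`, "proteins")),
      condition = unlist(lapply(out, `[[`, "condition")),
      stringsAsFactors = FALSE)
    n_t <- nrow(psms)
    psms$score <- stats::rnorm(n_t, mean = 8, sd = 1)
    psms$charge <- sample(2:3, n_t, replace = TRUE)
    psms$replicate <- sample(replicates[[arm]], n_t, replace = TRUE)
    psms$is_decoy <- FALSE
    # decoy PSMs: same count scale, scores shifted down
    n_d <- max(1L, round(0.3 * n_t))
    di <- sample(nrow(decoys), n_d, replace = TRUE)
    dpeps <- lapply(unique(di), function(j) {
      d <- digest_tryptic(decoys$sequence[j], max_missed = 0L)
      d <- d[nchar(d$peptide) >= 6L, , drop = FALSE]
      if (nrow(d) == 0L) decoys$sequence[j] else d$peptide
    })
    names(dpeps) <- as.character(unique(di))
    dpep <- vapply(di, function(j) {
      p <- dpeps[[as.character(j)]]
      p[sample(length(p), 1L)]
    }, "")
    dec <- data.frame(
      peptide = dpep, modifications = "", proteins = decoys$accession[di],
      condition = sample(CONDITIONS, n_d, replace = TRUE),
      score = stats::rnorm(n_d, mean = 8 - config$decoy_score_shift, sd = 1),
      charge = sample(2:3, n_d, replace = TRUE),
      replicate = sample(replicates[[arm]], n_d, replace = TRUE),
      is_decoy = TRUE, stringsAsFactors = FALSE)
    psms <- rbind(psms, dec)
    psms$q_value <- NA_real_
    row.names(psms) <- NULL
    psms[, c(PSM_REQUIRED, "q_value", "is_decoy")]
  }

  list(csc = build_arm("csc"), sgm = build_arm("sgm"))
}

#' Generate a synthetic PRM run
#'
#' Emits MS2 scans with Gaussian elution profiles for the singly-charged
#' y-ion transitions of the light and heavy forms of the target peptide.
#' Per-transition light areas are exactly `ratio` times the heavy areas
#' before jitter/noise; fragment m/z jitter is uniform within
#' `jitter_ppm` and random noise peaks are added at uniform m/z.
#'
#' @param config [simulation_config()] (its `prm_ratios` supplies the
#'   condition ratio; its `seed` the RNG stream).
#' @param peptide Target peptide (C-terminal K/R).
#' @param condition `"KRAS"` or `"EV"`.
#' @param label [label_scheme()].
#' @param n_scans Number of MS2 scans (default 40).
#' @param jitter_ppm Maximum fragment m/z jitter, ppm (default 1; 0 for the
#'   noiseless limit).
#' @param n_noise_peaks Noise peaks per scan (default 20; 0 for noiseless).
#' @return A list of scans suitable for [write_mgf()] / [prm_ratio()].
#' @export
generate_prm_run <- function(config, peptide, condition = "KRAS",
                             label = label_scheme(), n_scans = 40L,
                             jitter_ppm = 1, n_noise_peaks = 20L) {
  stopifnot(condition %in% names(config$prm_ratios))
  cterm <- substr(peptide, nchar(peptide), nchar(peptide))
  if (!cterm %in% label$labeled_residues)
    stop("target peptide must end in a labeled residue (C-terminal K/R)",
         call. = FALSE)
  set.seed(config$seed + 100L + match(condition, CONDITIONS))
  ratio <- unname(config$prm_ratios[[condition]])
  tr <- predict_transitions(peptide, label)
  amp_heavy <- stats::runif(nrow(tr), 0.4, 1) * 1e6
  times <- seq(600, 660, length.out = n_scans)
  center <- 630
  width <- 8
  prec_light <- (mono_mass(peptide) + 2 * MASS_PROTON) / 2
  lapply(seq_along(times), function(s) {
    g <- exp(-(times[s] - center)^2 / (2 * width^2))
    jit <- function(mz) mz * (1 + stats::runif(length(mz), -1, 1) *
                                jitter_ppm * 1e-6)
    mz <- c(jit(tr$mz_heavy), jit(tr$mz_light))
    intensity <- c(amp_heavy * g, ratio * amp_heavy * g)
    if (n_noise_peaks > 0L) {
      mz <- c(mz, stats::runif(n_noise_peaks, 200, 1300))
      intensity <- c(intensity, stats::runif(n_noise_peaks, 0, 0.02 * 1e6))
    }
    o <- order(mz)
    list(title = sprintf("%s scan=%d", condition, s),
         scan_time = times[s], precursor_mz = prec_light,
         mz = mz[o], intensity = intensity[o])
  })
}
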