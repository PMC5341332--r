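# directory-based pipeline stages: each stage reads the artifacts of its
# upstream stage from `dir`, writes its own, and is idempotent given
# identical inputs and seed

artifact <- function(dir, name) file.path(dir, name)

require_artifact <- function(dir, name, producer) {
  p <- artifact(dir, name)
  if (!file.exists(p))
    stop("missing artifact '", name, "': run ", producer, "() first",
         call. = FALSE)
  p
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Simulate a full synthetic experiment into a run directory
#'
#' Writes the synthetic proteome FASTA, annotation lists, per-arm PSM tables,
#' per-condition PRM runs, the ground truth and the configuration into
#' `dir`.
#'
#' @param config [simulation_config()].
#' @param dir Output run directory (created if needed).
#' @param prm_peptide Target peptide for the PRM runs.
#' @return `dir`, invisibly.
#' @export
run_simulate <- function(config, dir,
                         prm_peptide = "INQLISETEAVVTNELEDGDR") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_proteome(config)
  write_fasta(sim$proteins, artifact(dir, "proteome.fasta"))
  for (key in names(sim$annotations))
    writeLines(sim$annotations[[key]]$accessions,
               artifact(dir, paste0(key, ".txt")))
  tabs <- generate_psm_tables(config, sim)
  write_psm_table(tabs$csc, artifact(dir, "psm_csc.tsv"))
  write_psm_table(tabs$sgm, artifact(dir, "psm_sgm.tsv"))
  for (cond in CONDITIONS)
    write_mgf(generate_prm_run(config, prm_peptide, cond),
              artifact(dir, paste0("prm_", cond, ".mgf")))
  truth <- sim$truth
  write_json(truth, artifact(dir, "ground_truth.json"))
  cfg <- unclass(config)
  cfg$prm_peptide <- prm_peptide
  write_json(cfg, artifact(dir, "config.json"))
  message("simulated run written to ", dir)
  invisible(dir)
}

read_run_annotations <- function(dir) {
  ann <- list()
  if (file.exists(artifact(dir, "cspa.txt")))
    ann$cspa <- read_annotation_list(artifact(dir, "cspa.txt"), "CSPA")
  if (file.exists(artifact(dir, "cd.txt")))
    ann$cd <- read_annotation_list(artifact(dir, "cd.txt"), "CD",
                                   baseline_fraction = 0.02)
  if (file.exists(artifact(dir, "pathway.txt")))
    ann$pathway <- read_annotation_list(artifact(dir, "pathway.txt"), "RAS2")
  ann
}

run_arm_stage <- function(dir, arm, params) {
  psms <- read_psm_table(require_artifact(dir, paste0("psm_", arm, ".tsv"),
                                          "run_simulate"))
  groups <- if (arm == "csc") {
    db <- read_fasta(require_artifact(dir, "proteome.fasta", "run_simulate"))
    csc_glycoproteome(psms, db, params)
  } else {
    sgm_proteome(psms, params)
  }
  for (cond in names(groups))
    utils::write.table(groups[[cond]],
                       artifact(dir, sprintf("%s_%s.tsv", arm, cond)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  stages <- attr(groups, "stages")
  write_json(stages, artifact(dir, paste0(arm, "_summary.json")))
  message(arm, " arm: ", paste(names(stages), unlist(stages),
                               sep = "=", collapse = " "))
  invisible(groups)
}

#' Run the CSC arm on a run directory
#'
#' Reads `psm_csc.tsv` and `proteome.fasta`, applies the CSC filter chain
#' (q-values, FDR gate, sequon gate, grouping, min-PSM gate) and writes
#' per-condition glycoproteome tables plus a stage-count summary.
#'
#' @param dir Run directory.
#' @param params [filter_params()].
#' @return Named list of per-condition group tables, invisibly.
#' @export
run_csc <- function(dir, params = filter_params()) {
  run_arm_stage(dir, "csc", params)
}

#' Run the SGM arm on a run directory
#'
#' @param dir Run directory.
#' @param params [filter_params()].
#' @return Named list of per-condition group tables, invisibly.
#' @export
run_sgm <- function(dir, params = filter_params()) {
  run_arm_stage(dir, "sgm", params)
}

read_groups <- function(dir, arm, cond, producer) {
  p <- require_artifact(dir, sprintf("%s_%s.tsv", arm, cond), producer)
  utils::read.delim(p, stringsAsFactors = FALSE)
}

#' Differential spectral-counting analysis for both arms
#'
#' Reads the grouped identifications of each arm, builds count tables and
#' fits [surface_diff()], writing `diff_csc.tsv` / `diff_sgm.tsv`.
#'
#' @param dir Run directory.
#' @param params [diff_params()].
#' @return Named list of `surface_diff` objects (`csc`, `sgm`), invisibly.
#' @export
run_diff <- function(dir, params = diff_params()) {
  out <- list()
  for (arm in c("csc", "sgm")) {
    producer <- if (arm == "csc") "run_csc" else "run_sgm"
    tab <- build_count_table(read_groups(dir, arm, "KRAS", producer),
                             read_groups(dir, arm, "EV", producer))
    fit <- surface_diff(tab, params)
    utils::write.table(as.data.frame(fit),
                       artifact(dir, paste0("diff_", arm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out[[arm]] <- fit
  }
  write_json(lapply(out, function(f) as.list(table(f$class))),
             artifact(dir, "diff_summary.json"))
  invisible(out)
}

read_diff <- function(dir, arm) {
  p <- require_artifact(dir, paste0("diff_", arm, ".tsv"), "run_diff")
  utils::read.delim(p, stringsAsFactors = FALSE)
}

#' Build the non-redundant surface map for a run directory
#'
#' @param dir Run directory.
#' @param alpha_fdr Significance gate for the demotion rule.
#' @return The surface-map data.frame, invisibly.
#' @export
run_map <- function(dir, alpha_fdr = 0.05) {
  map <- merge_nonredundant(read_diff(dir, "csc"), read_diff(dir, "sgm"),
                            annotations = read_run_annotations(dir),
                            alpha_fdr = alpha_fdr)
  utils::write.table(map, artifact(dir, "surface_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  message("surface map: ", nrow(map), " non-redundant entries")
  invisible(map)
}

#' Quantify the PRM assay for a run directory
#'
#' @param dir Run directory containing `prm_KRAS.mgf` / `prm_EV.mgf`.
#' @param peptide Target peptide; defaults to the one recorded in
#'   `config.json`.
#' @param ... Passed to [prm_ratio()].
#' @return data.frame of per-condition light/heavy ratios, invisibly.
#' @export
run_prm <- function(dir, peptide = NULL, ...) {
  if (is.null(peptide)) {
    cfgp <- require_artifact(dir, "config.json", "run_simulate")
    peptide <- jsonlite::read_json(cfgp)$prm_peptide
  }
  rows <- lapply(CONDITIONS, function(cond) {
    spectra <- read_mgf(require_artifact(dir, paste0("prm_", cond, ".mgf"),
                                         "run_simulate"))
    r <- prm_ratio(spectra, peptide, ...)
    data.frame(condition = cond, peptide = peptide,
               light_area = r$light_area, heavy_area = r$heavy_area,
               ratio = r$ratio, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  utils::write.table(res, artifact(dir, "prm_ratios.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(res)
}

#' Summary report of a completed run
#'
#' Aggregates per-class map counts, CSPA/CD/pathway enrichment (every
#' percentage stored with its numerator and denominator), and PRM ratios
#' into `report.json` plus a short human-readable summary.
#'
#' @param dir Run directory with the map (and optionally PRM) artifacts.
#' @return The report list, invisibly.
#' @export
build_report <- function(dir) {
  p <- require_artifact(dir, "surface_map.tsv", "run_map")
  map <- utils::read.delim(p, stringsAsFactors = FALSE)
  ann <- read_run_annotations(dir)
  report <- list(n_map_entries = nrow(map))
  for (cls in c("UNIQUE_KRAS", "UP_KRAS"))
    report[[paste0("n_", tolower(cls))]] <- sum(map$class == cls)
  if (nrow(map) > 0) {
    cspa <- enrichment_report(sum(map$in_cspa), nrow(map))
    cd <- enrichment_report(sum(map$is_cd), nrow(map),
                            baseline_fraction =
                              if (!is.null(ann$cd))
                                ann$cd$baseline_fraction else NULL)
    report$cspa <- unclass(cspa)
    report$cd <- unclass(cd)
    per_class <- glyco_fraction_of_map(map)
    report$cspa_by_class <- lapply(per_class, unclass)
    if (!is.null(ann$pathway))
      report$pathway <- pathway_coverage(map$accession, ann$pathway)
  }
  prm_p <- artifact(dir, "prm_ratios.tsv")
  if (file.exists(prm_p)) {
    prm <- utils::read.delim(prm_p, stringsAsFactors = FALSE)
    report$prm <- prm
    if (all(CONDITIONS %in% prm$condition)) {
      r <- prm$ratio[match(CONDITIONS, prm$condition)]
      report$prm_kras_over_ev <- r[1] / r[2]
    }
  }
  write_json(report, artifact(dir, "report.json"))
  lines <- c(
    sprintf("Non-redundant KRas surface map: %d entries (%d unique, %d upregulated)",
            report$n_map_entries, report$n_unique_kras, report$n_up_kras),
    if (!is.null(report$cspa))
      sprintf("CSPA-annotated: %d of %d (%s%%)", report$cspa$n_annotated,
              report$cspa$n_total, format(report$cspa$percent)),
    if (!is.null(report$cd) && !is.na(report$cd$fold))
      sprintf("CD molecules: %d of %d (%s%%), %d-fold over baseline",
              report$cd$n_annotated, report$cd$n_total,
              format(report$cd$percent), fold_label(report$cd$fold)),
    if (!is.null(report$pathway))
      sprintf("Pathway coverage: %d hits (%s%%)", report$pathway$n_hit,
              format(report$pathway$percent)),
    if (!is.null(report$prm_kras_over_ev))
      sprintf("PRM KRas/EV fold: %.3f", report$prm_kras_over_ev))
  writeLines(lines, artifact(dir, "report.txt"))
  message(paste(lines, collapse = "\n"))
  invisible(report)
}
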