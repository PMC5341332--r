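#' Read a protein database from FASTA
#'
#' Reads a (possibly wrapped) FASTA protein database. Decoy entries are
#' recognized by an accession prefix; sequences are upper-cased and trailing
#' stop characters (`*`) are stripped. Gene symbols are picked up from a
#' `GN=SYMBOL` token in the header description when present.
#'
#' @param path Path to a FASTA file.
#' @param decoy_prefix Accession prefix marking decoy entries (default
#'   `"DECOY_"`).
#' @return A data.frame with columns `accession`, `gene_symbol` (NA when the
#'   header carries none), `sequence` and `is_decoy`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 GN=GENE1", "MKNGSR", ">DECOY_P1", "RSGNKM"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, decoy_prefix = "DECOY_") {
  stopifnot(file.exists(path))
  raw <- readLines(path, warn = FALSE)
  if (length(raw) == 0L || !any(startsWith(raw, ">"))) {
    warning("FASTA file '", path, "' contains no sequence entries")
    return(data.frame(accession = character(), gene_symbol = character(),
                      sequence = character(), is_decoy = logical(),
                      stringsAsFactors = FALSE))
  }
  aa <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("FASTA parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  headers <- names(aa)
  accession <- sub("\\s.*$", "", headers)
  if (any(accession == ""))
    stop("FASTA parse error: empty accession in entry ",
         which(accession == "")[1], call. = FALSE)
  if (anyDuplicated(accession))
    stop("FASTA parse error: duplicate accession '",
         accession[duplicated(accession)][1], "'", call. = FALSE)
  gene_symbol <- rep(NA_character_, length(headers))
  gn <- regmatches(headers, regexpr("GN=[^ ]+", headers))
  has_gn <- grepl("GN=[^ ]+", headers)
  gene_symbol[has_gn] <- sub("^GN=", "", gn)
  sequence <- toupper(gsub("\\*", "", as.character(aa)))
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", sequence)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("FASTA parse error: illegal residue character in entry ", i,
         " ('", accession[i], "')", call. = FALSE)
  }
  if (any(nchar(sequence) == 0L))
    stop("FASTA parse error: empty sequence for '",
         accession[nchar(sequence) == 0L][1], "'", call. = FALSE)
  data.frame(accession = accession, gene_symbol = gene_symbol,
             sequence = sequence,
             is_decoy = startsWith(accession, decoy_prefix),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a protein database to FASTA
#'
#' Inverse of [read_fasta()]: emits one unwrapped record per row, with a
#' `GN=` token when a gene symbol is present.
#'
#' @param proteins data.frame as returned by [read_fasta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  stopifnot(is.data.frame(proteins),
            all(c("accession", "sequence") %in% names(proteins)))
  gs <- proteins$gene_symbol %||% rep(NA_character_, nrow(proteins))
  hdr <- ifelse(is.na(gs), paste0(">", proteins$accession),
                paste0(">", proteins$accession, " GN=", gs))
  writeLines(rbind(hdr, proteins$sequence), path)
  invisible(path)
}

#' Parse modification strings
#'
#' Modifications travel through PSM tables in a compact
#' `"pos:name:delta;pos:name:delta"` dialect (1-based position within the
#' peptide, signed delta mass in Da).
#'
#' @param x Character vector of modification strings; `""` or `NA` means no
#'   modification.
#' @return A list (one element per input string) of data.frames with columns
#'   `position` (integer), `name`, `delta` (numeric).
#' @examples
#' parse_modifications(c("2:Deamidated:0.984", ""))
#' @export
parse_modifications <- function(x) {
  empty <- data.frame(position = integer(), name = character(),
                      delta = numeric(), stringsAsFactors = FALSE)
  lapply(seq_along(x), function(i) {
    s <- x[[i]]
    if (is.na(s) || !nzchar(s)) return(empty)
    toks <- strsplit(s, ";", fixed = TRUE)[[1]]
    parts <- strsplit(toks, ":", fixed = TRUE)
    ok <- vapply(parts, length, 1L) == 3L
    pos <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    delta <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3L)))
    if (!all(ok) || anyNA(pos) || anyNA(delta))
      stop("unparsable modification token in element ", i, ": '", s, "'",
           call. = FALSE)
    data.frame(position = pos, name = vapply(parts, `[`, "", 2L),
               delta = delta, stringsAsFactors = FALSE)
  })
}

format_modifications <- function(mods) {
  vapply(mods, function(m) {
    if (nrow(m) == 0L) return("")
    paste(sprintf("%d:%s:%.4g", m$position, m$name, m$delta), collapse = ";")
  }, "")
}

PSM_REQUIRED <- c("peptide", "modifications", "proteins", "score",
                  "charge", "condition", "replicate")

#' Read a scored PSM table
#'
#' Reads a tab-separated peptide-spectrum-match table with required columns
#' `peptide`, `modifications`, `proteins` (semicolon-joined accessions),
#' `score`, `charge`, `condition`, `replicate`, and optional columns `q_value`
#' and `is_decoy`. When `is_decoy` is absent it is derived from the decoy
#' accession prefix: a PSM is a decoy iff *all* of its mapped accessions are
#' decoys. Modification tokens are validated on read; rows are preserved in
#' file order.
#'
#' @param path Path to the TSV file.
#' @param decoy_prefix Accession prefix marking decoy proteins.
#' @return A data.frame of PSMs; `q_value` is `NA` where not yet estimated.
#' @seealso [estimate_qvalues()] to fill missing q-values.
#' @export
read_psm_table <- function(path, decoy_prefix = "DECOY_") {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = "NA")
  missing_cols <- setdiff(PSM_REQUIRED, names(df))
  if (length(missing_cols))
    stop("PSM table schema error: missing required column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df$modifications <- ifelse(is.na(df$modifications), "",
                             as.character(df$modifications))
  # validates tokens; errors carry the row index
  for (i in seq_len(nrow(df))) {
    tryCatch(parse_modifications(df$modifications[i]),
             error = function(e) stop("PSM table row ", i, ": ",
                                      conditionMessage(e), call. = FALSE))
  }
  if (!"q_value" %in% names(df)) df$q_value <- NA_real_
  df$q_value <- as.numeric(df$q_value)
  if (any(!is.na(df$q_value) & (df$q_value < 0 | df$q_value > 1)))
    stop("PSM table schema error: q_value outside [0,1]", call. = FALSE)
  if (!"is_decoy" %in% names(df)) {
    accs <- strsplit(df$proteins, ";", fixed = TRUE)
    df$is_decoy <- vapply(accs, function(a) all(startsWith(a, decoy_prefix)),
                          logical(1))
  } else {
    df$is_decoy <- as.logical(df$is_decoy)
  }
  df
}

#' Write a PSM table
#'
#' @param psms PSM data.frame (see [read_psm_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  cols <- c(PSM_REQUIRED, intersect(c("q_value", "is_decoy"), names(psms)))
  utils::write.table(psms[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an annotation reference list
#'
#' One accession per line; blank lines and `#` comments are ignored;
#' duplicates are collapsed. An empty resulting set is an error — an empty
#' reference list is always a mistake.
#'
#' @param path Path to the list file.
#' @param name Name of the annotation (e.g. `"CSPA"`, `"CD"`, `"RAS2"`).
#' @param baseline_fraction Optional whole-proteome baseline fraction in
#'   (0, 1] (e.g. 0.02 for CD molecules) used by [fold_enrichment()].
#' @return An object of class `annotation_set`: a list with `name`,
#'   `accessions` (character) and `baseline_fraction`.
#' @export
read_annotation_list <- function(path, name, baseline_fraction = NULL) {
  stopifnot(file.exists(path))
  x <- readLines(path, warn = FALSE)
  x <- trimws(sub("#.*$", "", x))
  x <- unique(x[nzchar(x)])
  if (length(x) == 0L)
    stop("annotation list '", path, "' is empty", call. = FALSE)
  message("annotation '", name, "': ", length(x), " accessions")
  annotation_set(name, x, baseline_fraction)
}

#' Construct an annotation set
#'
#' @param name Annotation name.
#' @param accessions Character vector of accessions (deduplicated).
#' @param baseline_fraction Optional baseline fraction in (0, 1].
#' @return An `annotation_set` object.
#' @export
annotation_set <- function(name, accessions, baseline_fraction = NULL) {
  accessions <- unique(as.character(accessions))
  stopifnot(length(accessions) > 0L)
  if (!is.null(baseline_fraction))
    stopifnot(baseline_fraction > 0, baseline_fraction <= 1)
  structure(list(name = name, accessions = accessions,
                 baseline_fraction = baseline_fraction),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("Annotation set '", x$name, "': ", length(x$accessions),
      " accessions", sep = "")
  if (!is.null(x$baseline_fraction))
    cat(" (baseline ", 100 * x$baseline_fraction, "%)", sep = "")
  cat("\n")
  invisible(x)
}

#' Read an MGF peak-list file
#'
#' Minimal Mascot Generic Format reader for PRM runs: each `BEGIN IONS` block
#' yields one MS2 scan with its title, retention time (`RTINSECONDS`),
#' precursor m/z (`PEPMASS`, first number) and peak list. Peaks are returned
#' sorted ascending by m/z.
#'
#' @param path Path to the MGF file.
#' @return A list of scans, each a list with `title`, `scan_time` (s),
#'   `precursor_mz` (Th), `mz` and `intensity` (parallel numeric vectors).
#'   Scans are ordered by `scan_time`.
#' @export
read_mgf <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends) || any(ends < starts))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in '", path, "'",
         call. = FALSE)
  scans <- mapply(function(s, e) {
    blk <- lines[(s + 1L):(e - 1L)]
    kv <- grepl("=", blk, fixed = TRUE)
    keys <- sub("=.*$", "", blk[kv])
    vals <- sub("^[^=]*=", "", blk[kv])
    peaks <- blk[!kv & nzchar(blk)]
    pm <- do.call(rbind, lapply(strsplit(peaks, "[ \t]+"), function(p)
      as.numeric(p[1:2])))
    if (is.null(pm)) pm <- matrix(numeric(), ncol = 2)
    o <- order(pm[, 1])
    list(
      title = if ("TITLE" %in% keys) vals[match("TITLE", keys)] else NA_character_,
      scan_time = if ("RTINSECONDS" %in% keys)
        as.numeric(vals[match("RTINSECONDS", keys)]) else NA_real_,
      precursor_mz = if ("PEPMASS" %in% keys)
        as.numeric(strsplit(vals[match("PEPMASS", keys)], "[ \t]+")[[1]][1])
      else NA_real_,
      mz = pm[o, 1], intensity = pm[o, 2]
    )
  }, starts, ends, SIMPLIFY = FALSE)
  scans[order(vapply(scans, `[[`, 0, "scan_time"))]
}

#' Write spectra to an MGF file
#'
#' @param scans List of scans as returned by [read_mgf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(scans, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sc in scans) {
    writeLines(c(
      "BEGIN IONS",
      if (!is.null(sc$title) && !is.na(sc$title)) paste0("TITLE=", sc$title),
      sprintf("RTINSECONDS=%.4f", sc$scan_time),
      sprintf("PEPMASS=%.6f", sc$precursor_mz),
      if (length(sc$mz)) sprintf("%.6f %.6f", sc$mz, sc$intensity),
      "END IONS"
    ), con)
  }
  invisible(path)
}
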