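#' Filtering parameters for the surface-capture (CSC) arm
#'
#' @param peptide_fdr_max Maximum peptide q-value retained (default 0.01).
#' @param deamidation_delta Deamidation mass shift in Da (default +0.984,
#'   the PNGase F Asn->Asp conversion mark).
#' @param deamidation_tolerance Matching tolerance around the deamidation
#'   delta, Da (default 0.01).
#' @param min_psm Minimum PSMs per protein group per condition (default 2):
#'   single-PSM identifications are discarded.
#' @param require_sequon Keep only PSMs bearing at least one sequon-valid
#'   deamidation site (default TRUE; the CSC arm).
#' @param sequon_exclude_proline Disallow proline at the x position of NxS/T
#'   (default FALSE: the motif as written allows any x).
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(peptide_fdr_max = 0.01,
                          deamidation_delta = 0.984,
                          deamidation_tolerance = 0.01,
                          min_psm = 2L,
                          require_sequon = TRUE,
                          sequon_exclude_proline = FALSE) {
  stopifnot(peptide_fdr_max > 0, peptide_fdr_max < 1, min_psm >= 1)
  structure(list(peptide_fdr_max = peptide_fdr_max,
                 deamidation_delta = deamidation_delta,
                 deamidation_tolerance = deamidation_tolerance,
                 min_psm = as.integer(min_psm),
                 require_sequon = require_sequon,
                 sequon_exclude_proline = sequon_exclude_proline),
            class = "filter_params")
}

#' Check the N-glycosylation sequon at a protein position
#'
#' The obligatory N-glycosylation acceptor motif is N-x-S/T: an asparagine
#' followed two residues later by serine or threonine. Optionally proline is
#' disallowed at the x position (biologically, NPS/NPT is essentially never
#' glycosylated).
#'
#' @param sequence Protein sequence string.
#' @param n_pos 1-based position of the asparagine; the residue there must be
#'   `N` (contract violation otherwise).
#' @param exclude_proline If TRUE, `N-P-S/T` fails the check.
#' @return TRUE iff the motif holds at `n_pos`.
#' @examples
#' check_sequon("MKLNGSR", 4)           # NGS -> TRUE
#' check_sequon("MKLNPSR", 4)           # NPS -> TRUE (x unrestricted)
#' check_sequon("MKLNPSR", 4, TRUE)     # FALSE with proline exclusion
#' @export
check_sequon <- function(sequence, n_pos, exclude_proline = FALSE) {
  n <- nchar(sequence)
  if (n_pos < 1L || n_pos > n)
    stop("n_pos ", n_pos, " out of range for sequence of length ", n,
         call. = FALSE)
  if (substr(sequence, n_pos, n_pos) != "N")
    stop("residue at position ", n_pos, " is not 'N'", call. = FALSE)
  if (n_pos + 2L > n) return(FALSE)
  third <- substr(sequence, n_pos + 2L, n_pos + 2L)
  if (!third %in% c("S", "T")) return(FALSE)
  if (exclude_proline && substr(sequence, n_pos + 1L, n_pos + 1L) == "P")
    return(FALSE)
  TRUE
}

#' Map deamidated asparagines to protein glycosite coordinates
#'
#' For each modification on the PSM whose delta matches the deamidation shift
#' (within tolerance) and whose peptide residue is `N`, the site is projected
#' onto every mapped protein via the leftmost occurrence of the peptide, and
#' the NxS/T sequon is checked at the protein coordinate.
#'
#' @param psm A single-row PSM data.frame (or list) with fields `peptide`,
#'   `modifications` (dialect string) and `proteins` (semicolon-joined).
#' @param db Protein database data.frame from [read_fasta()].
#' @param params [filter_params()].
#' @return A data.frame of glycosite evidence: `accession`,
#'   `protein_position` (1-based), `peptide`, `sequon_valid`, `motif_window`.
#' @export
map_deamidation_sites <- function(psm, db, params = filter_params()) {
  peptide <- psm$peptide[[1]]
  mods <- parse_modifications(psm$modifications[[1]])[[1]]
  accs <- strsplit(psm$proteins[[1]], ";", fixed = TRUE)[[1]]
  out <- data.frame(accession = character(), protein_position = integer(),
                    peptide = character(), sequon_valid = logical(),
                    motif_window = character(), stringsAsFactors = FALSE)
  if (nrow(mods) == 0L) return(out)
  deam <- mods[abs(mods$delta - params$deamidation_delta) <=
                 params$deamidation_tolerance, , drop = FALSE]
  if (nrow(deam) == 0L) return(out)
  # only asparagines can carry the PNGase F mark
  isN <- substring(peptide, deam$position, deam$position) == "N"
  deam <- deam[isN, , drop = FALSE]
  if (nrow(deam) == 0L) return(out)
  seqs <- db$sequence[match(accs, db$accession)]
  for (k in seq_along(accs)) {
    if (is.na(seqs[k]))
      stop("accession '", accs[k], "' not present in database", call. = FALSE)
    at <- regexpr(peptide, seqs[k], fixed = TRUE)[[1]]
    if (at < 0L)
      stop("peptide '", peptide, "' not found in protein '", accs[k], "'",
           call. = FALSE)
    pos <- at + deam$position - 1L
    win <- substring(seqs[k], pos, pmin(pos + 2L, nchar(seqs[k])))
    valid <- vapply(pos, function(p)
      check_sequon(seqs[k], p, params$sequon_exclude_proline), logical(1))
    out <- rbind(out, data.frame(
      accession = accs[k], protein_position = as.integer(pos),
      peptide = peptide, sequon_valid = valid, motif_window = win,
      stringsAsFactors = FALSE))
  }
  out
}

#' Parsimony protein grouping by greedy set cover
#'
#' Repeatedly picks the accession explaining the most not-yet-explained
#' peptides (ties broken lexicographically by accession) and assigns those
#' peptides' PSMs to it as a group lead. Accessions never selected, all of
#' whose peptides were assigned to a single lead, are reported as members of
#' that lead's group. Every input PSM is assigned to exactly one group.
#'
#' @param psms PSM data.frame (`peptide`, `proteins`); expected to be already
#'   FDR-filtered targets.
#' @return A data.frame with one row per group: `lead_accession`, `members`
#'   (semicolon-joined, possibly empty), `peptides` (semicolon-joined),
#'   `n_psms`. The per-PSM lead assignment is attached as attribute
#'   `"assignment"` (character vector parallel to the input rows).
#' @export
group_proteins <- function(psms) {
  empty <- data.frame(lead_accession = character(), members = character(),
                      peptides = character(), n_psms = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(psms) == 0L) return(empty)
  pep_accs <- strsplit(psms$proteins, ";", fixed = TRUE)
  edges <- unique(data.frame(
    peptide = rep(psms$peptide, lengths(pep_accs)),
    accession = unlist(pep_accs), stringsAsFactors = FALSE))
  acc2peps <- split(edges$peptide, edges$accession)
  uncovered <- unique(psms$peptide)
  pep_lead <- character(0)
  leads <- character(0)
  lead_peps <- list()
  while (length(uncovered) > 0L) {
    gain <- vapply(acc2peps, function(p) sum(p %in% uncovered), 0L)
    best <- max(gain)
    lead <- sort(names(acc2peps)[gain == best])[1]
    got <- intersect(acc2peps[[lead]], uncovered)
    leads <- c(leads, lead)
    lead_peps[[lead]] <- got
    pep_lead[got] <- lead
    uncovered <- setdiff(uncovered, got)
  }
  members <- lapply(leads, function(l) character(0))
  names(members) <- leads
  for (acc in setdiff(names(acc2peps), leads)) {
    covering <- unique(pep_lead[acc2peps[[acc]]])
    if (length(covering) == 1L)
      members[[covering]] <- c(members[[covering]], acc)
  }
  assignment <- pep_lead[psms$peptide]
  res <- data.frame(
    lead_accession = leads,
    members = vapply(members[leads], function(m)
      paste(sort(m), collapse = ";"), ""),
    peptides = vapply(lead_peps[leads], function(p)
      paste(sort(p), collapse = ";"), ""),
    n_psms = as.integer(vapply(leads, function(l)
      sum(assignment == l), 0L)),
    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[order(res$lead_accession), , drop = FALSE]
  row.names(res) <- NULL
  attr(res, "assignment") <- unname(assignment)
  res
}

# shared CSC/SGM arm pipeline: q-values -> FDR gate -> (sequon gate) ->
# per-condition grouping -> min-PSM gate
run_arm <- function(psms, db = NULL, params = filter_params()) {
  stages <- list(input = nrow(psms))
  if (all(is.na(psms$q_value))) psms <- estimate_qvalues(psms)
  keep <- !psms$is_decoy & !is.na(psms$q_value) &
    psms$q_value <= params$peptide_fdr_max
  psms <- psms[keep, , drop = FALSE]
  stages$fdr_pass <- nrow(psms)
  sites <- NULL
  if (isTRUE(params$require_sequon)) {
    if (is.null(db))
      stop("a protein database is required for sequon validation",
           call. = FALSE)
    # identical (peptide, modifications, proteins) triples map identically:
    # compute each distinct triple once
    key <- paste(psms$peptide, psms$modifications, psms$proteins,
                 sep = "\r")
    first <- !duplicated(key)
    uniq_sites <- lapply(which(first), function(i)
      map_deamidation_sites(psms[i, ], db, params))
    sites <- uniq_sites[match(key, key[first])]
    has_valid <- vapply(sites, function(s)
      nrow(s) > 0L && any(s$sequon_valid), logical(1))
    psms <- psms[has_valid, , drop = FALSE]
    sites <- sites[has_valid]
    stages$sequon_pass <- nrow(psms)
  }
  conditions <- intersect(CONDITIONS, unique(psms$condition))
  groups <- list()
  for (cond in conditions) {
    in_cond <- psms$condition == cond
    g <- group_proteins(psms[in_cond, , drop = FALSE])
    if (!is.null(sites)) {
      assignment <- attr(g, "assignment")
      cond_sites <- lapply(seq_along(assignment), function(i) {
        s <- sites[in_cond][[i]]
        s <- s[s$sequon_valid, , drop = FALSE]
        if (nrow(s) == 0L) return(NULL)
        s$lead <- assignment[i]
        s
      })
      cond_sites <- do.call(rbind, cond_sites)
      g$glycosites <- vapply(g$lead_accession, function(l) {
        if (is.null(cond_sites)) return("")
        s <- cond_sites[cond_sites$lead == l, , drop = FALSE]
        # report sites only on accessions belonging to this group
        in_group <- c(l, strsplit(g$members[g$lead_accession == l],
                                  ";")[[1]])
        s <- s[s$accession %in% in_group, , drop = FALSE]
        if (nrow(s) == 0L) return("")
        paste(sort(unique(sprintf("%s:N%d", s$accession,
                                  s$protein_position))), collapse = ";")
      }, "")
      g$n_glycosites <- vapply(strsplit(g$glycosites, ";"), function(x)
        sum(nzchar(x)), 0L)
    }
    g <- g[g$n_psms >= params$min_psm, , drop = FALSE]
    attr(g, "assignment") <- NULL
    row.names(g) <- NULL
    groups[[cond]] <- g
  }
  stages$grouped <- sum(vapply(groups, nrow, 0L))
  structure(groups, stages = stages, params = params)
}

#' Run the cell-surface capture (CSC) glycoproteomics arm
#'
#' Fixed pipeline order: estimate q-values (if absent) -> keep target PSMs at
#' q <= `peptide_fdr_max` -> keep PSMs bearing at least one sequon-valid
#' deamidation site -> parsimony grouping per condition -> drop groups with
#' fewer than `min_psm` PSMs. Each retained group carries its validated
#' glycosites as `"ACCESSION:N<position>"` strings.
#'
#' @param psms PSM data.frame ([read_psm_table()]).
#' @param db Protein database ([read_fasta()]).
#' @param params [filter_params()].
#' @return Named list (one element per condition) of group data.frames, with
#'   attribute `"stages"` recording counts at each filter stage.
#' @export
csc_glycoproteome <- function(psms, db, params = filter_params()) {
  run_arm(psms, db, params)
}

#' Run the shotgun membrane (SGM) proteomics arm
#'
#' Same filtering and grouping as [csc_glycoproteome()] but without the
#' glycosite/sequon requirement: q-value gate, parsimony grouping per
#' condition, minimum-PSM gate.
#'
#' @param psms PSM data.frame.
#' @param params [filter_params()]; `require_sequon` is forced off.
#' @return Named list of group data.frames per condition, with `"stages"`.
#' @export
sgm_proteome <- function(psms, params = filter_params()) {
  params$require_sequon <- FALSE
  run_arm(psms, db = NULL, params)
}
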