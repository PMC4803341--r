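# Decoy/contaminant flags honour both the MaxQuant marker columns ("+") and
# the accession-prefix conventions (REV__ / CON__), which differ between
# MaxQuant versions; the contaminant marker column is "Potential contaminant"
# in 1.4+ and "Contaminant" in earlier releases.

flag_col <- function(df, titles) {
  for (t in titles) if (!is.null(df[[t]])) return(df[[t]] == "+")
  rep(FALSE, nrow(df))
}

has_prefix <- function(ids, prefix) {
  vapply(ids, function(x) any(startsWith(split_ids(x), prefix)), logical(1),
         USE.NAMES = FALSE)
}

#' Flag reverse (decoy) rows of a MaxQuant table
#' @param df A table read by [read_table()] with a `Reverse` column and/or
#'   an accession column carrying `REV__` prefixes.
#' @param id_col Accession column consulted for the `REV__` prefix.
#' @return Logical vector.
#' @export
is_reverse_row <- function(df, id_col = "Protein IDs") {
  out <- flag_col(df, "Reverse")
  if (!is.null(df[[id_col]])) out <- out | has_prefix(df[[id_col]], "REV__")
  out
}

#' Flag contaminant rows of a MaxQuant table
#' @inheritParams is_reverse_row
#' @return Logical vector.
#' @export
is_contaminant_row <- function(df, id_col = "Protein IDs") {
  out <- flag_col(df, c("Potential contaminant", "Contaminant"))
  if (!is.null(df[[id_col]])) out <- out | has_prefix(df[[id_col]], "CON__")
  out
}

#' Remove decoy and contaminant rows
#'
#' The first filtering step of the protein report: reverse-database hits and
#' known contaminants are dropped; relative row order is preserved.
#'
#' @param df A table read by [read_table()].
#' @param id_col Accession column consulted for prefix conventions.
#' @return `df` restricted to rows with both flags false.
#' @export
filter_decoys_contaminants <- function(df, id_col = "Protein IDs") {
  drop <- is_reverse_row(df, id_col) | is_contaminant_row(df, id_col)
  if (any(drop))
    mr_log_info(sprintf("%s: removed %d reverse/contaminant row(s)",
                        attr(df, "table_name") %||% "table", sum(drop)))
  out <- df[!drop, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("table_name", "source_path")) attr(out, a) <- attr(df, a)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Minimize a protein group to its best-supported accessions
#'
#' A protein group lists every accession compatible with its peptides. For
#' minimum reporting only the accessions mapped by the largest number of
#' unique peptides — and, among those, the largest number of total peptides —
#' are retained, in their original order. Ties keep all tied accessions; the
#' first retained accession is the lead.
#'
#' @param accessions Ordered character vector of the group's accessions.
#' @param unique_counts,total_counts Per-accession non-negative integer
#'   counts, aligned with `accessions`.
#' @return Integer indices (into `accessions`) of the retained accessions.
#' @export
minimize_group <- function(accessions, unique_counts, total_counts) {
  n <- length(accessions)
  if (length(unique_counts) != n || length(total_counts) != n ||
      anyNA(unique_counts) || anyNA(total_counts)) {
    mr_log_warn("per-accession peptide counts missing or misaligned; group kept in full")
    return(seq_len(n))
  }
  top_u <- which(unique_counts == max(unique_counts))
  top_u[total_counts[top_u] == max(total_counts[top_u])]
}

#' Build the filtered, minimized and annotated protein-group report
#'
#' Applies [filter_decoys_contaminants()], minimizes every group via
#' [minimize_group()] (using MaxQuant's per-accession `Peptide counts
#' (unique)` / `Peptide counts (all)` columns), and annotates the lead
#' accession with gene and description from the sequence catalog. Adds the
#' columns `Retained protein IDs`, `Lead protein`, `Gene name` and
#' `Protein description`.
#'
#' @param groups The `proteinGroups.txt` table ([read_table()]).
#' @param catalog A [read_fasta()] catalog.
#' @return The reported protein-group data frame.
#' @export
build_protein_report <- function(groups, catalog) {
  out <- filter_decoys_contaminants(groups, "Protein IDs")
  n <- nrow(out)
  retained <- character(n); lead <- character(n)
  for (i in seq_len(n)) {
    accs <- split_ids(out[["Protein IDs"]][i])
    uc <- split_nums(out[["Peptide counts (unique)"]][i] %||% NA_character_)
    tc <- split_nums(out[["Peptide counts (all)"]][i] %||% NA_character_)
    if (length(uc) != length(accs)) uc <- rep(NA_real_, length(accs))
    if (length(tc) != length(accs)) tc <- rep(NA_real_, length(accs))
    keep <- minimize_group(accs, uc, tc)
    retained[i] <- paste(accs[keep], collapse = ";")
    lead[i] <- accs[keep][1]
  }
  out[["Retained protein IDs"]] <- retained
  out[["Lead protein"]] <- lead
  ann <- catalog_get(catalog, lead)
  missing <- is.na(ann$sequence)
  if (any(missing) && n > 0)
    mr_log_warn(sprintf("lead accession(s) absent from sequence catalog: %s",
                        paste(unique(lead[missing]), collapse = ", ")))
  out[["Gene name"]] <- ifelse(missing, "", ann$gene)
  out[["Protein description"]] <- ifelse(missing, "", ann$description)
  out
}

#' Resolve the best protein group for a peptide or site
#'
#' When a peptide or site maps to several protein groups, the group with the
#' best (largest) MaxQuant score is chosen; ties go to the group appearing
#' first in the reported protein table. Candidates not present in the
#' reported table (removed as decoy/contaminant) are ignored; if none
#' survive, `NA` is returned and the event is logged so the entity can be
#' dropped from reporting.
#'
#' @param candidate_ids Character vector of candidate group ids.
#' @param groups The reported protein-group table (must have `id` and
#'   `Score` columns).
#' @return The chosen group id, or `NA_character_`.
#' @export
resolve_best_group <- function(candidate_ids, groups) {
  idx <- match(candidate_ids, groups[["id"]])
  ok <- !is.na(idx)
  if (!any(ok)) {
    mr_log_info(sprintf(
      "entity mapped only to filtered-out group(s) [%s]; dropped",
      paste(candidate_ids, collapse = ";")))
    return(NA_character_)
  }
  idx <- idx[ok]
  scores <- num_or_na(groups[["Score"]][idx])
  scores[is.na(scores)] <- -Inf
  best <- idx[order(-scores, idx)][1]  # max score, earlier row wins ties
  groups[["id"]][best]
}
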