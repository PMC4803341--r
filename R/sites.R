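#' Extract the sequence window around a site
#'
#' Returns `2*flank + 1` residues centred on the site, padded with `"_"`
#' (the MaxQuant convention) where the window runs past a protein terminus.
#'
#' @param sequence Protein sequence (amino-acid string).
#' @param position 1-based residue index of the site.
#' @param flank Residues reported each side (>= 0).
#' @param accession Optional accession used in the error message.
#' @return Window string of length `2*flank + 1`.
#' @export
extract_sequence_window <- function(sequence, position, flank,
                                    accession = NULL) {
  len <- nchar(sequence)
  if (is.na(position) || position < 1L || position > len)
    stop("site position ", position, " outside sequence",
         if (!is.null(accession)) paste0(" of ", accession),
         " (length ", len, ")")
  if (flank < 0L) stop("flank must be >= 0")
  lo <- position - flank
  hi <- position + flank
  core <- substr(sequence, max(lo, 1L), min(hi, len))
  paste0(strrep("_", max(0L, 1L - lo)), core, strrep("_", max(0L, hi - len)))
}

#' Classify a site as specific or ambiguous
#'
#' A site is specific when its localization probability is strictly larger
#' than the threshold. An absent probability (`NA`) also counts as specific:
#' it arises for sites whose position is fixed by the peptide terminus, e.g.
#' protein N-terminal modifications.
#'
#' @param localization_probability Numeric in `[0, 1]`, or `NA`.
#' @param threshold Threshold in `[0, 1]` (default 0.5).
#' @return `"specific"` or `"ambiguous"` (vectorized).
#' @export
classify_site <- function(localization_probability, threshold = 0.5) {
  p <- as.numeric(localization_probability)
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("localization probability outside [0, 1]")
  ifelse(is.na(p) | p > threshold, "specific", "ambiguous")
}

site_columns <- c("PTM", "Protein", "Position", "Amino acid",
                  "Localization prob", "Site class", "Sequence window",
                  "Sequence", "Score", "Protein group IDs", "MS/MS IDs")

empty_site_table <- function() {
  df <- as.data.frame(setNames(rep(list(character()), length(site_columns)),
                               site_columns), check.names = FALSE)
  df
}

# first parenthesized number in a MaxQuant probability string, e.g.
# "A(0.9)MKDE..." -> 0.9; NA when absent
prob_from_string <- function(x) {
  m <- regmatches(x, regexec("\\(([0-9.]+)\\)", x))
  vapply(m, function(g) if (length(g) >= 2) as.numeric(g[2]) else NA_real_,
         numeric(1))
}

# locate a peptide at the protein N-terminus: position 1 (full start) or
# position 2 (initiator-Met cleaved); internal matches do not count
nterm_position <- function(peptide, sequence, ile_eq_leu = FALSE) {
  p <- il_key(peptide, ile_eq_leu)
  s <- il_key(sequence, ile_eq_leu)
  if (startsWith(s, p)) return(1L)
  if (startsWith(s, "M") && startsWith(substr(s, 2L, nchar(s)), p)) return(2L)
  NA_integer_
}

#' Detect protein N-terminal modification sites from msms.txt
#'
#' MaxQuant reports residue PTMs in dedicated site tables but not protein
#' N-terminal modifications; those are recognized here from the MS/MS scans.
#' A scan supports an N-terminal site when its `Modifications` string carries
#' the configured N-terminal PTM name and its peptide sits at protein
#' position 1, or at position 2 of a Met-initiated protein
#' (initiator-methionine cleavage). The protein group is resolved via
#' [resolve_best_group()] and the window is taken from the best-scored
#' group's lead accession. A localization probability is read from the
#' `"<PTM> Probabilities"` column when present (first parenthesized value);
#' absent probabilities count as specific.
#'
#' @param msms The `msms.txt` table.
#' @param groups The reported protein-group table ([build_protein_report()]).
#' @param catalog A [read_fasta()] catalog.
#' @param config A [reporting_config()]; `nterm_ptm_names(config)` selects
#'   the modification(s).
#' @param ptm_name Single N-terminal PTM name; defaults to the first
#'   configured one.
#' @return A site-table data frame (one row per distinct protein/position,
#'   supporting scan ids `;`-joined).
#' @export
detect_nterm_sites <- function(msms, groups, catalog, config,
                               ptm_name = nterm_ptm_names(config)[1]) {
  if (is.na(ptm_name) || !length(ptm_name)) return(empty_site_table())
  hit <- grepl(ptm_name, msms[["Modifications"]], fixed = TRUE)
  if (!any(hit)) return(empty_site_table())
  rows <- msms[hit, , drop = FALSE]
  prob_col <- paste0(ptm_name, " Probabilities")
  probs <- if (!is.null(rows[[prob_col]])) prob_from_string(rows[[prob_col]])
           else rep(NA_real_, nrow(rows))
  recs <- list()
  for (i in seq_len(nrow(rows))) {
    gid <- resolve_best_group(split_ids(rows[["Protein group IDs"]][i]), groups)
    if (is.na(gid)) next
    grow <- groups[match(gid, groups[["id"]]), ]
    pep <- rows[["Sequence"]][i]
    pos <- NA_integer_; acc <- NA_character_; seqs <- NA_character_
    for (a in split_ids(grow[["Retained protein IDs"]])) {
      entry <- catalog_get(catalog, a)
      if (is.na(entry$sequence)) next
      p <- nterm_position(pep, entry$sequence, config$ile_eq_leu)
      if (!is.na(p)) { pos <- p; acc <- a; seqs <- entry$sequence; break }
    }
    if (is.na(pos)) {
      mr_log_warn(sprintf(
        "N-terminal scan %s: peptide '%s' not at the start of any retained accession; skipped",
        rows[["id"]][i] %||% "?", pep))
      next
    }
    key <- paste(acc, pos, sep = "@")
    prev <- recs[[key]]
    recs[[key]] <- list(
      accession = acc, position = pos, sequence = seqs,
      peptide = pep, group = gid,
      prob = if (is.null(prev)) probs[i] else max(prev$prob, probs[i], na.rm = !all(is.na(c(prev$prob, probs[i])))),
      score = max(if (is.null(prev)) -Inf else prev$score,
                  num_or_na(rows[["Score"]][i]), na.rm = TRUE),
      scans = c(if (!is.null(prev)) prev$scans, rows[["id"]][i]))
  }
  if (!length(recs)) return(empty_site_table())
  df <- data.frame(
    "PTM" = ptm_name,
    "Protein" = vapply(recs, `[[`, character(1), "accession"),
    "Position" = as.character(vapply(recs, `[[`, integer(1), "position")),
    "Amino acid" = vapply(recs, function(r)
      substr(r$sequence, r$position, r$position), character(1)),
    "Localization prob" = vapply(recs, function(r)
      if (is.na(r$prob)) "" else format(r$prob), character(1)),
    "Site class" = vapply(recs, function(r)
      classify_site(r$prob, config$loc_prob_threshold), character(1)),
    "Sequence window" = vapply(recs, function(r)
      extract_sequence_window(r$sequence, r$position, config$flank_length,
                              r$accession), character(1)),
    "Sequence" = vapply(recs, `[[`, character(1), "peptide"),
    "Score" = vapply(recs, function(r) format(r$score), character(1)),
    "Protein group IDs" = vapply(recs, `[[`, character(1), "group"),
    "MS/MS IDs" = vapply(recs, function(r)
      paste(r$scans, collapse = ";"), character(1)),
    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Build the unified site table for one PTM
#'
#' For PTMs MaxQuant itself reports, the `<PTM>Sites.txt` table is filtered
#' (decoys/contaminants and sites whose every candidate group was filtered
#' out are dropped), classified against the localization threshold, and given
#' sequence windows from the best-scored group's lead accession. For protein
#' N-terminal PTMs the [detect_nterm_sites()] output is used. Both sources
#' share one schema.
#'
#' @param ptm_name PTM name (e.g. `"Oxidation (M)"`).
#' @param txt_dir The `combined/txt` folder (for `<PTM>Sites.txt`).
#' @param msms The `msms.txt` table.
#' @param groups The reported protein-group table.
#' @param catalog A [read_fasta()] catalog.
#' @param config A [reporting_config()].
#' @return A site-table data frame (possibly empty).
#' @export
build_site_table <- function(ptm_name, txt_dir, msms, groups, catalog, config) {
  if (ptm_name %in% nterm_ptm_names(config))
    return(detect_nterm_sites(msms, groups, catalog, config, ptm_name))
  path <- file.path(txt_dir, paste0(ptm_name, "Sites.txt"))
  if (!file.exists(path)) {
    mr_log_warn(sprintf("site table for '%s' not found (%s); skipped",
                        ptm_name, basename(path)))
    return(empty_site_table())
  }
  raw <- read_table(path)
  raw <- filter_decoys_contaminants(raw, "Proteins")
  if (nrow(raw) == 0L) return(empty_site_table())
  out <- empty_site_table()
  for (i in seq_len(nrow(raw))) {
    gid <- resolve_best_group(split_ids(raw[["Protein group IDs"]][i]), groups)
    if (is.na(gid)) next
    grow <- groups[match(gid, groups[["id"]]), ]
    lead <- grow[["Lead protein"]]
    entry <- catalog_get(catalog, lead)
    pos <- as.integer(num_or_na(raw[["Position"]][i]))
    window <- if (!is.na(entry$sequence) && !is.na(pos) &&
                  pos >= 1L && pos <= nchar(entry$sequence))
      extract_sequence_window(entry$sequence, pos, config$flank_length, lead)
    else raw[["Sequence window"]][i] %||% ""
    prob <- num_or_na(raw[["Localization prob"]][i])
    out <- rbind(out, data.frame(
      "PTM" = ptm_name, "Protein" = lead,
      "Position" = raw[["Position"]][i],
      "Amino acid" = raw[["Amino acid"]][i] %||% "",
      "Localization prob" = raw[["Localization prob"]][i] %||% "",
      "Site class" = classify_site(prob, config$loc_prob_threshold),
      "Sequence window" = window,
      "Sequence" = raw[["Sequence"]][i] %||% "",
      "Score" = raw[["Score"]][i] %||% "",
      "Protein group IDs" = gid,
      "MS/MS IDs" = raw[["MS/MS IDs"]][i] %||% "",
      check.names = FALSE, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
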