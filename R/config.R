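#' @importFrom stats median sd setNames
#' @importFrom utils write.table
NULL

.mr_table_names <- c("protein_groups", "peptides", "sites", "msms", "summary")

#' Column title selection rule
#'
#' MaxQuant column titles vary between versions, so reported columns are
#' selected by rules: an `exact` rule selects a title equal to its pattern, a
#' `keyword` rule selects every title containing the pattern as a
#' (case-sensitive) substring. Keyword rules are how experiment-specific
#' columns such as `"Reporter intensity 0 exp1"` are captured.
#'
#' @param pattern Non-empty character scalar.
#' @param mode `"exact"` or `"keyword"`.
#' @return An object of class `title_rule`.
#' @export
title_rule <- function(pattern, mode = c("exact", "keyword")) {
  mode <- match.arg(mode)
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern))
    stop("title_rule: 'pattern' must be a non-empty string")
  structure(list(pattern = pattern, mode = mode), class = "title_rule")
}

#' Select column titles by rule
#'
#' Applies the rules in order; within a keyword rule, matched titles keep
#' their header order. Duplicates (a title matched by several rules) are kept
#' once, at their first selection. An exact rule matching no title logs a
#' warning (the column may simply be absent in this MaxQuant version) and is
#' otherwise ignored.
#'
#' @param header Character vector of column titles (non-empty).
#' @param rules List of [title_rule()] objects.
#' @return Character vector of selected titles.
#' @export
match_columns <- function(header, rules) {
  stopifnot(is.character(header), length(header) > 0L)
  out <- character()
  for (r in rules) {
    hit <- if (r$mode == "exact") header[header == r$pattern]
           else header[grepl(r$pattern, header, fixed = TRUE)]
    if (r$mode == "exact" && length(hit) == 0L)
      mr_log_warn(sprintf("exact title '%s' matched no column", r$pattern))
    out <- c(out, hit)
  }
  unique(out)
}

default_table_specs <- function() {
  k <- function(p) title_rule(p, "keyword")
  e <- function(p) title_rule(p, "exact")
  list(
    protein_groups = list(e("Protein IDs"), e("Majority protein IDs"),
      k("Peptide counts"), e("Peptides"), e("Unique peptides"), e("Score"),
      k("Reporter intensity"), e("id"), e("MS/MS IDs")),
    peptides = list(e("Sequence"), e("Proteins"), e("Protein group IDs"),
      e("Unique (Groups)"), e("Score"), e("id"), e("MS/MS IDs")),
    sites = list(e("Proteins"), e("Protein"), e("Position"),
      e("Amino acid"), e("Localization prob"), e("Score"),
      e("Protein group IDs"), e("MS/MS IDs"), e("id")),
    msms = list(e("Raw file"), e("Scan number"), e("Sequence"),
      e("Modified sequence"), e("Modifications"), e("Proteins"),
      e("Protein group IDs"), e("Score"), k("Reporter intensity"),
      e("Masses"), e("Matches"), e("Intensities"), e("id")),
    summary = list(e("Raw file"), e("Experiment"))
  )
}

#' Reporting configuration
#'
#' Owns every tunable of the pipeline: per-table column-selection rules, the
#' PTM names to report as site tables (a name containing
#' `"(Protein N-term)"` is treated as a protein N-terminal modification and
#' detected from `msms.txt` rather than read from a MaxQuant site table), the
#' sequence-window flank length, the site localization-probability threshold,
#' the outlier-rejection sigma multiplier, the low-intensity spectrum
#' threshold, and peptide-usage flags.
#'
#' @param table_specs Named list (`protein_groups`, `peptides`, `sites`,
#'   `msms`, `summary`) of lists of [title_rule()]s.
#' @param ptm_names Character vector of PTM names to build site tables for.
#' @param flank_length Residues reported each side of a site (default 6,
#'   giving 13-residue windows).
#' @param loc_prob_threshold Sites with localization probability strictly
#'   above this are "specific" (default 0.5).
#' @param outlier_sigma Reporter fractions farther than this many population
#'   standard deviations from their channel mean are rejected (default 1.96).
#' @param low_intensity_threshold Spectra whose summed reporter intensity is
#'   at or below this are excluded from quantification (default 0).
#' @param use_unique_peptides_only Quantify proteins from unique peptides
#'   only (default TRUE).
#' @param ile_eq_leu Treat Ile and Leu as equal when locating peptides in
#'   protein sequences (default FALSE).
#' @param calibrate_channels Apply the equal-total channel calibration
#'   (default TRUE). Calibration corrects technical loading bias by forcing
#'   per-channel intensity totals to be equal; disable it for designs where
#'   total loading differs on purpose (factors are still computed and
#'   exported as a diagnostic).
#' @return A validated object of class `reporting_config`.
#' @export
reporting_config <- function(table_specs = default_table_specs(),
                             ptm_names = character(),
                             flank_length = 6L,
                             loc_prob_threshold = 0.5,
                             outlier_sigma = 1.96,
                             low_intensity_threshold = 0,
                             use_unique_peptides_only = TRUE,
                             ile_eq_leu = FALSE,
                             calibrate_channels = TRUE) {
  # partial table_specs are completed with the defaults so that a written
  # configuration always round-trips
  full_specs <- default_table_specs()
  for (nm in names(table_specs)) full_specs[[nm]] <- table_specs[[nm]]
  cfg <- structure(list(
    table_specs = full_specs, ptm_names = as.character(ptm_names),
    flank_length = as.integer(flank_length),
    loc_prob_threshold = as.numeric(loc_prob_threshold),
    outlier_sigma = as.numeric(outlier_sigma),
    low_intensity_threshold = as.numeric(low_intensity_threshold),
    use_unique_peptides_only = isTRUE(use_unique_peptides_only),
    ile_eq_leu = isTRUE(ile_eq_leu),
    calibrate_channels = isTRUE(calibrate_channels)),
    class = "reporting_config")
  validate_reporting_config(cfg)
}

validate_reporting_config <- function(cfg) {
  if (is.na(cfg$flank_length) || cfg$flank_length < 0L)
    stop("reporting_config: flank_length must be >= 0")
  if (is.na(cfg$loc_prob_threshold) || cfg$loc_prob_threshold < 0 ||
      cfg$loc_prob_threshold > 1)
    stop("reporting_config: loc_prob_threshold must lie in [0, 1]")
  if (is.na(cfg$outlier_sigma) || cfg$outlier_sigma <= 0)
    stop("reporting_config: outlier_sigma must be > 0")
  if (is.na(cfg$low_intensity_threshold) || cfg$low_intensity_threshold < 0)
    stop("reporting_config: low_intensity_threshold must be >= 0")
  bad <- setdiff(names(cfg$table_specs), .mr_table_names)
  if (length(bad))
    stop("reporting_config: unknown table name(s): ", paste(bad, collapse = ", "))
  for (nm in names(cfg$table_specs)) {
    if (length(cfg$table_specs[[nm]]) < 1L)
      stop("reporting_config: table '", nm, "' has no title rules")
    ok <- vapply(cfg$table_specs[[nm]], inherits, logical(1), "title_rule")
    if (!all(ok)) stop("reporting_config: table '", nm,
                       "' contains a non-title_rule entry")
  }
  cfg
}

#' Names of protein N-terminal PTMs in a configuration
#'
#' @param config A [reporting_config()].
#' @return Character vector (possibly empty).
#' @export
nterm_ptm_names <- function(config) {
  config$ptm_names[grepl("(Protein N-term)", config$ptm_names, fixed = TRUE)]
}

## --- configuration file: line-oriented key/value with [sections] ----------
## [general] holds scalar settings; each logical table has its own section
## with one rule per line, "exact = <title>" or "keyword = <substring>".

#' Load a reporting configuration file
#'
#' The file is UTF-8 plain text. `#` starts a comment, blank lines are
#' ignored. A `[general]` section carries `key = value` settings
#' (`ptm_names` is `;`-separated); a section per logical table
#' (`[protein_groups]`, `[peptides]`, `[sites]`, `[msms]`, `[summary]`)
#' carries one column rule per line: `exact = <title>` or
#' `keyword = <substring>`. Settings omitted from the file keep the defaults
#' of [reporting_config()].
#'
#' @param path Path to the configuration file.
#' @return A validated [reporting_config()].
#' @export
load_reporting_config <- function(path) {
  if (!file.exists(path))
    stop("reporting configuration file not found: ", path)
  lines <- read_text_lines(path)
  defaults <- reporting_config()
  general <- list()
  specs <- list()
  section <- NA_character_
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[[i]])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      if (!identical(section, "general") && !section %in% .mr_table_names)
        stop(sprintf("%s:%d: unknown section [%s]", path, i, section))
      next
    }
    if (!grepl("=", ln, fixed = TRUE))
      stop(sprintf("%s:%d: malformed line (expected 'key = value'): %s",
                   path, i, ln))
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (is.na(section))
      stop(sprintf("%s:%d: entry before any [section]", path, i))
    if (identical(section, "general")) {
      general[[key]] <- val
    } else {
      if (!key %in% c("exact", "keyword"))
        stop(sprintf("%s:%d: rule mode must be 'exact' or 'keyword', got '%s'",
                     path, i, key))
      if (!nzchar(val))
        stop(sprintf("%s:%d: empty rule pattern", path, i))
      specs[[section]] <- c(specs[[section]], list(title_rule(val, key)))
    }
  }
  as_bool <- function(x) tolower(x) %in% c("true", "yes", "1")
  pick <- function(key, default, f = identity)
    if (is.null(general[[key]])) default else f(general[[key]])
  split_names <- function(x) {
    out <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
    out[nzchar(out)]
  }
  table_specs <- defaults$table_specs
  for (nm in names(specs)) table_specs[[nm]] <- specs[[nm]]
  reporting_config(
    table_specs = table_specs,
    ptm_names = pick("ptm_names", defaults$ptm_names, split_names),
    flank_length = pick("flank_length", defaults$flank_length, as.integer),
    loc_prob_threshold = pick("loc_prob_threshold",
                              defaults$loc_prob_threshold, as.numeric),
    outlier_sigma = pick("outlier_sigma", defaults$outlier_sigma, as.numeric),
    low_intensity_threshold = pick("low_intensity_threshold",
                                   defaults$low_intensity_threshold, as.numeric),
    use_unique_peptides_only = pick("use_unique_peptides_only",
                                    defaults$use_unique_peptides_only, as_bool),
    ile_eq_leu = pick("ile_eq_leu", defaults$ile_eq_leu, as_bool),
    calibrate_channels = pick("calibrate_channels",
                              defaults$calibrate_channels, as_bool))
}

#' Write a reporting configuration file
#'
#' Inverse of [load_reporting_config()]: `load_reporting_config(write_reporting_config(cfg, path))`
#' reproduces `cfg`.
#'
#' @param config A [reporting_config()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_reporting_config <- function(config, path) {
  lines <- c("# mqreport reporting configuration", "[general]",
    paste0("ptm_names = ", paste(config$ptm_names, collapse = "; ")),
    paste0("flank_length = ", config$flank_length),
    paste0("loc_prob_threshold = ", format(config$loc_prob_threshold)),
    paste0("outlier_sigma = ", format(config$outlier_sigma)),
    paste0("low_intensity_threshold = ", format(config$low_intensity_threshold)),
    paste0("use_unique_peptides_only = ",
           tolower(config$use_unique_peptides_only)),
    paste0("ile_eq_leu = ", tolower(config$ile_eq_leu)),
    paste0("calibrate_channels = ", tolower(config$calibrate_channels)))
  for (nm in names(config$table_specs)) {
    lines <- c(lines, "", paste0("[", nm, "]"),
      vapply(config$table_specs[[nm]],
             function(r) paste0(r$mode, " = ", r$pattern), character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}

## --- isotope-impurity correction matrix -----------------------------------

#' Isotope-impurity correction matrix
#'
#' Entry (i, j) is the fraction of channel j's true signal observed in
#' channel i (columns = true channel, rows = observed channel). Columns whose
#' sum exceeds 1 (e.g. vendor sheets in percent) are rescaled to unit sum
#' with a logged warning.
#'
#' @param labels Ordered reporter channel names.
#' @param values Square numeric matrix, entries >= 0, diagonal > 0.
#' @return An object of class `correction_matrix`.
#' @export
correction_matrix <- function(labels, values) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("correction matrix must be square, got ",
         nrow(values), "x", ncol(values))
  if (length(labels) != nrow(values))
    stop("correction matrix has ", length(labels), " labels but dimension ",
         nrow(values))
  if (any(values < 0)) stop("correction matrix entries must be >= 0")
  if (any(diag(values) <= 0)) stop("correction matrix diagonal must be > 0")
  cs <- colSums(values)
  over <- cs > 1 + 1e-9
  if (any(over)) {
    values[, over] <- sweep(values[, over, drop = FALSE], 2, cs[over], "/")
    mr_log_warn(sprintf(
      "correction matrix: %d column(s) summed above 1 and were rescaled",
      sum(over)))
  }
  dimnames(values) <- list(labels, labels)
  structure(list(labels = as.character(labels), values = values),
            class = "correction_matrix")
}

#' Load a correction matrix file
#'
#' Tab-separated text: comment lines start with `#`; the first data row holds
#' the channel labels; each following row is `label<TAB>v1<TAB>...<TAB>vn`.
#'
#' @param path Path to the matrix file.
#' @return A [correction_matrix()].
#' @export
load_correction_matrix <- function(path) {
  if (!file.exists(path)) stop("correction matrix file not found: ", path)
  lines <- read_text_lines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2L) stop("correction matrix file has no data: ", path)
  labels <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  labels <- labels[nzchar(labels)]
  n <- length(labels)
  rows <- lapply(lines[-1], function(ln) strsplit(ln, "\t", fixed = TRUE)[[1]])
  if (length(rows) != n)
    stop("correction matrix is not square: ", n, " labels but ",
         length(rows), " rows in ", path)
  values <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    fields <- rows[[i]]
    if (length(fields) != n + 1L)
      stop("correction matrix row ", i, " has ", length(fields) - 1L,
           " values, expected ", n)
    values[i, ] <- as.numeric(fields[-1])
  }
  if (anyNA(values)) stop("correction matrix contains non-numeric entries")
  correction_matrix(labels, values)
}

#' Write a correction matrix file
#'
#' @param cm A [correction_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_correction_matrix <- function(cm, path) {
  lines <- c("# isotope-impurity correction matrix",
    "# columns = true channel, rows = observed channel",
    paste(c("", cm$labels), collapse = "\t"),
    vapply(seq_along(cm$labels), function(i)
      paste(c(cm$labels[i], format(cm$values[i, ], trim = TRUE)),
            collapse = "\t"), character(1)))
  writeLines(lines, path)
  invisible(path)
}

## --- experimental design ---------------------------------------------------

#' Experimental design (raw file to replicate assignment)
#'
#' Built from MaxQuant's `summary.txt` (columns `Raw file`, `Experiment`) or
#' from a two-column tab-separated template (header row required). A template
#' overrides the summary. Raw files with an empty experiment label — and raw
#' files seen in `msms.txt` but absent from the design — are assigned the
#' single replicate `"default"` (with a logged warning in the latter case).
#'
#' @param summary Optional summary table (data frame) as read by
#'   [read_table()]; a `Raw file` of `"Total"` is ignored.
#' @param template_path Optional path to a design template file.
#' @param raw_files Optional character vector of raw files that must be
#'   covered (typically the distinct raw files of `msms.txt`).
#' @return An object of class `experimental_design`: a data frame with
#'   columns `raw_file`, `replicate`, plus attribute `replicates` (ordered
#'   distinct labels).
#' @export
load_experimental_design <- function(summary = NULL, template_path = NULL,
                                     raw_files = NULL) {
  map <- data.frame(raw_file = character(), replicate = character(),
                    stringsAsFactors = FALSE)
  if (!is.null(summary)) {
    rf <- summary[["Raw file"]]
    ex <- if (!is.null(summary[["Experiment"]])) summary[["Experiment"]]
          else rep("", length(rf))
    keep <- !is.na(rf) & nzchar(rf) & rf != "Total"
    map <- data.frame(raw_file = rf[keep], replicate = ex[keep],
                      stringsAsFactors = FALSE)
  }
  if (!is.null(template_path)) {
    if (!file.exists(template_path))
      stop("experimental design template not found: ", template_path)
    tmpl <- read_table(template_path)
    if (ncol(tmpl) < 2L)
      stop("experimental design template needs two columns (raw file, label)")
    tm <- data.frame(raw_file = tmpl[[1]], replicate = tmpl[[2]],
                     stringsAsFactors = FALSE)
    # template wins over summary.txt for the files it lists
    map <- map[!map$raw_file %in% tm$raw_file, , drop = FALSE]
    map <- rbind(tm, map)
  }
  map$replicate[is.na(map$replicate) | !nzchar(map$replicate)] <- "default"
  map <- map[!duplicated(map$raw_file), , drop = FALSE]
  if (!is.null(raw_files)) {
    missing <- setdiff(raw_files, map$raw_file)
    if (length(missing)) {
      mr_log_warn(sprintf(
        "raw file(s) absent from experimental design, assigned 'default': %s",
        paste(missing, collapse = ", ")))
      map <- rbind(map, data.frame(raw_file = missing, replicate = "default",
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(map) <- NULL
  structure(map, replicates = unique(map$replicate),
            class = c("experimental_design", "data.frame"))
}

#' @export
print.experimental_design <- function(x, ...) {
  cat("Experimental design:", nrow(x), "raw file(s),",
      length(attr(x, "replicates")), "replicate(s)\n")
  print.data.frame(x, ...)
  invisible(x)
}

## --- FASTA header parse rules ----------------------------------------------

parse_extractor <- function(spec) {
  if (is.null(spec) || !nzchar(spec)) return(NULL)
  if (startsWith(spec, "regex:")) {
    list(type = "regex", pattern = sub("^regex:", "", spec))
  } else if (startsWith(spec, "token:")) {
    parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
    if (length(parts) != 3L)
      stop("token extractor must be 'token:<delim>:<index>', got: ", spec)
    list(type = "token", delim = parts[2], index = as.integer(parts[3]))
  } else stop("unknown extractor spec (want 'regex:' or 'token:'): ", spec)
}

#' FASTA header parse rule
#'
#' Extractors pull the accession, gene name and description out of a FASTA
#' header line. An extractor is either `regex:<pattern>` (first capture
#' group, PCRE) or `token:<delimiter>:<index>` (1-based delimited token).
#' Presets ship for the common header dialects: `"uniprot"`
#' (`>sp|P00924|ENO1_YEAST Enolase 1 OS=... GN=ENO1 ...`), `"ensembl"`
#' (`>ENSP... pep ... gene:ENSG... description:...`) and `"ncbi"`
#' (`>NP_012345.1 description [Organism]`, also the legacy `gi|` form).
#'
#' @param preset One of `"uniprot"`, `"ensembl"`, `"ncbi"`, or `NULL` to give
#'   explicit extractors.
#' @param accession,gene,description Extractor specs (see above); `gene` and
#'   `description` may be `NULL`.
#' @return An object of class `header_parse_rule`.
#' @export
header_parse_rule <- function(preset = NULL, accession = NULL, gene = NULL,
                              description = NULL) {
  if (!is.null(preset)) {
    presets <- list(
      uniprot = list(
        accession = "regex:^(?:sp|tr)\\|([^|\\s]+)\\|",
        gene = "regex:\\bGN=(\\S+)",
        description = "regex:^\\S+\\s+(.+?)(?:\\s+[A-Z]{2}=.*)?$"),
      ensembl = list(
        accession = "regex:^(\\S+)",
        gene = "regex:\\bgene_symbol:(\\S+)",
        description = "regex:\\bdescription:(.+)$"),
      ncbi = list(
        accession = "regex:^(?:gi\\|\\d+\\|\\w+\\|)?([^|\\s]+)",
        gene = NULL,
        description = "regex:^\\S+\\s+(.+?)(?:\\s*\\[[^]]*\\])?$"))
    p <- presets[[match.arg(preset, names(presets))]]
    accession <- p$accession; gene <- p$gene; description <- p$description
  }
  if (is.null(accession)) stop("header_parse_rule needs an accession extractor")
  structure(list(accession = parse_extractor(accession),
                 gene = parse_extractor(gene),
                 description = parse_extractor(description)),
            class = "header_parse_rule")
}

#' Load a FASTA header parse-rule file
#'
#' Plain text with lines `accession = <extractor>`, `gene = <extractor>`,
#' `description = <extractor>` (or a single line `preset = <name>`);
#' extractor syntax as in [header_parse_rule()].
#'
#' @param path Path to the rule file.
#' @return A [header_parse_rule()].
#' @export
load_parse_rule <- function(path) {
  if (!file.exists(path)) stop("parse-rule file not found: ", path)
  lines <- trimws(read_text_lines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed parse-rule line (expected 'key = value'): ", ln)
    key <- trimws(sub("=.*$", "", ln))
    kv[[key]] <- trimws(sub("^[^=]*=", "", ln))
  }
  if (!is.null(kv$preset)) return(header_parse_rule(preset = kv$preset))
  header_parse_rule(accession = kv$accession, gene = kv$gene,
                    description = kv$description)
}

apply_extractor <- function(header, ex) {
  if (is.null(ex)) return("")
  if (ex$type == "regex") {
    m <- regexec(ex$pattern, header, perl = TRUE)[[1]]
    if (m[1] == -1L || length(m) < 2L) return("")
    start <- m[2]; len <- attr(m, "match.length")[2]
    if (start == -1L) return("")
    substr(header, start, start + len - 1L)
  } else {
    tok <- strsplit(header, ex$delim, fixed = TRUE)[[1]]
    if (ex$index > length(tok)) "" else tok[ex$index]
  }
}

#' Parse one FASTA header line with a rule
#'
#' Falls back to the first whitespace-delimited token as accession (empty
#' gene/description, logged warning) when the rule's accession extractor
#' fails on the header.
#'
#' @param header Header line, without the leading `>`.
#' @param rule A [header_parse_rule()].
#' @return List with `accession`, `gene`, `description`.
#' @export
parse_fasta_header <- function(header, rule) {
  acc <- apply_extractor(header, rule$accession)
  if (!nzchar(acc)) {
    acc <- strsplit(trimws(header), "\\s+")[[1]][1]
    mr_log_warn(sprintf("header not parseable by rule, using token '%s': %s",
                        acc, header))
    return(list(accession = acc, gene = "", description = ""))
  }
  list(accession = acc,
       gene = apply_extractor(header, rule$gene),
       description = apply_extractor(header, rule$description))
}
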