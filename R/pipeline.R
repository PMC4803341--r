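#' Run the full post-processing pipeline on a MaxQuant project
#'
#' Reads the `combined/txt` tables, builds the filtered/minimized/annotated
#' protein-group report, the peptide and MS/MS reports, per-PTM site tables
#' (including protein N-terminal modifications detected from `msms.txt`),
#' performs Libra-style isobaric quantification when reporter intensities
#' are present, computes descriptive statistics and replication assignment,
#' and writes the organized report bundle with an `index.html` entry page
#' into `out_dir` (default: a `maxreport` folder inside the project).
#'
#' On failure, the processing log — ending in an ERROR line — is still
#' written to the output folder, but no index page is produced; the error is
#' then re-signalled.
#'
#' @param project_dir MaxQuant project directory (contains `combined/txt`).
#' @param config A [reporting_config()] or path to a configuration file.
#' @param fasta Character vector of FASTA paths.
#' @param rules Parse rules paired positionally with `fasta`: a list of
#'   [header_parse_rule()]s, preset names, or rule-file paths.
#' @param correction_matrix Optional [correction_matrix()] or path.
#' @param design_template Optional experimental-design template path
#'   (overrides `summary.txt`).
#' @param out_dir Output folder.
#' @return Invisibly, an object of class `maxreport_run` with elements
#'   `proteins`, `peptides`, `msms`, `site_tables`, `catalog`, `design`,
#'   `quant`, `stats`, `replication`, `config`, `out_dir`.
#' @export
run_maxreport <- function(project_dir, config, fasta, rules,
                          correction_matrix = NULL, design_template = NULL,
                          out_dir = file.path(project_dir, "maxreport")) {
  mr_log_reset()
  mr_log_info(sprintf("processing project %s", project_dir))
  run <- tryCatch(
    run_maxreport_impl(project_dir, config, fasta, rules, correction_matrix,
                       design_template, out_dir),
    error = function(e) {
      mr_log_error(conditionMessage(e))
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      mr_log_write(file.path(out_dir, "maxreport.log"))
      idx <- file.path(out_dir, "index.html")
      if (file.exists(idx)) unlink(idx)
      stop(e)
    })
  invisible(run)
}

run_maxreport_impl <- function(project_dir, config, fasta, rules,
                               correction_matrix, design_template, out_dir) {
  if (is.character(config)) config <- load_reporting_config(config)
  stopifnot(inherits(config, "reporting_config"))
  if (is.character(correction_matrix) && length(correction_matrix))
    correction_matrix <- load_correction_matrix(correction_matrix)

  txt <- file.path(project_dir, "combined", "txt")
  if (!dir.exists(txt))
    stop("no combined/txt folder under ", project_dir)
  as_rule <- function(r) {
    if (inherits(r, "header_parse_rule")) r
    else if (file.exists(r)) load_parse_rule(r)
    else header_parse_rule(preset = r)
  }
  rules <- if (inherits(rules, "header_parse_rule")) list(rules)
           else lapply(if (is.list(rules)) rules else as.list(rules), as_rule)
  catalog <- read_fasta(fasta, rules)
  mr_log_info(sprintf("sequence catalog: %d entries", nrow(catalog)))

  groups_raw <- read_table(file.path(txt, "proteinGroups.txt"))
  peptides_raw <- read_table(file.path(txt, "peptides.txt"))
  msms_raw <- read_table(file.path(txt, "msms.txt"))
  summary_tab <- tryCatch(read_table(file.path(txt, "summary.txt")),
                          error = function(e) NULL)

  proteins <- build_protein_report(groups_raw, catalog)
  mr_log_info(sprintf("protein groups reported: %d of %d",
                      nrow(proteins), nrow(groups_raw)))

  drop_unmapped <- function(df, id_col = "Proteins") {
    df <- filter_decoys_contaminants(df, id_col)
    gid <- vapply(df[["Protein group IDs"]], function(k)
      resolve_best_group(split_ids(k), proteins), character(1),
      USE.NAMES = FALSE)
    keep <- !is.na(gid)
    out <- df[keep, , drop = FALSE]
    out[["Resolved group"]] <- gid[keep]
    rownames(out) <- NULL
    for (a in c("table_name", "source_path")) attr(out, a) <- attr(df, a)
    out
  }
  peptides <- drop_unmapped(peptides_raw)
  msms <- drop_unmapped(msms_raw)
  mr_log_info(sprintf("peptides reported: %d; MS/MS scans reported: %d",
                      nrow(peptides), nrow(msms)))

  site_tables <- list()
  for (ptm in config$ptm_names)
    site_tables[[ptm]] <- build_site_table(ptm, txt, msms, proteins,
                                           catalog, config)

  design <- load_experimental_design(summary_tab, design_template,
                                     raw_files = unique(msms[["Raw file"]]))
  quant <- quantify_project(msms, proteins, site_tables, design, config,
                            correction_matrix, peptides = peptides)

  stats <- compute_identification_stats(proteins, peptides, msms, site_tables)
  replication <- compute_replication_assignment(proteins, peptides, msms,
                                                site_tables, design)

  run <- structure(list(
    proteins = proteins, peptides = peptides, msms = msms,
    site_tables = site_tables, catalog = catalog, design = design,
    quant = quant, stats = stats, replication = replication,
    config = config, out_dir = out_dir,
    parameters = c(
      sprintf("project: %s", project_dir),
      sprintf("fasta: %s", paste(fasta, collapse = ", ")),
      sprintf("channels: %s",
              if (is.null(quant)) "none" else length(quant$channels)),
      sprintf("flank length: %d", config$flank_length),
      sprintf("localization threshold: %g", config$loc_prob_threshold),
      sprintf("outlier sigma: %g", config$outlier_sigma),
      sprintf("unique peptides only: %s", config$use_unique_peptides_only))),
    class = "maxreport_run")
  write_outputs(run, out_dir)
  run
}

#' @export
print.maxreport_run <- function(x, ...) {
  cat("MaxQuant post-processing run\n")
  cat(sprintf("  protein groups: %d\n  peptides: %d\n  MS/MS scans: %d\n",
              nrow(x$proteins), nrow(x$peptides), nrow(x$msms)))
  for (ptm in names(x$site_tables))
    cat(sprintf("  sites [%s]: %d\n", ptm, nrow(x$site_tables[[ptm]])))
  if (!is.null(x$quant)) print(x$quant)
  cat("  output:", x$out_dir, "\n")
  invisible(x)
}
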