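html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub('"', "&quot;", x, fixed = TRUE)
  gsub("'", "&apos;", x, fixed = TRUE)
}

nan_like <- function(x) {
  is.na(x) | !nzchar(x) | toupper(x) %in% c("NAN", "NA", "INF", "-INF",
                                            "INFINITY", "-INFINITY")
}

dedup_sheet_names <- function(names) {
  names <- substr(names, 1, 31)
  out <- character(length(names))
  seen <- character()
  for (i in seq_along(names)) {
    nm <- names[i]
    k <- 1L
    while (nm %in% seen) {
      suffix <- paste0("_", k)
      nm <- paste0(substr(names[i], 1, 31 - nchar(suffix)), suffix)
      k <- k + 1L
    }
    seen <- c(seen, nm)
    out[i] <- nm
  }
  out
}

#' Export tables to a single multi-sheet workbook
#'
#' Writes one spreadsheet file with one sheet per table, in SpreadsheetML
#' 2003 XML (plain text; opens in Excel and LibreOffice). Sheet names are
#' truncated to 31 characters and deduplicated. NaN-like and missing values
#' are written as empty cells; numeric-looking values as typed numbers.
#'
#' @param tables Named list of data frames.
#' @param path Output path (conventionally `.xml`).
#' @param max_rows Per-sheet row limit; sheets beyond it are truncated with
#'   a warning row (default 65000, the classic worksheet limit).
#' @return Invisibly, `path`.
#' @export
export_workbook <- function(tables, path, max_rows = 65000L) {
  sheet_names <- dedup_sheet_names(gsub("[\\\\/?*\\[\\]:]", "_",
                                        names(tables)))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl('<?xml version="1.0" encoding="UTF-8"?>',
     '<Workbook xmlns="urn:schemas-microsoft-com:office:spreadsheet"',
     ' xmlns:ss="urn:schemas-microsoft-com:office:spreadsheet">')
  for (i in seq_along(tables)) {
    df <- tables[[i]]
    wl(sprintf(' <Worksheet ss:Name="%s">', xml_escape(sheet_names[i])),
       "  <Table>")
    row_xml <- function(values, force_string = FALSE) {
      cells <- vapply(values, function(v) {
        v <- as.character(v)
        if (!force_string && nan_like(v)) return("<Cell/>")
        num <- suppressWarnings(as.numeric(v))
        if (!force_string && !is.na(num) && is.finite(num))
          sprintf('<Cell><Data ss:Type="Number">%s</Data></Cell>',
                  format(num, digits = 15, scientific = FALSE, trim = TRUE))
        else
          sprintf('<Cell><Data ss:Type="String">%s</Data></Cell>',
                  xml_escape(v))
      }, character(1))
      paste0("   <Row>", paste(cells, collapse = ""), "</Row>")
    }
    wl(row_xml(names(df), force_string = TRUE))
    nr <- nrow(df)
    truncated <- nr > max_rows
    if (truncated) {
      mr_log_warn(sprintf("sheet '%s' truncated to %d rows (had %d)",
                          sheet_names[i], max_rows, nr))
      nr <- max_rows
    }
    for (r in seq_len(nr))
      wl(row_xml(unlist(df[r, ], use.names = FALSE)))
    if (truncated)
      wl(row_xml(c("TRUNCATED: row limit reached",
                   rep("", max(0, ncol(df) - 1))), force_string = TRUE))
    wl("  </Table>", " </Worksheet>")
  }
  wl("</Workbook>")
  invisible(path)
}

#' Build the HTML index page of a report folder
#'
#' The index has exactly six sections: (i) input parameters, (ii)
#' identification results, (iii) summary and descriptive statistics, (iv)
#' quantification based on isobaric labelling, (v) miscellaneous, (vi) log
#' file. Each section lists links to the files the run produced; a section
#' with no files states so.
#'
#' @param manifest Named list with elements `parameters` (character vector of
#'   `key: value` lines) and, per section, a character vector of file paths
#'   relative to the output folder: `identification`, `statistics`,
#'   `quantification`, `miscellaneous`, `log`.
#' @param out_dir Output folder; `index.html` is written there and only
#'   existing files are linked.
#' @return Invisibly, the index path.
#' @export
build_index <- function(manifest, out_dir) {
  link_list <- function(paths, empty_note = "none produced") {
    paths <- paths[file.exists(file.path(out_dir, paths))]
    if (!length(paths)) return(paste0("<p><em>", empty_note, "</em></p>"))
    c("<ul>", sprintf('<li><a href="%s">%s</a></li>', paths,
                      html_escape(paths)), "</ul>")
  }
  sections <- c(
    "<h2>1. Input parameters</h2>",
    "<pre>", html_escape(manifest$parameters %||% character()), "</pre>",
    "<h2>2. Identification results</h2>",
    link_list(manifest$identification %||% character()),
    "<h2>3. Summary and descriptive statistics</h2>",
    link_list(manifest$statistics %||% character()),
    "<h2>4. Quantification based on isobaric labelling</h2>",
    link_list(manifest$quantification %||% character(),
              "not performed (no isobaric reporter intensities found)"),
    "<h2>5. Miscellaneous</h2>",
    link_list(manifest$miscellaneous %||% character()),
    "<h2>6. Log file</h2>",
    link_list(manifest$log %||% character()))
  html <- c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
            "<title>MaxQuant report</title></head><body>",
            "<h1>MaxQuant post-processing report</h1>", sections,
            "</body></html>")
  path <- file.path(out_dir, "index.html")
  writeLines(html, path)
  invisible(path)
}

write_catalog_fasta <- function(catalog, accessions, path) {
  entries <- catalog_get(catalog, unique(accessions))
  entries <- entries[!is.na(entries$sequence), , drop = FALSE]
  lines <- character()
  for (i in seq_len(nrow(entries))) {
    seq <- entries$sequence[i]
    chunks <- substring(seq, seq(1, nchar(seq), 60),
                        pmin(seq(60, nchar(seq) + 59, 60), nchar(seq)))
    lines <- c(lines, paste0(">", entries$accession[i],
                             ifelse(nzchar(entries$description[i]),
                                    paste0(" ", entries$description[i]), "")),
               chunks)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write the report bundle of a processed project
#'
#' Creates (or reuses, with a log note) the output folder and writes: the
#' minimized four-level identification tables (columns selected by the
#' configuration rules), the annotated-spectra table, per-PTM site tables,
#' quantification tables per replicate and merged, statistics and chart
#' files, replication assignment files, the extracted protein sequences
#' (FASTA), a combined workbook, the log, and the `index.html` entry page.
#'
#' @param run A `maxreport_run` object (see [run_maxreport()]).
#' @param out_dir Output folder.
#' @return Invisibly, a manifest of written files (relative paths).
#' @export
write_outputs <- function(run, out_dir) {
  if (dir.exists(out_dir))
    mr_log_info(sprintf("output folder %s exists; files will be overwritten",
                        out_dir))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "charts"), showWarnings = FALSE)

  cfg <- run$config
  select_cols <- function(df, spec_name) {
    sel <- match_columns(names(df), cfg$table_specs[[spec_name]])
    extra <- intersect(c("Retained protein IDs", "Lead protein", "Gene name",
                         "Protein description", "Site class",
                         "Sequence window", "PTM"), names(df))
    df[, unique(c(sel, extra)), drop = FALSE]
  }

  tables <- list()
  ident <- character()
  put <- function(df, file, sheet) {
    write_table(df, file.path(out_dir, file))
    tables[[sheet]] <<- df
    ident <<- c(ident, file)
  }
  put(select_cols(run$proteins, "protein_groups"), "proteinGroups.txt",
      "Protein groups")
  put(select_cols(run$peptides, "peptides"), "peptides.txt", "Peptides")
  put(select_cols(run$msms, "msms"), "msms.txt", "MSMS scans")
  for (ptm in names(run$site_tables)) {
    safe <- gsub("[^A-Za-z0-9]+", "_", ptm)
    put(run$site_tables[[ptm]], paste0("sites_", safe, ".txt"),
        paste0("Sites ", ptm))
  }
  # annotated spectra: peptide match, fragment annotations, ion intensities
  # and scores selected from msms.txt
  spec_cols <- intersect(c("Raw file", "Scan number", "Sequence",
                           "Modified sequence", "Modifications", "Proteins",
                           "Score", "Masses", "Matches", "Intensities", "id"),
                         names(run$msms))
  put(run$msms[, spec_cols, drop = FALSE], "annotated_spectra.txt",
      "Annotated spectra")

  stats_files <- character()
  su <- run$stats
  stat_lines <- c(
    sprintf("Protein groups\t%d", su$counts$protein_groups),
    sprintf("Peptides\t%d", su$counts$peptides),
    sprintf("MS/MS spectra\t%d", su$counts$spectra))
  writeLines(c("Item\tCount", stat_lines),
             file.path(out_dir, "summary_counts.txt"))
  stats_files <- c(stats_files, "summary_counts.txt")
  if (nrow(su$ptm_stats)) {
    write_table(su$ptm_stats, file.path(out_dir, "summary_ptm.txt"))
    stats_files <- c(stats_files, "summary_ptm.txt")
  }
  chart_files <- emit_charts(su, run$quant, file.path(out_dir, "charts"))
  stats_files <- c(stats_files,
                   file.path("charts", basename(chart_files)))
  if (!is.null(run$replication)) {
    for (nm in names(run$replication)) {
      f <- paste0("replication_", gsub("[^A-Za-z0-9]+", "_", nm), ".txt")
      write_table(run$replication[[nm]], file.path(out_dir, f))
      stats_files <- c(stats_files, f)
    }
  }

  quant_files <- character()
  if (!is.null(run$quant)) {
    calib <- data.frame(channel = run$quant$channels,
                        factor = as.numeric(unclass(run$quant$calibration)),
                        stringsAsFactors = FALSE)
    write_table(calib, file.path(out_dir, "calibration_factors.txt"))
    quant_files <- c(quant_files, "calibration_factors.txt")
    tables[["Calibration factors"]] <- calib
    for (lvl in c("protein", "peptide", "site")) {
      lv <- run$quant[[lvl]]
      for (r in names(lv$per_replicate)) {
        f <- sprintf("quant_%s_%s.txt", lvl, gsub("[^A-Za-z0-9]+", "_", r))
        write_table(lv$per_replicate[[r]], file.path(out_dir, f))
        quant_files <- c(quant_files, f)
      }
      if (!is.null(lv$merged)) {
        f <- sprintf("quant_%s_merged.txt", lvl)
        write_table(lv$merged, file.path(out_dir, f))
        quant_files <- c(quant_files, f)
        tables[[paste("Quant", lvl)]] <- lv$merged
      }
    }
  }

  misc <- character()
  if (!is.null(run$catalog) && nrow(run$proteins)) {
    write_catalog_fasta(run$catalog, run$proteins[["Lead protein"]],
                        file.path(out_dir, "reported_sequences.fasta"))
    misc <- c(misc, "reported_sequences.fasta")
  }
  scan_ids <- data.frame(id = run$msms[["id"]],
                         "Raw file" = run$msms[["Raw file"]],
                         check.names = FALSE, stringsAsFactors = FALSE)
  write_table(scan_ids, file.path(out_dir, "msms_scan_ids.txt"))
  misc <- c(misc, "msms_scan_ids.txt")

  export_workbook(tables, file.path(out_dir, "combined_results.xml"))
  misc <- c(misc, "combined_results.xml")

  mr_log_info("all result files written")
  mr_log_write(file.path(out_dir, "maxreport.log"))
  manifest <- list(parameters = run$parameters,
                   identification = ident, statistics = stats_files,
                   quantification = quant_files, miscellaneous = misc,
                   log = "maxreport.log")
  build_index(manifest, out_dir)
  invisible(manifest)
}
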