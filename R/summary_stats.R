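#' Descriptive statistics over the identification results
#'
#' Counts the reported protein groups, peptides and MS/MS scans; per PTM the
#' sites and the distinct supporting spectra, peptides and protein groups;
#' the distribution of all-peptide and unique-peptide counts over protein
#' groups; and, per PTM, the distribution of site counts over proteins.
#'
#' @param proteins,peptides,msms The reported tables.
#' @param site_tables Named list of site tables.
#' @return Object of class `stats_summary`.
#' @export
compute_identification_stats <- function(proteins, peptides, msms,
                                         site_tables = list()) {
  int_dist <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(data.frame(n = integer(), count = integer()))
    tb <- table(x)
    data.frame(n = as.integer(names(tb)), count = as.integer(tb))
  }
  ptm_stats <- do.call(rbind, lapply(names(site_tables), function(ptm) {
    st <- site_tables[[ptm]]
    data.frame(
      ptm = ptm, sites = nrow(st),
      spectra = length(unique(unlist(lapply(st[["MS/MS IDs"]], split_ids)))),
      peptides = length(unique(st[["Sequence"]][nzchar(st[["Sequence"]])])),
      protein_groups = length(unique(st[["Protein group IDs"]])),
      specific = sum(st[["Site class"]] == "specific"),
      ambiguous = sum(st[["Site class"]] == "ambiguous"),
      stringsAsFactors = FALSE)
  }))
  if (is.null(ptm_stats))
    ptm_stats <- data.frame(ptm = character(), sites = integer(),
                            spectra = integer(), peptides = integer(),
                            protein_groups = integer(), specific = integer(),
                            ambiguous = integer())
  site_dists <- lapply(site_tables, function(st) {
    if (!nrow(st)) return(data.frame(n = integer(), count = integer()))
    int_dist(as.integer(table(st[["Protein"]])))
  })
  structure(list(
    counts = list(protein_groups = nrow(proteins), peptides = nrow(peptides),
                  spectra = nrow(msms)),
    ptm_stats = ptm_stats,
    peptide_count_dist = list(
      all = int_dist(as.integer(num_or_na(proteins[["Peptides"]]))),
      unique = int_dist(as.integer(num_or_na(proteins[["Unique peptides"]])))),
    site_count_dists = site_dists), class = "stats_summary")
}

#' @export
print.stats_summary <- function(x, ...) {
  cat("Identification summary:\n")
  cat(sprintf("  protein groups %d, peptides %d, MS/MS spectra %d\n",
              x$counts$protein_groups, x$counts$peptides, x$counts$spectra))
  if (nrow(x$ptm_stats)) print.data.frame(x$ptm_stats)
  invisible(x)
}

#' Replication assignment matrices
#'
#' For designs with at least two replicates, builds one presence matrix per
#' reporting level (protein group, peptide, site, MS/MS scan): entry 1 when
#' the entity has at least one supporting scan in that replicate. With a
#' single replicate nothing is produced (logged note).
#'
#' @param proteins,peptides,msms Reported tables.
#' @param site_tables Named list of site tables.
#' @param design An [load_experimental_design()].
#' @return Named list of data frames (`id` column then one 0/1 column per
#'   replicate), or `NULL` for single-replicate designs.
#' @export
compute_replication_assignment <- function(proteins, peptides, msms,
                                           site_tables, design) {
  reps <- attr(design, "replicates")
  if (length(reps) < 2L) {
    mr_log_info("single replicate design; replication assignment skipped")
    return(NULL)
  }
  scan_rep <- design$replicate[match(msms[["Raw file"]], design$raw_file)]
  scan_rep[is.na(scan_rep)] <- "default"
  scan_id <- msms[["id"]]
  presence <- function(ids, scans_of) {
    m <- matrix(0L, length(ids), length(reps), dimnames = list(NULL, reps))
    for (i in seq_along(ids)) {
      r <- unique(scan_rep[match(scans_of[[i]], scan_id)])
      r <- r[!is.na(r)]
      m[i, match(r, reps)] <- 1L
    }
    cbind(data.frame(id = ids, stringsAsFactors = FALSE), as.data.frame(m))
  }
  sg <- scan_group_map(msms, proteins)
  out <- list(
    protein_groups = presence(proteins[["id"]],
      split(scan_id, factor(sg$group, levels = proteins[["id"]]))),
    peptides = presence(peptides[["Sequence"]],
      split(scan_id, factor(msms[["Sequence"]],
                            levels = peptides[["Sequence"]]))),
    msms = presence(scan_id, as.list(scan_id)))
  for (ptm in names(site_tables)) {
    st <- site_tables[[ptm]]
    if (!nrow(st)) next
    out[[paste0("sites_", ptm)]] <- presence(
      paste0(st[["Protein"]], "@", st[["Position"]]),
      lapply(st[["MS/MS IDs"]], split_ids))
  }
  out
}

## --- chart emission ---------------------------------------------------------
## Charts are presentation only: every chart is written as an SVG plus a
## same-named TSV holding the authoritative numeric series.

svg_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

svg_bar_chart <- function(path, labels, values, title) {
  w <- 640; h <- 400; pad <- 60
  n <- length(values)
  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">', w, h),
    sprintf('<text x="%d" y="24" font-size="16" text-anchor="middle">%s</text>',
            w %/% 2, svg_escape(title)))
  if (n > 0) {
    vmax <- max(values, 1)
    bw <- (w - 2 * pad) / n
    for (i in seq_len(n)) {
      bh <- (h - 2 * pad) * values[i] / vmax
      x <- pad + (i - 1) * bw
      lines <- c(lines,
        sprintf('<rect x="%.1f" y="%.1f" width="%.1f" height="%.1f" fill="#4477aa"/>',
                x + bw * 0.1, h - pad - bh, bw * 0.8, bh),
        sprintf('<text x="%.1f" y="%.1f" font-size="11" text-anchor="middle">%s</text>',
                x + bw / 2, h - pad + 14, svg_escape(labels[i])),
        sprintf('<text x="%.1f" y="%.1f" font-size="11" text-anchor="middle">%s</text>',
                x + bw / 2, h - pad - bh - 4, format(values[i])))
    }
  }
  writeLines(c(lines, "</svg>"), path)
  invisible(path)
}

svg_pie_chart <- function(path, labels, values, title) {
  w <- 480; h <- 400; cx <- 200; cy <- 210; r <- 140
  total <- sum(values)
  palette <- rep(c("#4477aa", "#ee6677", "#228833", "#ccbb44", "#66ccee",
                   "#aa3377", "#bbbbbb"), length.out = max(length(values), 1))
  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">', w, h),
    sprintf('<text x="%d" y="24" font-size="16" text-anchor="middle">%s</text>',
            w %/% 2, svg_escape(title)))
  if (total > 0) {
    a0 <- -pi / 2
    for (i in seq_along(values)) {
      if (values[i] <= 0) next
      a1 <- a0 + 2 * pi * values[i] / total
      large <- as.integer((a1 - a0) > pi)
      if (values[i] == total) {
        lines <- c(lines, sprintf(
          '<circle cx="%d" cy="%d" r="%d" fill="%s"/>', cx, cy, r, palette[i]))
      } else {
        lines <- c(lines, sprintf(
          '<path d="M%d,%d L%.2f,%.2f A%d,%d 0 %d 1 %.2f,%.2f Z" fill="%s"/>',
          cx, cy, cx + r * cos(a0), cy + r * sin(a0), r, r, large,
          cx + r * cos(a1), cy + r * sin(a1), palette[i]))
      }
      a0 <- a1
    }
    for (i in seq_along(values))
      lines <- c(lines, sprintf(
        '<rect x="360" y="%d" width="12" height="12" fill="%s"/><text x="378" y="%d" font-size="12">%s (%.1f%%)</text>',
        50 + 20 * i, palette[i], 61 + 20 * i, svg_escape(labels[i]),
        100 * values[i] / total))
  }
  writeLines(c(lines, "</svg>"), path)
  invisible(path)
}

#' Write statistics charts (SVG) with authoritative TSV series
#'
#' Every chart `<name>.svg` has a twin `<name>.tsv` carrying the plotted
#' series; tests and downstream consumers should read the TSV.
#'
#' @param summary A [compute_identification_stats()] result.
#' @param quant Optional [quantify_project()] result.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written file paths.
#' @export
emit_charts <- function(summary, quant = NULL, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(name, labels, values, title, type = "bar") {
    tsv <- file.path(out_dir, paste0(name, ".tsv"))
    svg <- file.path(out_dir, paste0(name, ".svg"))
    write_table(data.frame(label = labels, value = values,
                           stringsAsFactors = FALSE), tsv)
    if (type == "bar") svg_bar_chart(svg, labels, values, title)
    else svg_pie_chart(svg, labels, values, title)
    written <<- c(written, tsv, svg)
  }
  emit("identification_summary",
       c("Protein groups", "Peptides", "Spectra"),
       c(summary$counts$protein_groups, summary$counts$peptides,
         summary$counts$spectra),
       "Identification summary")
  pd <- summary$peptide_count_dist
  if (nrow(pd$all))
    emit("peptides_per_group", as.character(pd$all$n), pd$all$count,
         "Peptides per protein group")
  if (nrow(pd$unique))
    emit("unique_peptides_per_group", as.character(pd$unique$n),
         pd$unique$count, "Unique peptides per protein group")
  if (nrow(summary$ptm_stats)) {
    for (i in seq_len(nrow(summary$ptm_stats))) {
      ps <- summary$ptm_stats[i, ]
      safe <- gsub("[^A-Za-z0-9]+", "_", ps$ptm)
      emit(paste0("ptm_summary_", safe),
           c("Sites", "Spectra", "Peptides", "Protein groups"),
           c(ps$sites, ps$spectra, ps$peptides, ps$protein_groups),
           paste("Identification summary:", ps$ptm))
      if (ps$sites > 0)
        emit(paste0("site_class_", safe), c("specific", "ambiguous"),
             c(ps$specific, ps$ambiguous),
             paste("Site classes:", ps$ptm), type = "pie")
      sd <- summary$site_count_dists[[ps$ptm]]
      if (!is.null(sd) && nrow(sd))
        emit(paste0("sites_per_protein_", safe), as.character(sd$n),
             sd$count, paste("Sites per protein:", ps$ptm))
    }
  }
  if (!is.null(quant)) {
    emit("calibration_factors", quant$channels,
         as.numeric(unclass(quant$calibration)),
         "Channel calibration factors")
    emit("quantified_counts", c("Protein groups", "Peptides", "Sites"),
         c(nrow(quant$protein$merged %||% data.frame()),
           nrow(quant$peptide$merged %||% data.frame()),
           nrow(quant$site$merged %||% data.frame())),
         "Quantified entities")
  }
  written
}
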