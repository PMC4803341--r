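# Libra-style reporter-ion quantification. Order of operations is frozen:
# isotope-impurity correction -> channel calibration -> low-intensity filter
# -> per-spectrum normalization -> grouping by entity -> outlier rejection
# -> median/mean/SD summary.

#' Extract reporter intensities from msms.txt
#'
#' Collects the `Reporter intensity <i>` columns into a numeric matrix
#' (missing values become 0 — MaxQuant writes 0 for undetected reporters).
#'
#' @param msms The `msms.txt` table.
#' @return List with `intensities` (n_scans x n_channels matrix), `scan_id`,
#'   `raw_file`; or `NULL` when no reporter columns are present.
#' @export
reporter_intensities <- function(msms) {
  cols <- grep("^Reporter intensity [0-9]+$", names(msms), value = TRUE)
  if (!length(cols)) return(NULL)
  ord <- order(as.integer(sub("^Reporter intensity ", "", cols)))
  cols <- cols[ord]
  m <- vapply(cols, function(c) num_or_na(msms[[c]]), numeric(nrow(msms)))
  m <- matrix(m, nrow = nrow(msms),
              dimnames = list(NULL, sub("^Reporter intensity ", "Reporter ", cols)))
  m[is.na(m)] <- 0
  list(intensities = m, scan_id = msms[["id"]],
       raw_file = msms[["Raw file"]])
}

#' Correct reporter intensities for isotope impurity
#'
#' With observed = M %*% true (M the correction matrix, columns = true
#' channel), the true signal is recovered by solving the linear system;
#' negative solutions — possible with noisy low signals — are clamped to 0
#' and counted in the log. An identity matrix leaves intensities unchanged.
#'
#' @param intensities Numeric vector (one spectrum) or matrix (spectra in
#'   rows) of observed intensities.
#' @param cm A [correction_matrix()], or `NULL` for no correction.
#' @return Corrected intensities, same shape as the input.
#' @export
apply_correction <- function(intensities, cm) {
  if (is.null(cm)) return(intensities)
  vec <- is.null(dim(intensities))
  m <- if (vec) matrix(intensities, nrow = 1) else intensities
  if (ncol(m) != nrow(cm$values))
    stop("reporter vector length ", ncol(m), " does not match correction ",
         "matrix dimension ", nrow(cm$values))
  det_ok <- tryCatch({solve(cm$values); TRUE},
                     error = function(e) FALSE)
  if (!det_ok) stop("correction matrix is singular; cannot correct intensities")
  true <- t(solve(cm$values, t(m)))
  n_neg <- sum(true < 0)
  if (n_neg > 0) {
    mr_log_info(sprintf(
      "impurity correction clamped %d negative value(s) to 0", n_neg))
    true[true < 0] <- 0
  }
  dimnames(true) <- dimnames(m)
  if (vec) drop(true) else true
}

#' Compute per-channel calibration factors
#'
#' The overall intensity of every reporter channel is calibrated to be
#' equal: channel c gets the multiplicative factor
#' `mean(channel totals) / total_c`, so after application all channel totals
#' equal the across-channel mean. Factors are exported with the statistics as
#' a view of the experimental bias.
#'
#' @param intensities Matrix of (corrected) intensities, spectra in rows.
#' @return Numeric vector of positive factors, one per channel, of class
#'   `channel_calibration`.
#' @export
compute_calibration_factors <- function(intensities) {
  totals <- colSums(intensities)
  if (any(totals <= 0))
    stop("channel(s) with zero total intensity, cannot calibrate: ",
         paste(colnames(intensities)[totals <= 0], collapse = ", "))
  structure(mean(totals) / totals, class = "channel_calibration")
}

#' Normalize spectra to reporter fractions
#'
#' Each spectrum's reporter intensities are divided by their sum, so the
#' fractions of an included spectrum sum to 1. Spectra whose total is at or
#' below the low-intensity threshold are excluded (counted in the log, not
#' an error).
#'
#' @param intensities Matrix of corrected, calibrated intensities.
#' @param low_intensity_threshold Exclusion threshold on the per-spectrum
#'   total (default 0: only non-positive totals are dropped).
#' @return List with `fractions` (matrix over included spectra), `included`
#'   (logical vector over input rows), `n_excluded`.
#' @export
normalize_spectra <- function(intensities, low_intensity_threshold = 0) {
  totals <- rowSums(intensities)
  included <- totals > low_intensity_threshold
  n_excl <- sum(!included)
  if (n_excl > 0)
    mr_log_info(sprintf(
      "%d spectrum/spectra at or below the low-intensity threshold excluded",
      n_excl))
  fr <- intensities[included, , drop = FALSE] / totals[included]
  list(fractions = fr, included = included, n_excluded = n_excl)
}

#' Reject outlying fractions within a group of spectra
#'
#' Per channel independently: values differing from the channel mean by more
#' than `k` population standard deviations are removed, iterating until no
#' further value is removed so that re-running the rejection on the retained
#' set is a no-op. Groups of fewer than 3 values, and channels with zero
#' spread, are left untouched.
#'
#' @param values Numeric vector (one channel's fractions across a group's
#'   spectra).
#' @param k Sigma multiplier (default 1.96).
#' @return Logical vector: `TRUE` for retained values.
#' @export
remove_outliers <- function(values, k = 1.96) {
  keep <- rep(TRUE, length(values))
  repeat {
    n <- sum(keep)
    if (n < 3L) break
    x <- values[keep]
    mu <- mean(x)
    sigma <- sqrt(mean((x - mu)^2))  # population SD
    if (sigma == 0) break
    out <- keep & abs(values - mu) > k * sigma
    if (!any(out)) break
    keep <- keep & !out
  }
  keep
}

#' Summarize a group of spectra into per-channel statistics
#'
#' After outlier rejection the median and mean fractions are recalculated
#' per channel and reported as the relative expression values, together with
#' the population standard deviation. A channel left with no retained value
#' falls back to its pre-rejection values and is flagged.
#'
#' @param fractions Matrix of the group's spectrum fractions (spectra in
#'   rows, channels in columns).
#' @param k Outlier sigma multiplier.
#' @return List with numeric vectors `median`, `mean`, `sd` (population),
#'   `n_used`, integer `n_removed`, and character `fallback_channels`.
#' @export
summarize_group <- function(fractions, k = 1.96) {
  nch <- ncol(fractions)
  med <- mu <- sdv <- numeric(nch)
  n_used <- integer(nch)
  n_removed <- 0L
  fallback <- character()
  for (c in seq_len(nch)) {
    v <- fractions[, c]
    keep <- remove_outliers(v, k)
    if (!any(keep)) {
      fallback <- c(fallback, colnames(fractions)[c] %||% as.character(c))
      keep <- rep(TRUE, length(v))
    }
    x <- v[keep]
    n_removed <- n_removed + sum(!keep)
    med[c] <- stats::median(x)
    mu[c] <- mean(x)
    sdv[c] <- sqrt(mean((x - mu[c])^2))
    n_used[c] <- length(x)
  }
  names(med) <- names(mu) <- names(sdv) <- names(n_used) <- colnames(fractions)
  list(median = med, mean = mu, sd = sdv, n_used = n_used,
       n_removed = n_removed, fallback_channels = fallback)
}

## --- entity assignment and the full quantification -------------------------

# per-scan resolved protein group and peptide-uniqueness, cached per distinct
# "Protein group IDs" string
scan_group_map <- function(msms, groups) {
  keys <- msms[["Protein group IDs"]]
  uk <- unique(keys)
  resolved <- vapply(uk, function(k) {
    ids <- split_ids(k)
    resolve_best_group(ids, groups)
  }, character(1))
  n_retained <- vapply(uk, function(k)
    sum(split_ids(k) %in% groups[["id"]]), integer(1))
  i <- match(keys, uk)
  list(group = resolved[i], unique_pep = n_retained[i] == 1L)
}

#' Libra quantification of a MaxQuant project at all levels
#'
#' Runs the full reporter-ion pipeline on the identified spectra and
#' summarizes relative expression per protein group, peptide and PTM site,
#' separately per replicate, then merges replicates by entity id (full outer
#' join; no cross-replicate pooling). Protein-level grouping honours
#' `use_unique_peptides_only` (spectra from peptides mapping to more than one
#' reported group are skipped); site-level grouping uses specific sites only.
#'
#' @param msms The `msms.txt` table.
#' @param groups The reported protein-group table.
#' @param site_tables Named list of site tables ([build_site_table()]).
#' @param design An [load_experimental_design()] object.
#' @param config A [reporting_config()]; `calibrate_channels = FALSE` skips
#'   the application of the calibration factors (they are still computed and
#'   exported).
#' @param cm Optional [correction_matrix()].
#' @param peptides Optional reported peptide table; when given, peptide-level
#'   quantification is restricted to its `Sequence` values.
#' @return Object of class `libra_quant`: list with `calibration`,
#'   `n_excluded_low`, `channels`, and per level (`protein`, `peptide`,
#'   `site`) a list of per-replicate tables plus a `merged` table; `NULL`
#'   when `msms` has no reporter columns.
#' @export
quantify_project <- function(msms, groups, site_tables = list(),
                             design, config, cm = NULL, peptides = NULL) {
  rep_data <- reporter_intensities(msms)
  if (is.null(rep_data)) {
    mr_log_info("no reporter intensity columns found; quantification skipped")
    return(NULL)
  }
  corrected <- apply_correction(rep_data$intensities, cm)
  calib <- compute_calibration_factors(corrected)
  calibrated <- if (config$calibrate_channels %||% TRUE)
    sweep(corrected, 2, unclass(calib), "*") else corrected
  norm <- normalize_spectra(calibrated, config$low_intensity_threshold)
  fr <- norm$fractions
  scan_ids <- rep_data$scan_id[norm$included]
  raw_files <- rep_data$raw_file[norm$included]
  replicate <- design$replicate[match(raw_files, design$raw_file)]
  replicate[is.na(replicate)] <- "default"

  sg <- scan_group_map(msms, groups)
  group_of <- sg$group[norm$included]
  unique_of <- sg$unique_pep[norm$included]
  seq_of <- msms[["Sequence"]][norm$included]

  # entity membership: entity id -> scan ids (within all spectra included)
  protein_members <- function() {
    keep <- !is.na(group_of) & (!config$use_unique_peptides_only | unique_of)
    split(which(keep), group_of[keep])
  }
  peptide_members <- function() {
    keep <- !is.na(group_of)
    if (!is.null(peptides))
      keep <- keep & seq_of %in% peptides[["Sequence"]]
    split(which(keep), seq_of[keep])
  }
  site_members <- function() {
    out <- list()
    for (ptm in names(site_tables)) {
      st <- site_tables[[ptm]]
      if (!nrow(st)) next
      st <- st[st[["Site class"]] == "specific", , drop = FALSE]
      for (i in seq_len(nrow(st))) {
        sid <- paste0(ptm, ":", st[["Protein"]][i], "@", st[["Position"]][i])
        idx <- which(scan_ids %in% split_ids(st[["MS/MS IDs"]][i]))
        if (length(idx)) out[[sid]] <- idx
      }
    }
    out
  }
  levels <- list(protein = protein_members(), peptide = peptide_members(),
                 site = site_members())

  reps <- attr(design, "replicates") %||% unique(replicate)
  reps <- intersect(reps, unique(replicate))
  if (!length(reps)) reps <- unique(replicate)

  chans <- colnames(fr)
  quant_cols <- c("id", "Spectra used", "Outliers removed",
                  "Fallback channels", paste("Median", chans),
                  paste("Mean", chans), paste("SD", chans))
  quant_one <- function(members, rep_label) {
    rows <- list()
    for (ent in names(members)) {
      idx <- members[[ent]]
      idx <- idx[replicate[idx] == rep_label]
      if (!length(idx)) next
      s <- summarize_group(fr[idx, , drop = FALSE], config$outlier_sigma)
      rows[[ent]] <- data.frame(
        id = ent, "Spectra used" = length(idx),
        "Outliers removed" = s$n_removed,
        "Fallback channels" = paste(s$fallback_channels, collapse = ";"),
        t(setNames(s$median, paste("Median", chans))),
        t(setNames(s$mean, paste("Mean", chans))),
        t(setNames(s$sd, paste("SD", chans))),
        check.names = FALSE, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      out <- as.data.frame(setNames(
        c(list(character(), integer(), integer(), character()),
          rep(list(numeric()), 3 * length(chans))), quant_cols),
        check.names = FALSE)
      names(out) <- quant_cols
    }
    rownames(out) <- NULL
    out
  }

  merge_reps <- function(tabs) {
    merged <- NULL
    for (r in names(tabs)) {
      t <- tabs[[r]]
      if (ncol(t) > 1L)
        names(t)[-1] <- paste0(names(t)[-1], " [", r, "]")
      merged <- if (is.null(merged)) t
                else merge(merged, t, by = "id", all = TRUE, sort = FALSE)
    }
    if (!is.null(merged) && nrow(merged))
      merged <- merged[order(merged$id), , drop = FALSE]
    rownames(merged) <- NULL
    merged
  }

  result <- list(calibration = calib, n_excluded_low = norm$n_excluded,
                 channels = colnames(fr))
  for (lvl in names(levels)) {
    tabs <- lapply(setNames(reps, reps), function(r)
      quant_one(levels[[lvl]], r))
    result[[lvl]] <- list(per_replicate = tabs, merged = merge_reps(tabs))
  }
  class(result) <- "libra_quant"
  result
}

#' @export
print.libra_quant <- function(x, ...) {
  cat("Libra quantification over", length(x$channels), "channels\n")
  for (lvl in c("protein", "peptide", "site"))
    cat(sprintf("  %-8s %d entity(ies) quantified\n", lvl,
                nrow(x[[lvl]]$merged %||% data.frame())))
  invisible(x)
}
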