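# Synthetic MaxQuant-style projects with planted ground truth. The generator
# emulates the tab-separated combined/txt tables of a MaxQuant run (one
# chosen header dialect, "mq15"; a second smaller dialect, "mq12", renames
# the contaminant marker column as older releases did), a UniProt-style
# FASTA with its parse-rule file, an identity correction matrix and a
# reporting configuration, so the whole pipeline runs without instrument
# data.

.mr_aa <- c("A","C","D","E","F","G","H","K","N","P","Q","R","S","T","V","W","Y")
.mr_nterm_ptm <- "Acetyl (Protein N-term)"
.mr_ox_ptm <- "Oxidation (M)"

#' Specification of a synthetic MaxQuant project
#'
#' Defaults describe the desk-scale study conditions used throughout the
#' test suite: 20 proteins with 3 peptides each and 10 spectra per peptide
#' (30 spectra per protein), a 6-channel isobaric design, multiplicative
#' lognormal reporter noise with 10% CV, two technical replicates, and a
#' small admixture of decoy and contaminant groups.
#'
#' @param n_proteins Number of clean (reported) single-accession proteins.
#' @param peptides_per_protein Peptides generated per protein.
#' @param spectra_per_peptide MS/MS spectra per peptide.
#' @param n_channels Reporter channels (e.g. 6 for TMT6).
#' @param profiles Planted per-channel relative abundance, either a single
#'   vector of length `n_channels` applied to every protein or an
#'   `n_proteins x n_channels` matrix; default flat (all channels equal).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   reporter noise (default 0.1).
#' @param replicates Named character vector raw file -> replicate label.
#' @param n_decoys,n_contaminants Flagged protein groups to add.
#' @param n_multi_accession Groups carrying a second, less-supported
#'   accession (exercises group minimization).
#' @param nterm_sites Optional data frame with columns `position` (1 or 2)
#'   and `prob` (localization probability, `NA` for absent) planting protein
#'   N-terminal acetylation sites on the first proteins.
#' @param n_oxidation_sites Oxidation (M) sites planted (with a MaxQuant-style
#'   site table); probabilities recycled from `oxidation_probs`.
#' @param oxidation_probs Localization probabilities for planted oxidation
#'   sites.
#' @param n_reverse_oxidation_sites Extra decoy rows added to the oxidation
#'   site table.
#' @param dialect Column-title dialect, `"mq15"` (default) or `"mq12"`.
#' @param seed Random seed; a fixed seed makes the generated directory
#'   byte-identical across runs.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_proteins = 20L, peptides_per_protein = 3L,
                         spectra_per_peptide = 10L, n_channels = 6L,
                         profiles = NULL, noise_cv = 0.1,
                         replicates = c(raw1 = "R1", raw2 = "R2"),
                         n_decoys = 2L, n_contaminants = 1L,
                         n_multi_accession = 1L, nterm_sites = NULL,
                         n_oxidation_sites = 0L, oxidation_probs = 0.9,
                         n_reverse_oxidation_sites = 0L,
                         dialect = c("mq15", "mq12"), seed = 1L) {
  dialect <- match.arg(dialect)
  if (is.null(profiles)) profiles <- rep(1, n_channels)
  if (is.null(dim(profiles)))
    profiles <- matrix(profiles, n_proteins, n_channels, byrow = TRUE)
  stopifnot(nrow(profiles) == n_proteins, ncol(profiles) == n_channels,
            all(profiles >= 0), noise_cv >= 0, n_proteins >= 1)
  if (!is.null(nterm_sites))
    stopifnot(all(nterm_sites$position %in% 1:2),
              nrow(nterm_sites) <= n_proteins)
  structure(list(n_proteins = as.integer(n_proteins),
                 peptides_per_protein = as.integer(peptides_per_protein),
                 spectra_per_peptide = as.integer(spectra_per_peptide),
                 n_channels = as.integer(n_channels), profiles = profiles,
                 noise_cv = noise_cv, replicates = replicates,
                 n_decoys = as.integer(n_decoys),
                 n_contaminants = as.integer(n_contaminants),
                 n_multi_accession = as.integer(n_multi_accession),
                 nterm_sites = nterm_sites,
                 n_oxidation_sites = as.integer(n_oxidation_sites),
                 oxidation_probs = oxidation_probs,
                 n_reverse_oxidation_sites = as.integer(n_reverse_oxidation_sites),
                 dialect = dialect, seed = as.integer(seed)),
            class = "fixture_spec")
}

random_sequence <- function(len) paste(sample(.mr_aa, len, TRUE), collapse = "")

fmt_num <- function(x) formatC(x, format = "f", digits = 2, drop0trailing = FALSE)

#' Generate a synthetic MaxQuant project directory
#'
#' Writes `combined/txt/{proteinGroups,peptides,msms,summary}.txt`, an
#' optional `Oxidation (M)Sites.txt`, a UniProt-style FASTA with its
#' parse-rule file, an identity correction matrix and a matching reporting
#' configuration, and returns the planted ground truth for assertions.
#'
#' Reporter intensities are drawn as
#' `base x profile[protein, channel] x lognormal(CV)`; a profile entry of 0
#' plants true zero expression in that channel.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Project directory to create.
#' @return Invisibly, a list: `dir`, `paths` (config, fasta, rule,
#'   correction matrix, txt folder) and `truth` (planted counts, profiles,
#'   site positions/probabilities, replicate layout).
#' @export
generate_project <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  txt <- file.path(out_dir, "combined", "txt")
  dir.create(txt, recursive = TRUE, showWarnings = FALSE)
  contaminant_col <- if (spec$dialect == "mq12") "Contaminant"
                     else "Potential contaminant"

  np <- spec$n_proteins
  ox_pos <- 40L  # every sequence carries an M here so oxidation can be planted
  seqs <- vapply(seq_len(np), function(i) {
    s <- strsplit(random_sequence(80L), "")[[1]]
    s[1] <- "M"; s[ox_pos] <- "M"
    paste(s, collapse = "")
  }, character(1))
  acc <- sprintf("SYN%04d", seq_len(np))
  genes <- sprintf("GENE%04d", seq_len(np))

  nt <- spec$nterm_sites
  nt_protein_idx <- if (is.null(nt)) integer() else seq_len(nrow(nt))

  # peptides: peptide 1 covers the N-terminus (from residue 1, or residue 2
  # for planted Met-cleaved sites); the rest are consecutive internal chunks
  pep_len <- 10L
  peptide_seq <- function(p, j) {
    if (j == 1L) {
      start <- if (p %in% nt_protein_idx && nt$position[match(p, nt_protein_idx)] == 2L)
        2L else 1L
    } else start <- 2L + (j - 1L) * (pep_len + 2L)
    substr(seqs[p], start, start + pep_len - 1L)
  }

  ppp <- spec$peptides_per_protein
  spp <- spec$spectra_per_peptide
  raw_files <- names(spec$replicates)

  ## --- assemble msms / peptides / proteinGroups row by row ---------------
  msms_rows <- list(); pep_rows <- list(); grp_rows <- list()
  msms_id <- -1L; pep_id <- -1L; grp_id <- -1L
  sln <- if (spec$noise_cv > 0) sqrt(log(1 + spec$noise_cv^2)) else 0
  draw_intensities <- function(profile) {
    base <- stats::rlnorm(1, log(2e5), 0.5)
    noise <- if (sln > 0) stats::rlnorm(length(profile), -sln^2 / 2, sln)
             else rep(1, length(profile))
    base * profile * noise
  }

  add_msms <- function(raw, seqn, mods, prots, gid, profile, prob = NA,
                       reverse = "", contam = "") {
    msms_id <<- msms_id + 1L
    ints <- draw_intensities(profile)
    msms_rows[[length(msms_rows) + 1L]] <<- c(
      `Raw file` = raw, `Scan number` = as.character(10000L + msms_id),
      Sequence = seqn,
      `Modified sequence` = paste0("_", seqn, "_"),
      Modifications = mods, Proteins = prots,
      `Protein group IDs` = gid,
      Score = fmt_num(stats::runif(1, 60, 140)),
      setNames(fmt_num(ints),
               paste("Reporter intensity", seq_along(profile) - 1L)),
      `Acetyl (Protein N-term) Probabilities` =
        if (grepl("Protein N-term", mods) && !is.na(prob))
          paste0(substr(seqn, 1, 1), "(", format(prob), ")",
                 substr(seqn, 2, nchar(seqn))) else "",
      Masses = "200.10;300.20;400.30", Matches = "b2;y1;y2",
      Intensities = "1500;2200;1800",
      Reverse = reverse, Contaminant = contam,
      id = as.character(msms_id))
    msms_id
  }

  nt_truth <- NULL
  for (p in seq_len(np)) {
    grp_id <- grp_id + 1L
    accs <- acc[p]
    uniq_counts <- as.character(ppp)
    all_counts <- as.character(ppp)
    if (p <= spec$n_multi_accession) {
      accs <- paste0(acc[p], ";", acc[p], "b")
      uniq_counts <- paste0(ppp, ";", max(ppp - 2L, 0L))
      all_counts <- paste0(ppp, ";", max(ppp - 1L, 0L))
    }
    grp_scans <- integer()
    for (j in seq_len(ppp)) {
      pseq <- peptide_seq(p, j)
      is_nt <- p %in% nt_protein_idx && j == 1L
      mods <- if (is_nt) .mr_nterm_ptm else "Unmodified"
      prob <- if (is_nt) nt$prob[match(p, nt_protein_idx)] else NA
      scans <- integer()
      for (s in seq_len(spp)) {
        raw <- raw_files[((s - 1L) %% length(raw_files)) + 1L]
        scans <- c(scans, add_msms(raw, pseq, mods, accs,
                                   as.character(grp_id), spec$profiles[p, ],
                                   prob))
      }
      grp_scans <- c(grp_scans, scans)
      pep_id <- pep_id + 1L
      pep_rows[[length(pep_rows) + 1L]] <- c(
        Sequence = pseq, Proteins = accs,
        `Protein group IDs` = as.character(grp_id),
        `Unique (Groups)` = "yes",
        Score = fmt_num(stats::runif(1, 60, 140)),
        Reverse = "", Contaminant = "",
        id = as.character(pep_id),
        `MS/MS IDs` = paste(scans, collapse = ";"))
    }
    if (p %in% nt_protein_idx) {
      k <- match(p, nt_protein_idx)
      nt_truth <- rbind(nt_truth, data.frame(
        accession = acc[p], position = nt$position[k], prob = nt$prob[k],
        stringsAsFactors = FALSE))
    }
    grp_rows[[length(grp_rows) + 1L]] <- c(
      `Protein IDs` = accs, `Majority protein IDs` = acc[p],
      `Peptide counts (all)` = all_counts,
      `Peptide counts (unique)` = uniq_counts,
      Peptides = as.character(ppp), `Unique peptides` = as.character(ppp),
      Score = fmt_num(stats::runif(1, 50, 150)),
      Reverse = "", Contaminant = "",
      id = as.character(grp_id),
      `MS/MS IDs` = paste(grp_scans, collapse = ";"))
  }

  ## decoy and contaminant groups (flagged; removed by the report filters)
  add_flagged <- function(n, prefix, reverse, contam) {
    for (k in seq_len(n)) {
      grp_id <<- grp_id + 1L
      a <- paste0(prefix, sprintf("SYNX%03d", grp_id))
      pseq <- random_sequence(pep_len)
      sid <- add_msms(raw_files[1], pseq, "Unmodified", a,
                      as.character(grp_id), rep(1, spec$n_channels),
                      reverse = reverse, contam = contam)
      pep_id <<- pep_id + 1L
      pep_rows[[length(pep_rows) + 1L]] <<- c(
        Sequence = pseq, Proteins = a,
        `Protein group IDs` = as.character(grp_id),
        `Unique (Groups)` = "yes", Score = fmt_num(80),
        Reverse = reverse, Contaminant = contam,
        id = as.character(pep_id), `MS/MS IDs` = as.character(sid))
      grp_rows[[length(grp_rows) + 1L]] <<- c(
        `Protein IDs` = a, `Majority protein IDs` = a,
        `Peptide counts (all)` = "1", `Peptide counts (unique)` = "1",
        Peptides = "1", `Unique peptides` = "1", Score = fmt_num(40),
        Reverse = reverse, Contaminant = contam,
        id = as.character(grp_id), `MS/MS IDs` = as.character(sid))
    }
  }
  add_flagged(spec$n_decoys, "REV__", "+", "")
  add_flagged(spec$n_contaminants, "CON__", "", "+")

  ## planted oxidation sites with a MaxQuant-style site table
  ox_truth <- NULL; ox_rows <- list()
  if (spec$n_oxidation_sites > 0L) {
    probs <- rep(spec$oxidation_probs, length.out = spec$n_oxidation_sites)
    site_id <- -1L
    for (k in seq_len(spec$n_oxidation_sites)) {
      p <- ((k - 1L) %% np) + 1L
      pseq <- substr(seqs[p], ox_pos - 4L, ox_pos + 5L)
      sid <- add_msms(raw_files[1], pseq, .mr_ox_ptm, acc[p],
                      as.character(p - 1L), spec$profiles[p, ])
      pep_id <- pep_id + 1L
      pep_rows[[length(pep_rows) + 1L]] <- c(
        Sequence = pseq, Proteins = acc[p],
        `Protein group IDs` = as.character(p - 1L),
        `Unique (Groups)` = "yes", Score = fmt_num(90),
        Reverse = "", Contaminant = "",
        id = as.character(pep_id), `MS/MS IDs` = as.character(sid))
      site_id <- site_id + 1L
      ox_rows[[k]] <- c(
        Proteins = acc[p], Protein = acc[p],
        Position = as.character(ox_pos), `Amino acid` = "M",
        `Localization prob` = format(probs[k]),
        Score = fmt_num(stats::runif(1, 60, 140)),
        `Protein group IDs` = as.character(p - 1L),
        `MS/MS IDs` = as.character(sid),
        Reverse = "", Contaminant = "", id = as.character(site_id))
      ox_truth <- rbind(ox_truth, data.frame(
        accession = acc[p], position = ox_pos, prob = probs[k],
        stringsAsFactors = FALSE))
    }
    for (k in seq_len(spec$n_reverse_oxidation_sites)) {
      site_id <- site_id + 1L
      ox_rows[[length(ox_rows) + 1L]] <- c(
        Proteins = paste0("REV__", acc[1]), Protein = paste0("REV__", acc[1]),
        Position = "10", `Amino acid` = "M", `Localization prob` = "0.99",
        Score = fmt_num(50), `Protein group IDs` = "",
        `MS/MS IDs` = "", Reverse = "+", Contaminant = "",
        id = as.character(site_id))
    }
  }

  rows_to_df <- function(rows) {
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(df) <- sub("^Contaminant$", contaminant_col, names(df))
    df
  }
  write_table(rows_to_df(grp_rows), file.path(txt, "proteinGroups.txt"))
  write_table(rows_to_df(pep_rows), file.path(txt, "peptides.txt"))
  write_table(rows_to_df(msms_rows), file.path(txt, "msms.txt"))
  if (length(ox_rows))
    write_table(rows_to_df(ox_rows),
                file.path(txt, paste0(.mr_ox_ptm, "Sites.txt")))
  write_table(data.frame(
    "Raw file" = c(raw_files, "Total"),
    "Experiment" = c(unname(spec$replicates), ""),
    check.names = FALSE, stringsAsFactors = FALSE),
    file.path(txt, "summary.txt"))

  ## FASTA + parse rule (UniProt dialect), incl. secondary accessions
  fasta <- file.path(out_dir, "sequences.fasta")
  lines <- character()
  for (p in seq_len(np)) {
    lines <- c(lines, sprintf(
      ">sp|%s|PR%04d_SYN Synthetic protein %d OS=Synthetica sp. GN=%s PE=1 SV=1",
      acc[p], p, p, genes[p]), seqs[p])
    if (p <= spec$n_multi_accession)
      lines <- c(lines, sprintf(
        ">sp|%sb|PR%04dB_SYN Synthetic protein %db OS=Synthetica sp. GN=%sB PE=1 SV=1",
        acc[p], p, p, genes[p]), random_sequence(60L))
  }
  writeLines(lines, fasta)
  rule <- file.path(out_dir, "sequences.rule")
  writeLines(c("# FASTA header parse rule", "preset = uniprot"), rule)

  cmx <- file.path(out_dir, "correction_matrix.txt")
  write_correction_matrix(
    correction_matrix(paste0("TMT", 126:(126 + spec$n_channels - 1)),
                      diag(spec$n_channels)), cmx)

  ptm_names <- character()
  if (!is.null(nt)) ptm_names <- c(ptm_names, .mr_nterm_ptm)
  if (spec$n_oxidation_sites > 0L) ptm_names <- c(ptm_names, .mr_ox_ptm)
  cfg_path <- file.path(out_dir, "reporting_config.txt")
  write_reporting_config(reporting_config(ptm_names = ptm_names), cfg_path)

  truth <- list(
    n_groups = np, n_decoys = spec$n_decoys,
    n_contaminants = spec$n_contaminants,
    n_peptides = np * ppp + spec$n_oxidation_sites,
    n_scans = np * ppp * spp + spec$n_oxidation_sites,
    profiles = spec$profiles, accessions = acc, sequences = seqs,
    genes = genes, replicates = spec$replicates,
    nterm_sites = nt_truth, oxidation_sites = ox_truth,
    oxidation_position = ox_pos)
  invisible(list(dir = out_dir,
                 paths = list(txt = txt, config = cfg_path, fasta = fasta,
                              rule = rule, correction_matrix = cmx),
                 truth = truth))
}
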