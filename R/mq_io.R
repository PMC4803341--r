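# Text is read as UTF-8 with a latin-1 fallback: MaxQuant output is ASCII in
# practice but protein descriptions occasionally carry 8-bit characters.
read_text_lines <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  bad <- is.na(iconv(lines, "UTF-8", "UTF-8"))
  if (any(bad)) lines[bad] <- iconv(lines[bad], "latin1", "UTF-8")
  lines
}

#' Read a MaxQuant-style tab-separated table
#'
#' First line is the header. All values are kept as raw strings; typed
#' interpretation (numbers, `;`-joined multi-value fields) happens lazily in
#' the consumers, so a read/write cycle round-trips the file. Rows whose
#' field count does not match the header are skipped with a logged warning
#' naming the line number.
#'
#' @param path Path to the file.
#' @param selected_titles Optional character vector: retain only these
#'   columns (in the given order).
#' @return A character data frame with attributes `table_name` and
#'   `source_path`.
#' @export
read_table <- function(path, selected_titles = NULL) {
  if (!file.exists(path)) stop("table file not found: ", path)
  lines <- read_text_lines(path)
  if (length(lines) == 0L) stop("table file is empty: ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  n <- length(header)
  body <- lines[-1]
  while (length(body) && !nzchar(body[[length(body)]]))
    body <- body[-length(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  # field count = tab count + 1 (strsplit drops trailing empty fields, so
  # count delimiters instead); a row is valid iff it equals the header length
  true_counts <- nchar(body) - nchar(gsub("\t", "", body, fixed = TRUE)) + 1L
  valid <- true_counts == n
  if (any(!valid)) {
    for (i in which(!valid))
      mr_log_warn(sprintf("%s: line %d has %d field(s), expected %d; skipped",
                          basename(path), i + 1L, true_counts[[i]], n))
  }
  rows <- fields[valid]
  mat <- if (length(rows)) {
    t(vapply(rows, function(f) c(f, rep("", n - length(f))), character(n)))
  } else matrix(character(), 0L, n)
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- header
  if (!is.null(selected_titles)) {
    keep <- selected_titles[selected_titles %in% header]
    df <- df[, keep, drop = FALSE]
  }
  attr(df, "table_name") <- sub("\\.txt$", "", basename(path))
  attr(df, "source_path") <- path
  df
}

#' Write a table as tab-separated text
#'
#' Inverse of [read_table()] for character data frames: no quoting, `NA`
#' written as the empty string.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

## --- sequence catalog -------------------------------------------------------

#' Read FASTA files into an annotated sequence catalog
#'
#' Files are read in order (via \pkg{seqinr}) and merged; each file's headers
#' are parsed with the positionally paired rule. On a duplicated accession
#' the first occurrence wins and the duplicate is logged. Sequences are
#' uppercased.
#'
#' @param paths Character vector of FASTA paths.
#' @param rules List of [header_parse_rule()]s, same length as `paths` (a
#'   single rule is recycled).
#' @return An object of class `sequence_catalog`: a data frame with columns
#'   `accession`, `sequence`, `gene`, `description`, `source_index`.
#' @export
read_fasta <- function(paths, rules) {
  if (inherits(rules, "header_parse_rule")) rules <- list(rules)
  if (length(rules) == 1L && length(paths) > 1L)
    rules <- rep(rules, length(paths))
  if (length(paths) != length(rules))
    stop("read_fasta: ", length(paths), " FASTA file(s) but ",
         length(rules), " parse rule(s); they pair positionally")
  cat_list <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    if (!file.exists(paths[[i]])) stop("FASTA file not found: ", paths[[i]])
    seqs <- seqinr::read.fasta(paths[[i]], seqtype = "AA", as.string = TRUE,
                               whole.header = TRUE)
    if (length(seqs) == 0L) {
      cat_list[[i]] <- NULL
      next
    }
    headers <- names(seqs)
    parsed <- lapply(headers, parse_fasta_header, rule = rules[[i]])
    cat_list[[i]] <- data.frame(
      accession = vapply(parsed, `[[`, character(1), "accession"),
      sequence = toupper(vapply(seqs, `[[`, character(1), 1L)),
      gene = vapply(parsed, `[[`, character(1), "gene"),
      description = vapply(parsed, `[[`, character(1), "description"),
      source_index = i, stringsAsFactors = FALSE)
  }
  catalog <- do.call(rbind, cat_list)
  if (is.null(catalog))
    catalog <- data.frame(accession = character(), sequence = character(),
                          gene = character(), description = character(),
                          source_index = integer(), stringsAsFactors = FALSE)
  dup <- duplicated(catalog$accession)
  if (any(dup)) {
    mr_log_warn(sprintf("duplicate accession(s) in FASTA input, first kept: %s",
                        paste(unique(catalog$accession[dup]), collapse = ", ")))
    catalog <- catalog[!dup, , drop = FALSE]
  }
  rownames(catalog) <- NULL
  class(catalog) <- c("sequence_catalog", "data.frame")
  catalog
}

#' Look up catalog entries by accession
#'
#' @param catalog A [read_fasta()] catalog.
#' @param accession Character vector of accessions.
#' @return Data frame with one row per requested accession; `NA` fields for
#'   accessions absent from the catalog.
#' @export
catalog_get <- function(catalog, accession) {
  idx <- match(accession, catalog$accession)
  out <- catalog[idx, , drop = FALSE]
  out$accession <- accession
  rownames(out) <- NULL
  out
}

#' @export
print.sequence_catalog <- function(x, ...) {
  cat("Sequence catalog:", nrow(x), "entries from",
      length(unique(x$source_index)), "file(s)\n")
  print.data.frame(utils::head(as.data.frame(x), 5), ...)
  invisible(x)
}

## --- typed accessors for MaxQuant multi-value fields ------------------------

split_ids <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character())
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

split_nums <- function(x) suppressWarnings(as.numeric(split_ids(x)))

num_or_na <- function(x) suppressWarnings(as.numeric(x))

# I/L-insensitive comparison key used when matching peptides to sequences
il_key <- function(x, ile_eq_leu) {
  if (ile_eq_leu) chartr("I", "L", x) else x
}
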