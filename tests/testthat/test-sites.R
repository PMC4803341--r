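test_that("sequence windows are centred, padded and of fixed length", {
  # hand-constructed: centre M, 6 pads left, then KLV and 3 pads right
  expect_identical(extract_sequence_window("MKLV", 1, 6), "______MKLV___")
  expect_identical(extract_sequence_window("MKLV", 2, 0), "K")
  # exact fit: position 7 of a 13-mer needs no padding
  s13 <- "ABCDEFGHIKLMN"
  expect_identical(extract_sequence_window(s13, 7, 6), s13)
  expect_error(extract_sequence_window("MKLV", 5, 6, accession = "P1"), "P1")
  expect_error(extract_sequence_window("MKLV", 0, 6), "outside")

  # stripped of padding, the window is a substring containing the position
  set.seed(3)
  for (i in 1:25) {
    seq <- paste(sample(LETTERS[1:20], sample(5:40, 1), TRUE), collapse = "")
    pos <- sample(nchar(seq), 1)
    fl <- sample(0:8, 1)
    w <- extract_sequence_window(seq, pos, fl)
    expect_equal(nchar(w), 2 * fl + 1)
    core <- gsub("_", "", w)
    expect_true(grepl(core, seq, fixed = TRUE))
  }
})

test_that("sites are specific only strictly above the threshold; absent counts as specific", {
  expect_identical(classify_site(0.97, 0.5), "specific")
  # "larger than" is strict: exactly at threshold stays ambiguous
  expect_identical(classify_site(0.5, 0.5), "ambiguous")
  expect_identical(classify_site(NA, 0.5), "specific")
  expect_error(classify_site(1.2, 0.5), "\\[0, 1\\]")

  # monotone in probability for a fixed threshold
  probs <- seq(0, 1, by = 0.05)
  cls <- classify_site(probs, 0.5) == "specific"
  expect_true(all(diff(as.integer(cls)) >= 0))
})

test_that("protein N-terminal sites are detected at positions 1 and 2 only", {
  fx <- small_project(
    nterm_sites = data.frame(position = c(1, 2), prob = c(0.9, NA)))
  run <- run_project(fx)
  st <- run$site_tables[["Acetyl (Protein N-term)"]]
  expect_equal(nrow(st), 2)
  expect_identical(as.integer(st$Position), c(1L, 2L))
  expect_identical(st$Protein, fx$truth$nterm_sites$accession)
  # absent probability counts as specific (position fixed by the terminus)
  expect_identical(st[["Site class"]], c("specific", "specific"))
  # supporting scans exist in the reported msms table
  for (ids in st[["MS/MS IDs"]])
    expect_true(all(strsplit(ids, ";")[[1]] %in% run$msms$id))
  # windows come from the protein sequence with correct padding
  expect_identical(st[["Sequence window"]][1],
                   extract_sequence_window(fx$truth$sequences[1], 1, 6))
  expect_identical(st[["Sequence window"]][2],
                   extract_sequence_window(fx$truth$sequences[2], 2, 6))
})

test_that("peptides not locatable at a protein start are skipped with a warning", {
  fx <- small_project()
  cfg <- load_reporting_config(fx$paths$config)
  cfg$ptm_names <- "Acetyl (Protein N-term)"
  catalog <- read_fasta(fx$paths$fasta, load_parse_rule(fx$paths$rule))
  groups <- build_protein_report(
    read_table(file.path(fx$paths$txt, "proteinGroups.txt")), catalog)
  msms <- data.frame(
    id = "0", Sequence = "WWWWWWWWWW",  # matches nothing
    Modifications = "Acetyl (Protein N-term)",
    "Protein group IDs" = "0", Score = "100",
    check.names = FALSE, stringsAsFactors = FALSE)
  mr_log_reset()
  st <- detect_nterm_sites(msms, groups, catalog, cfg)
  expect_equal(nrow(st), 0)
  expect_equal(n_log("WARN"), 1)

  # no scan carries the modification at all: empty table, no warning
  msms$Modifications <- "Unmodified"
  mr_log_reset()
  expect_equal(nrow(detect_nterm_sites(msms, groups, catalog, cfg)), 0)
  expect_equal(n_log("WARN"), 0)
})

test_that("Ile = Leu matching locates N-terminal peptides across I/L substitutions", {
  catalog <- structure(data.frame(
    accession = "P1", sequence = "MILKAAAAAAAA", gene = "", description = "",
    source_index = 1L, stringsAsFactors = FALSE),
    class = c("sequence_catalog", "data.frame"))
  groups <- data.frame(id = "0", Score = "10",
                       "Retained protein IDs" = "P1", "Lead protein" = "P1",
                       check.names = FALSE, stringsAsFactors = FALSE)
  msms <- data.frame(id = "0", Sequence = "MLLKAAAA",  # I->L variant
                     Modifications = "Acetyl (Protein N-term)",
                     "Protein group IDs" = "0", Score = "50",
                     check.names = FALSE, stringsAsFactors = FALSE)
  cfg_strict <- reporting_config(ptm_names = "Acetyl (Protein N-term)")
  cfg_il <- reporting_config(ptm_names = "Acetyl (Protein N-term)",
                             ile_eq_leu = TRUE)
  mr_log_reset()
  expect_equal(nrow(detect_nterm_sites(msms, groups, catalog, cfg_strict)), 0)
  st <- detect_nterm_sites(msms, groups, catalog, cfg_il)
  expect_equal(nrow(st), 1)
  expect_identical(as.integer(st$Position), 1L)
  # the reported window shows the catalog residues, not the I/L-collapsed key
  expect_match(st[["Sequence window"]], "MILK")
})

test_that("MaxQuant site tables are filtered, resolved and windowed uniformly", {
  fx <- small_project(n_oxidation_sites = 3, oxidation_probs = c(0.9, 0.9, 0.4),
                      n_reverse_oxidation_sites = 1)
  run <- run_project(fx)
  st <- run$site_tables[["Oxidation (M)"]]
  expect_equal(nrow(st), 3)  # the decoy row is gone
  expect_identical(unique(as.integer(st$Position)),
                   fx$truth$oxidation_position)
  expect_identical(st[["Site class"]], c("specific", "specific", "ambiguous"))
  expect_true(all(nchar(st[["Sequence window"]]) == 13))
  # same schema as the N-terminal tables
  fx2 <- small_project(nterm_sites = data.frame(position = 1, prob = 0.9))
  run2 <- run_project(fx2)
  expect_identical(names(st), names(run2$site_tables[[1]]))
})

test_that("a site table referenced in the config but missing is skipped with a warning", {
  fx <- small_project()
  catalog <- read_fasta(fx$paths$fasta, load_parse_rule(fx$paths$rule))
  groups <- build_protein_report(
    read_table(file.path(fx$paths$txt, "proteinGroups.txt")), catalog)
  msms <- read_table(file.path(fx$paths$txt, "msms.txt"))
  mr_log_reset()
  st <- build_site_table("Phospho (STY)", fx$paths$txt, msms, groups, catalog,
                         reporting_config(ptm_names = "Phospho (STY)"))
  expect_equal(nrow(st), 0)
  expect_match(mr_log_entries("WARN")$message, "Phospho")
})
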