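test_that("identification counts and distributions match the tables", {
  proteins <- data.frame(id = c("0", "1", "2"),
                         Peptides = c("1", "2", "2"),
                         "Unique peptides" = c("1", "1", "2"),
                         check.names = FALSE, stringsAsFactors = FALSE)
  peptides <- data.frame(Sequence = paste0("PEP", 1:5),
                         stringsAsFactors = FALSE)
  msms <- data.frame(id = as.character(1:7), stringsAsFactors = FALSE)
  su <- compute_identification_stats(proteins, peptides, msms)
  expect_equal(su$counts$protein_groups, 3)
  expect_equal(su$counts$peptides, 5)
  expect_equal(su$counts$spectra, 7)
  expect_equal(su$peptide_count_dist$all,
               data.frame(n = c(1L, 2L), count = c(1L, 2L)))
  # bin totals sum to the parent count
  expect_equal(sum(su$peptide_count_dist$all$count), nrow(proteins))
  expect_equal(nrow(su$ptm_stats), 0)
})

test_that("per-PTM summaries count sites, spectra, peptides and groups", {
  st <- data.frame(
    PTM = "Oxidation (M)", Protein = c("P1", "P1", "P2"),
    Position = c("10", "20", "10"), "Site class" = "specific",
    Sequence = c("AAA", "CCC", "DDD"),
    "Protein group IDs" = c("0", "0", "1"),
    "MS/MS IDs" = c("1;2", "3", "4"),
    check.names = FALSE, stringsAsFactors = FALSE)
  su <- compute_identification_stats(
    data.frame(id = "0"), data.frame(Sequence = "A"), data.frame(id = "1"),
    site_tables = list("Oxidation (M)" = st))
  ps <- su$ptm_stats
  expect_equal(ps$sites, 3)
  expect_equal(ps$spectra, 4)
  expect_equal(ps$peptides, 3)
  expect_equal(ps$protein_groups, 2)
  # sites-per-protein distribution: P1 has 2, P2 has 1
  expect_equal(su$site_count_dists[["Oxidation (M)"]],
               data.frame(n = c(1L, 2L), count = c(1L, 1L)))

  # an empty site table yields all-zero counts for that PTM
  su0 <- compute_identification_stats(
    data.frame(id = "0"), data.frame(Sequence = "A"), data.frame(id = "1"),
    site_tables = list("Phospho (STY)" = st[0, ]))
  expect_equal(su0$ptm_stats$sites, 0)
  expect_equal(su0$ptm_stats$spectra, 0)
})

test_that("fixture ground-truth counts are reproduced end to end", {
  fx <- small_project(n_oxidation_sites = 2)
  run <- run_project(fx)
  expect_equal(run$stats$counts$protein_groups, fx$truth$n_groups)
  expect_equal(run$stats$counts$peptides, fx$truth$n_peptides)
  expect_equal(run$stats$counts$spectra, fx$truth$n_scans)
})

test_that("replication assignment marks presence per replicate", {
  fx <- small_project(n_oxidation_sites = 1)
  run <- run_project(fx)
  ra <- run$replication
  expect_named(ra, c("protein_groups", "peptides", "msms",
                     "sites_Oxidation (M)"))
  pg <- ra$protein_groups
  # every protein has spectra in both replicates (round-robin raw files)
  expect_true(all(pg$R1 == 1 & pg$R2 == 1))
  # oxidation scans are generated in raw1 only -> present in R1 only
  sa <- ra[["sites_Oxidation (M)"]]
  expect_equal(sa$R1, 1L)
  expect_equal(sa$R2, 0L)

  # single-replicate designs skip the assignment with a log note
  fx1 <- small_project(replicates = c(raw1 = "R1"))
  run1 <- run_project(fx1)
  expect_null(run1$replication)
})

test_that("every chart has a same-named TSV twin holding its series", {
  fx <- small_project(n_oxidation_sites = 2)
  run <- run_project(fx)
  charts <- file.path(run$out_dir, "charts")
  svgs <- list.files(charts, pattern = "\\.svg$")
  expect_gt(length(svgs), 0)
  for (svg in svgs)
    expect_true(file.exists(file.path(charts, sub("\\.svg$", ".tsv", svg))))
  # site-class pie series covers every planted site exactly once
  pie <- read_table(file.path(charts, "site_class_Oxidation_M_.tsv"))
  expect_identical(pie$label, c("specific", "ambiguous"))
  expect_equal(sum(as.numeric(pie$value)),
               nrow(run$site_tables[["Oxidation (M)"]]))

  # a summary with no PTMs emits no PTM charts
  out2 <- withr::local_tempdir()
  su <- compute_identification_stats(data.frame(id = "0"),
                                     data.frame(Sequence = "A"),
                                     data.frame(id = "1"))
  files <- emit_charts(su, NULL, out2)
  expect_false(any(grepl("ptm_summary|site_class", files)))
})
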