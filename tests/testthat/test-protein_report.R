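mini_groups <- function(reverse = c("", "+", "", "", ""),
                        contam = c("", "", "+", "", ""),
                        contam_col = "Potential contaminant") {
  df <- data.frame(
    "Protein IDs" = paste0("P", 1:5), "Peptide counts (all)" = "3",
    "Peptide counts (unique)" = "2", "Score" = as.character(c(10, 20, 30, 40, 50)),
    "Reverse" = reverse, "id" = as.character(0:4),
    check.names = FALSE, stringsAsFactors = FALSE)
  df[[contam_col]] <- contam
  df
}

test_that("reverse and contaminant groups are removed, order preserved", {
  out <- filter_decoys_contaminants(mini_groups())
  expect_identical(out[["Protein IDs"]], c("P1", "P4", "P5"))

  expect_equal(filter_decoys_contaminants(mini_groups("", "")),
               mini_groups("", ""), ignore_attr = TRUE)

  # flagged both ways: removed once, one log entry for the whole table
  mr_log_reset()
  both <- mini_groups(reverse = c("", "+", "", "", ""),
                      contam = c("", "+", "", "", ""))
  expect_equal(nrow(filter_decoys_contaminants(both)), 4)
  expect_equal(n_log("INFO"), 1)

  # prefix conventions work without marker columns
  pfx <- data.frame("Protein IDs" = c("P1", "REV__P2", "CON__P3;P4"),
                    check.names = FALSE, stringsAsFactors = FALSE)
  expect_identical(filter_decoys_contaminants(pfx)[["Protein IDs"]], "P1")

  # older dialect: "Contaminant" column instead of "Potential contaminant"
  old <- filter_decoys_contaminants(mini_groups(contam_col = "Contaminant"))
  expect_identical(old[["Protein IDs"]], c("P1", "P4", "P5"))
})

test_that("group minimization keeps the accessions with most unique, then total peptides", {
  expect_identical(minimize_group(c("A", "B", "C"), c(3, 3, 1), c(5, 4, 2)), 1L)
  expect_identical(minimize_group("A", 4, 6), 1L)
  expect_identical(minimize_group(c("A", "B"), c(2, 2), c(4, 4)), c(1L, 2L))
  mr_log_reset()
  expect_identical(minimize_group(c("A", "B"), c(1, NA), c(2, 2)), c(1L, 2L))
  expect_equal(n_log("WARN"), 1)
})

test_that("minimization matches a brute-force argmax and is idempotent", {
  # oracle: enumerate accessions, keep those whose (unique, total) pair is
  # lexicographically maximal
  brute <- function(u, t) {
    best <- NULL
    for (i in seq_along(u)) {
      key <- c(u[i], t[i])
      if (is.null(best) || key[1] > best[1] ||
          (key[1] == best[1] && key[2] > best[2])) best <- key
    }
    which(u == best[1] & t == best[2])
  }
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(1:8, 1)
    u <- sample(0:4, n, replace = TRUE)
    t <- u + sample(0:4, n, replace = TRUE)
    accs <- paste0("A", seq_len(n))
    keep <- minimize_group(accs, u, t)
    expect_identical(keep, brute(u, t))
    # re-minimizing the minimized group changes nothing
    keep2 <- minimize_group(accs[keep], u[keep], t[keep])
    expect_identical(accs[keep][keep2], accs[keep])
  }
})

test_that("protein report annotates lead accessions from the catalog", {
  fx <- small_project(n_multi_accession = 1)
  catalog <- read_fasta(fx$paths$fasta, load_parse_rule(fx$paths$rule))
  groups <- read_table(file.path(fx$paths$txt, "proteinGroups.txt"))
  rep <- build_protein_report(groups, catalog)
  expect_equal(nrow(rep), fx$truth$n_groups)
  expect_false(any(is_reverse_row(rep) | is_contaminant_row(rep)))
  # the multi-accession group is minimized to its better-supported accession
  expect_identical(rep[["Lead protein"]][1], fx$truth$accessions[1])
  expect_identical(rep[["Retained protein IDs"]][1], fx$truth$accessions[1])
  expect_identical(rep[["Gene name"]],
                   fx$truth$genes[match(rep[["Lead protein"]],
                                        fx$truth$accessions)])
  # two groups sharing a lead would share annotation; here every gene is
  # distinct, so annotation must be a pure catalog lookup
  expect_identical(rep[["Protein description"]][2],
                   catalog$description[catalog$accession == rep[["Lead protein"]][2]])

  # lead absent from the catalog: empty annotation plus a warning
  mr_log_reset()
  ghost <- data.frame("Protein IDs" = "GHOST", "Peptide counts (all)" = "1",
                      "Peptide counts (unique)" = "1", Score = "1", id = "0",
                      check.names = FALSE, stringsAsFactors = FALSE)
  rep2 <- build_protein_report(ghost, catalog)
  expect_identical(rep2[["Gene name"]], "")
  expect_equal(n_log("WARN"), 1)
})

test_that("the best-scored candidate group wins, ties to the earlier row", {
  groups <- data.frame(id = c("0", "1", "2"),
                       Score = c("12.1", "45.0", "45.0"),
                       stringsAsFactors = FALSE)
  expect_identical(resolve_best_group(c("0", "1"), groups), "1")
  expect_identical(resolve_best_group("2", groups), "2")
  expect_identical(resolve_best_group(c("2", "1"), groups), "1")
  mr_log_reset()
  expect_true(is.na(resolve_best_group(c("7", "9"), groups)))
  expect_equal(n_log("INFO"), 1)
})
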