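test_that("isotope-impurity correction inverts the mixing matrix", {
  cm2 <- correction_matrix(c("a", "b"), matrix(c(0.9, 0.1, 0.1, 0.9), 2))
  # observed [90, 10] is exactly M %*% [100, 0]
  expect_equal(unname(apply_correction(c(90, 10), cm2)), c(100, 0))
  expect_equal(apply_correction(c(5, 7, 9), NULL), c(5, 7, 9))
  id6 <- correction_matrix(paste0("c", 1:6), diag(6))
  v <- c(1, 10, 100, 1000, 0, 3)
  expect_equal(unname(apply_correction(v, id6)), v)
  expect_error(apply_correction(c(1, 2, 3), cm2), "dimension")
  sing <- structure(list(labels = c("a", "b"),
                         values = matrix(c(1, 1, 1, 1), 2)),
                    class = "correction_matrix")
  expect_error(apply_correction(c(1, 2), sing), "singular")

  # negative solutions clamp to zero and are counted in the log
  mr_log_reset()
  out <- apply_correction(c(0, 100), cm2)
  expect_equal(unname(out[1]), 0)
  expect_match(mr_log_entries("INFO")$message, "clamped")
})

test_that("calibration factors equalize channel totals to their mean", {
  m <- rbind(c(150, 70), c(50, 30))  # totals 200, 100
  f <- compute_calibration_factors(m)
  expect_equal(unname(unclass(f)), c(0.75, 1.5))
  post <- sweep(m, 2, unclass(f), "*")
  expect_equal(colSums(post), c(150, 150), ignore_attr = TRUE)

  expect_equal(unname(unclass(compute_calibration_factors(
    rbind(c(100, 100, 100))))), c(1, 1, 1))
  expect_equal(unname(unclass(compute_calibration_factors(
    rbind(c(50, 100))))), c(1.5, 0.75))

  bad <- matrix(c(1, 1, 0, 0), 2, dimnames = list(NULL, c("ok", "dead")))
  expect_error(compute_calibration_factors(bad), "dead")
})

test_that("spectrum normalization yields unit-sum fractions and drops low totals", {
  m <- rbind(rep(100, 6), c(300, 100, 0, 0, 0, 0), rep(0, 6))
  mr_log_reset()
  norm <- normalize_spectra(m, 0)
  expect_identical(norm$included, c(TRUE, TRUE, FALSE))
  expect_equal(norm$n_excluded, 1)
  expect_equal(unname(norm$fractions[1, ]), rep(1 / 6, 6))
  expect_equal(unname(norm$fractions[2, 1:2]), c(0.75, 0.25))
  expect_equal(rowSums(norm$fractions), c(1, 1), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(n_log("INFO"), 1)
})

test_that("sigma-based rejection removes distant values, with small-group guards", {
  expect_true(all(remove_outliers(rep(0.3, 10), 1.96)))
  # frozen hand computation: mu = 0.26, population sigma = 0.32,
  # |0.9 - 0.26| = 0.64 > 1.96 * 0.32 = 0.6272, so 0.9 is removed
  keep <- remove_outliers(c(0.1, 0.1, 0.1, 0.1, 0.9), 1.96)
  expect_identical(keep, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # groups of fewer than 3 values are never touched
  expect_true(all(remove_outliers(c(0.1, 0.9), 1.96)))

  # re-running rejection on the retained set removes nothing further
  set.seed(5)
  for (i in 1:40) {
    v <- stats::rlnorm(sample(3:30, 1), 0, 0.3)
    keep1 <- remove_outliers(v, 1.96)
    keep2 <- remove_outliers(v[keep1], 1.96)
    expect_true(all(keep2))
  }
})

test_that("group summaries report median, mean and population SD per channel", {
  one <- matrix(c(0.75, 0.25), 1, dimnames = list(NULL, c("a", "b")))
  s <- summarize_group(one)
  expect_equal(unname(s$median), c(0.75, 0.25))
  expect_equal(unname(s$mean), c(0.75, 0.25))
  expect_equal(unname(s$sd), c(0, 0))

  m <- matrix(c(0.2, 0.4, 0.6), 3, 1)
  s2 <- summarize_group(m)
  expect_equal(unname(s2$median), 0.4)
  expect_equal(unname(s2$mean), 0.4)
  expect_equal(unname(s2$sd), sqrt(mean((c(.2, .4, .6) - .4)^2)))
})

test_that("a flat fixture quantifies every channel at 1/n_channels", {
  fx <- small_project()  # flat profiles
  run <- run_project(fx)
  merged <- run$quant$protein$merged
  med_cols <- grep("^Median", names(merged), value = TRUE)
  vals <- unlist(merged[med_cols])
  vals <- vals[!is.na(vals)]
  expect_true(all(abs(vals - 0.25) < 0.05))  # 4 channels
  expect_equal(nrow(merged), fx$truth$n_groups)
})

test_that("balanced planted profiles are recovered through the full default pipeline", {
  # half the proteins at 2:1:1:1, half at 1:2:1:1 keeps channel totals equal,
  # so the loading calibration leaves per-protein ratios intact
  profiles <- rbind(matrix(rep(c(2, 1, 1, 1), each = 3), 3),
                    matrix(rep(c(1, 2, 1, 1), each = 3), 3))
  fx <- local_project(n_proteins = 6, peptides_per_protein = 3,
                      spectra_per_peptide = 10, n_channels = 4,
                      profiles = profiles, replicates = c(raw1 = "R1"),
                      n_decoys = 0, n_contaminants = 0,
                      n_multi_accession = 0, seed = 21)
  run <- run_project(fx)
  m <- run$quant$protein$merged
  m <- m[order(as.integer(m$id)), ]
  ratio <- m[["Median Reporter 0 [R1]"]] / m[["Median Reporter 1 [R1]"]]
  truth <- profiles[, 1] / profiles[, 2]
  expect_equal(ratio, truth, tolerance = 0.05, ignore_attr = TRUE)
})

test_that("proteins with only shared peptides stay unquantified under unique-only", {
  groups <- data.frame(id = c("0", "1"), Score = c("10", "20"),
                       stringsAsFactors = FALSE)
  msms <- data.frame(
    id = c("0", "1"), "Raw file" = "r1",
    Sequence = c("AAAA", "CCCC"),
    "Protein group IDs" = c("0;1", "1"),  # first peptide is shared
    "Reporter intensity 0" = c("100", "300"),
    "Reporter intensity 1" = c("100", "100"),
    check.names = FALSE, stringsAsFactors = FALSE)
  design <- load_experimental_design(
    data.frame("Raw file" = "r1", "Experiment" = "R1", check.names = FALSE))
  cfg <- reporting_config()
  q <- quantify_project(msms, groups, list(), design, cfg)
  expect_identical(q$protein$merged$id, "1")
  # hand-derived through the calibration step: channel totals are [400, 200],
  # so factors are [0.75, 1.5]; the unique spectrum [300, 100] becomes
  # [225, 150], i.e. fractions [0.6, 0.4]
  expect_equal(q$protein$merged[["Median Reporter 0 [R1]"]], 0.6,
               tolerance = 1e-9)

  # with all peptides allowed, the shared spectrum quantifies its best group
  cfg2 <- reporting_config(use_unique_peptides_only = FALSE)
  q2 <- quantify_project(msms, groups, list(), design, cfg2)
  expect_setequal(q2$protein$merged$id, "1")  # best-scored group of "0;1" is 1
  expect_equal(q2$protein$per_replicate$R1[["Spectra used"]][1], 2)
})

test_that("replicates are quantified separately and merged by entity id", {
  fx <- small_project()  # two replicates raw1/raw2 -> R1/R2
  run <- run_project(fx)
  q <- run$quant$protein
  expect_named(q$per_replicate, c("R1", "R2"))
  merged <- q$merged
  expect_true(all(c("Median Reporter 0 [R1]", "Median Reporter 0 [R2]")
                  %in% names(merged)))
  # a single-spectrum single-replicate project: merged equals the replicate
  fx1 <- local_project(n_proteins = 1, peptides_per_protein = 1,
                       spectra_per_peptide = 1, n_channels = 2,
                       replicates = c(raw1 = "R1"), n_decoys = 0,
                       n_contaminants = 0, n_multi_accession = 0, seed = 2)
  run1 <- run_project(fx1)
  q1 <- run1$quant$protein
  expect_equal(nrow(q1$merged), nrow(q1$per_replicate$R1))
  expect_equal(q1$merged[["Median Reporter 0 [R1]"]],
               q1$per_replicate$R1[["Median Reporter 0"]])
  expect_equal(q1$per_replicate$R1[["Spectra used"]], 1)
})

test_that("an entity absent from one replicate leaves that block empty", {
  # oxidation scans are generated in raw1 only, so the site appears in R1
  fx <- small_project(n_oxidation_sites = 1)
  run <- run_project(fx)
  sq <- run$quant$site$merged
  expect_equal(nrow(sq), 1)
  expect_false(is.na(sq[["Median Reporter 0 [R1]"]]))
  expect_true(is.na(sq[["Median Reporter 0 [R2]"]]))
})
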