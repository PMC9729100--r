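test_that("sim_config validates its invariants", {
  expect_error(sim_config(), "seed is mandatory")
  expect_error(sim_config(seed = 1, outcome_probs = c(unedited = 0.5,
                                                      VARIANT_KI = 0.2,
                                                      WTPRIME_KI = 0.2,
                                                      FRAMESHIFT_INDEL = 0.2,
                                                      INFRAME_INDEL = 0.2)),
               "sum to 1")
  expect_error(sim_config(seed = 1, fitness = c(variant = -1, wtprime = 1,
                                                frameshift = 1, inframe = 1,
                                                wt = 1)),
               "negative fitness")
  expect_error(sim_config(seed = 1, frameshift_lengths = c(3L)), "multiples")
})

test_that("cut probability zero leaves every cell wild type", {
  cfg <- sim_config(seed = 5, n_cells = 500L, cut_prob = 0)
  pop <- simulate_editing(cfg)
  expect_true(all(pop$cells$allele_1 == "WT"))
  expect_true(all(pop$cells$allele_2 == "WT"))
  expect_equal(pop$truth$allele_counts[["WT"]], 1000)
})

test_that("second-allele outcomes follow the conditional law under independence", {
  cfg <- sim_config(seed = 6, n_cells = 40000L, cut_prob = 0.8)
  pop <- simulate_editing(cfg)
  has_var <- pop$cells$allele_1 == "VARIANT_KI"
  other <- pop$cells$allele_2[has_var]
  # expected marginal law of any allele
  p_cat <- cfg$cut_prob * cfg$outcome_probs
  expected <- c(WT = unname(p_cat[["unedited"]]) + (1 - cfg$cut_prob),
                p_cat[setdiff(names(p_cat), "unedited")])
  for (cat in names(expected)) {
    phat <- mean(other == cat)
    se <- sqrt(expected[[cat]] * (1 - expected[[cat]]) / length(other))
    expect_lt(abs(phat - expected[[cat]]), 4 * se + 1e-9)
  }
})

test_that("symmetric template masses give a balanced baseline cell ratio", {
  cfg <- sim_config(seed = 7, n_cells = 30000L)
  pop <- simulate_editing(cfg)
  expect_gt(pop$truth$variant_wtprime_cell_ratio, 0.9)
  expect_lt(pop$truth$variant_wtprime_cell_ratio, 1.1)
})

test_that("explicit joint tables override the independence model", {
  jt <- tibble::tibble(
    allele_1 = c("VARIANT_KI", "WTPRIME_KI", "FRAMESHIFT_INDEL", "WT"),
    allele_2 = c("WT", "WT", "WT", "WT"),
    prob = c(0.1, 0.1, 0.3, 0.5))
  cfg <- sim_config(seed = 8, n_cells = 5000L, joint_table = jt)
  pop <- simulate_editing(cfg)
  expect_true(all(pop$cells$allele_2 == "WT"))
  expect_false(any(pop$cells$allele_1 == "INFRAME_INDEL"))
})

test_that("neutral fitness keeps the cell ratio constant across timepoints", {
  cfg <- sim_config(seed = 9, n_cells = 5000L)
  tc <- simulate_selection(simulate_editing(cfg))
  expect_equal(tc$truth$cell_ratio[1L], tc$truth$cell_ratio[2L])
  expect_equal(tc$truth$total_cells[1L], tc$truth$total_cells[2L])
})

test_that("configured fitness reproduces the closed-form expected fold", {
  # non-overlapping genotypes so the exponential expectation is exact
  jt <- tibble::tibble(
    allele_1 = c("VARIANT_KI", "WTPRIME_KI", "FRAMESHIFT_INDEL", "WT"),
    allele_2 = c("WT", "WT", "WT", "WT"),
    prob = c(0.08, 0.08, 0.4, 0.44))
  fit <- 0.2^(1 / 10)          # day 12 : day 2 fold of 0.2
  cfg <- sim_config(seed = 10, n_cells = 8000L, joint_table = jt,
                    fitness = c(variant = fit, wtprime = 1, frameshift = 1,
                                inframe = 1, wt = 1),
                    timepoints = c(2, 12))
  tc <- simulate_selection(simulate_editing(cfg))
  fold <- tc$truth$cell_ratio[2L] / tc$truth$cell_ratio[1L]
  expect_equal(fold, 0.2, tolerance = 1e-9)
})

test_that("passaging resamples but conserves the expected composition", {
  cfg <- sim_config(seed = 11, n_cells = 20000L)
  tc <- simulate_selection(simulate_editing(cfg), passage_fraction = 0.25)
  expect_equal(tc$truth$total_cells[2L], 0.25 * tc$truth$total_cells[1L],
               tolerance = 0.01)
  expect_equal(tc$truth$cell_ratio[2L], tc$truth$cell_ratio[1L],
               tolerance = 0.2)
})

test_that("read emission conserves truth counts and round-trips error-free reads", {
  cas <- fixture_cassette()
  jt <- tibble::tibble(allele_1 = "VARIANT_KI", allele_2 = "VARIANT_KI",
                       prob = 1)
  cfg <- sim_config(seed = 12, n_cells = 500L, joint_table = jt,
                    depth = 400L, error_rate = 0)
  pop <- simulate_editing(cfg)
  fq <- tempfile(fileext = ".fastq")
  em <- emit_reads(pop, cas, fq)
  expect_identical(sum(em$truth$reads), 400L)
  expect_identical(em$truth$reads[em$truth$category == "VARIANT_KI"], 400L)
  prof <- quantify_sample(fq, cas)
  expect_identical(prof$reads[prof$category == "VARIANT_KI"], 400L)
})

test_that("emitted category frequencies match truth within binomial error", {
  cas <- fixture_cassette()
  cfg <- sim_config(seed = 13, n_cells = 4000L, depth = 6000L,
                    error_rate = 0.003)
  pop <- simulate_editing(cfg)
  fq <- tempfile(fileext = ".fastq")
  em <- emit_reads(pop, cas, fq)
  prof <- quantify_sample(fq, cas)
  for (cat in c("VARIANT_KI", "WTPRIME_KI", "FRAMESHIFT_INDEL")) {
    p_true <- em$truth$reads[em$truth$category == cat] / cfg$depth
    p_obs <- prof$frequency[prof$category == cat]
    se <- sqrt(p_true * (1 - p_true) / cfg$depth)
    expect_lt(abs(p_obs - p_true), 3 * se + 2e-3)
  }
})

test_that("the same seed gives byte-identical FASTQ output", {
  cas <- fixture_cassette()
  cfg <- sim_config(seed = 14, n_cells = 300L, depth = 300L)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  emit_reads(simulate_editing(cfg), cas, f1)
  emit_reads(simulate_editing(cfg), cas, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # and a different seed does not
  cfg2 <- sim_config(seed = 15, n_cells = 300L, depth = 300L)
  f3 <- tempfile(fileext = ".fastq")
  emit_reads(simulate_editing(cfg2), cas, f3)
  expect_false(tools::md5sum(f1)[[1L]] == tools::md5sum(f3)[[1L]])
})

test_that("zero depth emits an empty FASTQ with a warning", {
  cas <- fixture_cassette()
  cfg <- sim_config(seed = 16, n_cells = 100L, depth = 0L)
  pop <- simulate_editing(cfg)
  fq <- tempfile(fileext = ".fastq")
  expect_warning(em <- emit_reads(pop, cas, fq), "depth 0")
  expect_identical(length(readLines(fq)), 0L)
})

test_that("simulate_experiment produces a coherent sheet and truth table", {
  cas <- fixture_cassette()
  cfg <- sim_config(seed = 17, n_cells = 800L, depth = 500L)
  dir <- tempfile()
  ex <- simulate_experiment(cas, cfg, dir, n_replicates = 2L)
  expect_identical(nrow(ex$sample_sheet), 4L)
  expect_true(all(file.exists(ex$sample_sheet$fastq_path)))
  expect_setequal(unique(ex$truth$replicate), 1:2)
  # replicates are independent realizations
  expect_false(tools::md5sum(ex$sample_sheet$fastq_path[1L])[[1L]] ==
                 tools::md5sum(ex$sample_sheet$fastq_path[3L])[[1L]])
})
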