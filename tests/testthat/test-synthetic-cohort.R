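test_that("configuration validation rejects malformed inputs before generation", {
  expect_error(sim_config(missing_sample_rate = 1.2), class = "bcelldyn_validation_error")
  expect_error(sim_config(depletion_month_probs = c(`1` = 0.5, `3` = 0.2, `6` = 0.2)),
               class = "bcelldyn_validation_error")
  expect_error(sim_config(not_a_field = 1), class = "bcelldyn_validation_error")
  expect_error(sim_config(clonotypes_per_sample = 10, n_lineages_baseline = 20),
               class = "bcelldyn_validation_error")
  expect_error(sim_config(baseline_gini_target = 1.4), class = "bcelldyn_parameter_error")
  # an invalidated config fails before any file is written
  cfg_bad <- tiny_config()
  cfg_bad$missing_sample_rate <- 2
  out <- file.path(tempdir(), "never_created")
  expect_error(generate_cohort(cfg_bad, out), class = "bcelldyn_validation_error")
  expect_false(dir.exists(out))
})

test_that("identical seed and configuration give byte-identical cohorts", {
  cfg <- tiny_config(seed = 7)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  unlink(c(d1, d2), recursive = TRUE)
  s1 <- generate_cohort(cfg, d1)
  s2 <- generate_cohort(cfg, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_equal(f1, f2)
  h1 <- tools::md5sum(file.path(d1, f1)); h2 <- tools::md5sum(file.path(d2, f2))
  expect_equal(unname(h1), unname(h2))
  expect_identical(s1$truth, s2$truth)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("planted truth is internally consistent across seeds", {
  for (seed in 1:8) {
    sim <- simulate_cohort(desk_config(seed = seed), repertoires = FALSE)
    tr <- sim$truth
    both <- !is.na(tr$true_repopulation_month)
    expect_true(all(tr$true_repopulation_month[both] > tr$true_depletion_month[both]))
    expect_true(all(tr$true_depletion_month %in% c(1L, 3L, 6L)))
    # study-scale composition: marginals are exact at n = 23
    expect_equal(unname(table(factor(tr$true_depletion_month, c(1, 3, 6)))),
                 c(14L, 5L, 4L), ignore_attr = TRUE)
    expect_equal(sum(both), 14L)
    # baseline planted values sit above, depleted visits below the threshold
    pl <- sim$planted[sim$planted$sample_status == "ok", ]
    expect_true(all(pl$planted_pct[pl$state %in% c("baseline", "pre", "repop")] >= sim$threshold))
    expect_true(all(pl$planted_pct[pl$state == "depleted"] < sim$threshold))
  }
})

test_that("forcing month-1 depletion pushes every month-1 sample below threshold", {
  cfg <- desk_config(seed = 9,
                     depletion_month_probs = c(`1` = 1, `3` = 0, `6` = 0),
                     missing_sample_rate = 0)
  sim <- simulate_cohort(cfg, repertoires = FALSE)
  m1 <- sim$planted[sim$planted$visit_month == 1L, ]
  expect_true(all(m1$planted_pct < 4.4))
})

test_that("the Gini shape solver hits feasible targets and refuses infeasible ones", {
  for (target in c(0.05, 0.15, 0.27, 0.4, 0.52, 0.7, 0.9)) {
    counts <- solve_gini_counts(2000, target)
    expect_true(all(counts >= 3))
    expect_lt(abs(gini_expansion(counts) - target), 1e-3)
  }
  expect_equal(gini_expansion(solve_gini_counts(500, 0)), 0)
  expect_error(solve_gini_counts(2, 0.9), class = "bcelldyn_infeasible_target")
})

test_that("the lineage-size solver matches Shannon targets and clamps at the entropy ceiling", {
  for (target in c(6, 7, 7.53)) {
    sizes <- solve_lineage_sizes(2500, 5000, target)
    expect_equal(sum(sizes), 5000)
    expect_true(all(sizes >= 1))
    expect_lt(abs(shannon_lineage_diversity(sizes) - target), 1e-3)
  }
  # month-1-like contraction: 1000 clonotypes over 400 lineages
  sizes1 <- solve_lineage_sizes(400, 1000, 4.75)
  expect_equal(sum(sizes1), 1000)
  expect_lt(abs(shannon_lineage_diversity(sizes1) - 4.75), 1e-3)
  # target above ln(n_lineages): clamps to the attainable maximum
  sizes <- solve_lineage_sizes(50, 100, 10)
  expect_equal(shannon_lineage_diversity(sizes), log(50), tolerance = 0.01)
  expect_error(solve_lineage_sizes(10, 5, 1), class = "bcelldyn_parameter_error")
})

test_that("generated repertoires realize their planted targets through the metrics pipeline", {
  cfg <- tiny_config(seed = 13)
  sim <- simulate_cohort(cfg, months = 0)
  met <- cohort_metrics(sim, months = 0)
  pl <- sim$planted[sim$planted$visit_month == 0L, ]
  # percent unmutated is exact by construction
  expect_equal(met$pct_unmutated[match(pl$patient_id, met$patient_id)], pl$planted_pct)
  # lineage clustering recovers the planted partition size
  expect_equal(met$n_lineages, rep(cfg$n_lineages_baseline, nrow(met)))
  # UMI floor mirrors the upstream consensus filter: nothing lost to it
  expect_true(all(met$n_records >= met$n_clonotypes))
  expect_true(all(met$gini > 0 & met$gini < 1))
})

test_that("degenerate repertoire requests behave as documented", {
  cfg <- tiny_config(seed = 17)
  set.seed(17)
  pools <- bcelldyn:::build_germline_pools(cfg)
  # fully unmutated sample: zero mutation load everywhere
  rec <- generate_repertoire(100, 40, 100, 0.3, 3, 0.04, pools, "P01", 0, cfg)
  m <- compute_sample_metrics(rec)
  expect_equal(m$pct_unmutated, 100)
  expect_equal(m$mean_mutation_freq, 0)
  # Gini target 0: all clonotype UMI counts equal after collapse
  rec0 <- generate_repertoire(50, 20, 10, 0, 2.5, 0.04, pools, "P01", 0, cfg)
  cl <- assign_clonotypes(filter_by_umi_support(rec0))
  expect_equal(length(unique(cl$umi_count)), 1L)
  expect_error(generate_repertoire(10, 20, 0, 0.3, 2, 0.04, pools, "P01", 0, cfg),
               class = "bcelldyn_parameter_error")
})

test_that("cohorts round-trip through the on-disk formats", {
  cfg <- tiny_config(seed = 23)
  dir <- file.path(tempdir(), "roundtrip")
  unlink(dir, recursive = TRUE)
  sim <- generate_cohort(cfg, dir)
  manifest <- tibble::tibble(
    patient_id = sub("_M.*$", "", basename(list.files(dir, pattern = "^P.*tsv$"))),
    visit_month = as.integer(sub("^.*_M(\\d+)\\.tsv$", "\\1",
                                 list.files(dir, pattern = "^P.*tsv$"))),
    path = list.files(dir, pattern = "^P.*tsv$", full.names = TRUE)
  )
  clinical <- read_clinical_table(file.path(dir, "clinical.csv"))
  expect_equal(nrow(clinical), nrow(sim$clinical))
  cohort <- assemble_cohort(clinical, manifest)
  expect_equal(nrow(cohort$exclusions), 0)
  key <- names(sim$repertoires)[1]
  back <- cohort$repertoires[[key]]
  orig <- sim$repertoires[[key]]
  expect_equal(back$sequence_alignment, orig$sequence_alignment)
  expect_equal(back$consensus_count, orig$consensus_count)

  truth <- read_truth_table(file.path(dir, "truth.csv"))
  expect_equal(truth$true_repopulation_month, sim$truth$true_repopulation_month)
  # never-repopulated patients have an empty cell, not a sentinel
  raw <- readLines(file.path(dir, "truth.csv"))
  never <- sim$truth$patient_id[is.na(sim$truth$true_repopulation_month)][1]
  expect_match(grep(never, raw, value = TRUE), paste0(never, ",\\d+,,"))
  unlink(dir, recursive = TRUE)
})
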