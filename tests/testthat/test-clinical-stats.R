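test_that("the omnibus normality statistic matches independently computed values", {
  # expected values computed with an independent implementation of the
  # D'Agostino-Pearson K-squared test on these frozen samples
  x <- c(0.304717, -1.039984, 0.750451, 0.940565, -1.951035, -1.30218,
         0.12784, -0.316243, -0.016801, -0.853044, 0.879398, 0.777792,
         0.066031, 1.127241, 0.467509, -0.859292, 0.368751, -0.958883,
         0.87845, -0.049926)
  r <- dagostino_pearson(x)
  expect_equal(r$statistic, 1.6864870246, tolerance = 1e-9)
  expect_equal(r$p_value, 0.4303125335, tolerance = 1e-9)

  y <- c(1.247386, 0.223576, 1.83797, 1.227086, 0.655796, 0.417087, 0.45332,
         0.077077, 0.179632, 0.68532, 0.38868, 1.264207, 0.708491, 0.23793,
         0.461088, 0.641557, 0.343833, 0.321911, 0.878915, 0.296947,
         1.333702, 1.390864, 1.084083, 0.073028, 1.134068, 1.354338,
         1.12204, 0.280049, 0.320936, 0.165736)
  r2 <- dagostino_pearson(y)
  expect_equal(r2$statistic, 3.3424204613, tolerance = 1e-9)
  expect_equal(r2$p_value, 0.1880193811, tolerance = 1e-9)

  expect_error(dagostino_pearson(rnorm(5)), class = "bcelldyn_insufficient_data")
  expect_error(dagostino_pearson(rep(2, 20)), class = "bcelldyn_degenerate_data")
})

test_that("the normality gate routes small, degenerate and skewed samples to rank tests", {
  expect_equal(normality_gate(list(c(1, 2, 3, 4, 5), rnorm(20))), "nonparametric")
  expect_equal(normality_gate(list(rep(1, 10), rnorm(20))), "nonparametric")
  set.seed(101)
  expect_equal(normality_gate(list(rnorm(50), rnorm(50))), "parametric")
  set.seed(102)
  expect_equal(normality_gate(list(rexp(50), rnorm(50))), "nonparametric")
})

test_that("two-group comparisons pick the gated test and match exact references", {
  # identical normal-looking groups: t path, statistic 0, p = 1
  set.seed(103)
  g <- rnorm(15)
  cmp <- compare_two_groups(g, g)
  expect_equal(cmp$test_name, "t_unpaired")
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 1)

  # small groups force the rank path; exact two-sided p for 1:3 vs 4:6 is 0.1
  cmp2 <- compare_two_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp2$test_name, "mann_whitney")
  expect_equal(cmp2$p_value, 0.1)
  expect_match(cmp2$group_summaries[1], "\\(")

  expect_error(compare_two_groups(1, c(2, 3)), class = "bcelldyn_insufficient_data")
})

test_that("exact Mann-Whitney path equals full permutation enumeration", {
  set.seed(104)
  for (i in 1:30) {
    n1 <- sample(2:7, 1); n2 <- sample(2:7, 1) # below the parametric-gate floor
    repeat { # tie-free samples so the exact path is in force
      a <- round(rnorm(n1), 3); b <- round(rnorm(n2, sample(c(0, 1), 1)), 3)
      if (!any(duplicated(c(a, b)))) break
    }
    expect_equal(compare_two_groups(a, b)$p_value, mann_whitney_oracle(a, b),
                 tolerance = 1e-12)
  }
})

test_that("multi-timepoint comparisons gate between ANOVA and Kruskal-Wallis", {
  set.seed(105)
  g <- rnorm(12)
  same <- compare_timepoints(list(m0 = g, m1 = g, m3 = g))
  expect_equal(same$test_name, "anova_oneway")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_true(all(same$posthoc$p_adjusted >= same$posthoc$p_raw - 1e-12))
  expect_true(all(same$posthoc$p_adjusted <= 1))

  # one shifted group: omnibus blows up, post-hoc isolates the shifted pairs
  set.seed(106)
  grps <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30, 3))
  shifted <- compare_timepoints(grps)
  expect_lt(shifted$p_value, 0.001)
  ph <- shifted$posthoc
  involves_c <- ph$group1 == "c" | ph$group2 == "c"
  expect_true(all(ph$p_adjusted[involves_c] < 0.05))
  expect_true(all(ph$p_adjusted[!involves_c] > 0.05))

  # rank path on clearly non-normal data runs Dunn post-tests
  set.seed(107)
  skewed <- compare_timepoints(list(a = rexp(20), b = rexp(20), c = rexp(20, 0.2)))
  expect_equal(skewed$test_name, "kruskal_wallis")
  expect_equal(skewed$posthoc$method, rep("dunn", 3))
  expect_true(all(skewed$posthoc$p_adjusted >= skewed$posthoc$p_raw - 1e-12))

  expect_error(compare_timepoints(list(a = 1:5, b = 2:6)),
               class = "bcelldyn_parameter_error")
})

test_that("Fisher's exact test matches enumeration and both sidedness conventions", {
  tab <- matrix(c(10, 4, 4, 9), 2, byrow = TRUE)
  expect_equal(round(fisher_exact_2x2(tab, "one")$p_value, 4), 0.0412)
  expect_equal(round(fisher_exact_2x2(tab, "two")$p_value, 4), 0.0570)
  expect_equal(fisher_exact_2x2(matrix(c(1, 0, 0, 1), 2), "one")$p_value, 0.5)
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE), "one"),
               class = "bcelldyn_degenerate_table")

  # two-sided p agrees with the standard exact test on random tables
  set.seed(108)
  for (i in 1:50) {
    t2 <- matrix(rpois(4, 6) + 1, 2)
    expect_equal(fisher_exact_2x2(t2, "two")$p_value,
                 stats::fisher.test(t2)$p.value, tolerance = 1e-9)
    expect_equal(fisher_exact_2x2(t2, "one")$p_value,
                 fisher_oracle(t2, "one"), tolerance = 1e-12)
  }
})

test_that("DAS28 deltas propagate missing scores instead of imputing", {
  cl <- tibble::tibble(
    patient_id = rep(c("P01", "P02", "P03"), each = 5),
    visit_month = rep(c(0L, 1L, 3L, 6L, 12L), 3),
    das28 = c(5.0, 4.0, 3.5, 5.0, 3.8,
              6.0, NA, 4.0, 4.2, 4.2,
              4.0, 4.0, 4.0, 4.0, 4.0)
  )
  d <- delta_das28(cl, 6, 12)
  expect_equal(d$delta_das28[d$patient_id == "P01"], -1.2)
  expect_equal(d$delta_das28[d$patient_id == "P03"], 0)
  d01 <- delta_das28(cl, 0, 1)
  expect_true(is.na(d01$delta_das28[d01$patient_id == "P02"]))
  expect_error(delta_das28(cl, 0, 2), class = "bcelldyn_parameter_error")
})

test_that("EULAR categories follow the response grid, exhaustively and exclusively", {
  expect_equal(eular_response(5.0, 3.0)$category, "good")
  expect_equal(eular_response(5.0, 4.5)$category, "none")
  expect_equal(eular_response(6.0, 4.4)$category, "moderate")
  # boundary: improvement 1.2 exactly is not "good"
  expect_equal(eular_response(4.4, 3.2)$category, "moderate")

  grid <- expand.grid(b = seq(0, 10, 0.25), e = seq(0, 10, 0.25))
  res <- eular_response(grid$b, grid$e)
  expect_true(all(res$category %in% c("good", "moderate", "none")))
  # independent re-derivation of the grid
  imp <- grid$b - grid$e
  want <- ifelse(grid$e <= 3.2,
                 ifelse(imp > 1.2, "good", ifelse(imp > 0.6, "moderate", "none")),
                 ifelse(grid$e <= 5.1,
                        ifelse(imp > 0.6, "moderate", "none"),
                        ifelse(imp > 1.2, "moderate", "none")))
  expect_equal(res$category, want)
})

test_that("planted repopulation-group DAS28 effect is detected in most cohorts", {
  # power check: early vs late repopulator month-6->12 contrast at the
  # configured effect sizes, using planted classes (no repertoires needed)
  set.seed(109)
  hits <- 0
  n_rep <- 60
  for (i in 1:n_rep) {
    sim <- simulate_cohort(desk_config(seed = 5000 + i), repertoires = FALSE)
    dd <- delta_das28(sim$clinical, 6, 12)
    cls <- sim$truth$repopulator_class_true[match(dd$patient_id, sim$truth$patient_id)]
    p <- compare_two_groups(dd$delta_das28[cls == "early"],
                            dd$delta_das28[cls == "late"])$p_value
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("association report covers the headline contrasts and sensitivity variants", {
  sim <- simulate_cohort(desk_config(seed = 51))
  met <- cohort_metrics(sim, lineages = FALSE)
  ep <- call_endpoints(met, sim$clinical, threshold = sim$threshold)
  rep_tbl <- associate_endpoints(sim$clinical, ep$calls)
  expect_setequal(unique(rep_tbl$contrast),
                  c("delta_das28_0_1", "delta_das28_0_3", "delta_das28_6_12",
                    "ada_x_repop_onesided", "ada_x_repop_twosided"))
  expect_equal(nrow(rep_tbl), 5 * 4) # 4 sensitivity variants
  full <- rep_tbl[rep_tbl$include_imputed & rep_tbl$include_retreated, ]
  d612 <- full[full$contrast == "delta_das28_6_12", ]
  expect_lt(d612$mean1, d612$mean2) # early repopulators improve more
  fisher_rows <- full[grepl("ada_x_repop", full$contrast), ]
  expect_true(all(fisher_rows$p_value >= 0 & fisher_rows$p_value <= 1, na.rm = TRUE))
})
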