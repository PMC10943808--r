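#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness and kurtosis into the K-squared
#' statistic, referred to a chi-squared distribution with 2 degrees of
#' freedom. Follows D'Agostino's skewness transformation and the
#' Anscombe-Glynn kurtosis transformation; requires `n >= 8`.
#'
#' @param x numeric sample.
#' @return list with `statistic` (K-squared), `p_value`, `z_skewness`,
#'   `z_kurtosis`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8L) {
    stop_bcd("the omnibus normality test requires n >= 8", "bcelldyn_insufficient_data")
  }
  if (sd(x) == 0) {
    stop_bcd("zero-variance sample: normality test undefined", "bcelldyn_degenerate_data")
  }
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)

  # skewness: D'Agostino (1970) transformation to normality
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt(((n + 1) * (n + 3)) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis: Anscombe & Glynn (1983) transformation
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqrtb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrtb1 * (2 / sqrtb1 + sqrt(1 + 4 / sqrtb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skewness = z1, z_kurtosis = z2, n = n)
}

#' Normality gate for test selection
#'
#' Chooses between the parametric and nonparametric test family the way a
#' normality-screened clinical workflow does: parametric only if every group
#' has at least `min_n` observations, none is degenerate (zero variance),
#' and every group passes the D'Agostino-Pearson omnibus test at `alpha`.
#' The omnibus test is unreliable below about 8 observations, hence the
#' small-n floor.
#'
#' @param groups list of numeric samples.
#' @param alpha normality rejection level (default 0.05).
#' @param min_n smallest group size eligible for the parametric path
#'   (default 8).
#' @return `"parametric"` or `"nonparametric"`.
#' @export
normality_gate <- function(groups, alpha = 0.05, min_n = 8L) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  for (g in groups) {
    if (length(g) < min_n) return("nonparametric")
    if (sd(g) == 0) return("nonparametric")
    if (dagostino_pearson(g)$p_value < alpha) return("nonparametric")
  }
  "parametric"
}

fmt_mean_sd <- function(x) sprintf("%.2f ± %.2f", mean(x), sd(x))
fmt_median_iqr <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  sprintf("%.2f (%.2f – %.2f)", q[2], q[1], q[3])
}

#' Two-group comparison with normality gating
#'
#' Runs either the classic equal-variance unpaired t-test (parametric path)
#' or the two-sided Mann-Whitney test (nonparametric path), chosen by
#' [normality_gate()]. The Mann-Whitney p-value is computed by exact
#' enumeration when both groups have at most 20 observations and no ties are
#' present, and by the tie-corrected normal approximation otherwise. Group
#' summaries are formatted as mean +/- SD on the parametric path and median
#' (IQR) on the nonparametric path.
#'
#' @param a,b numeric samples (each n >= 2 after removing missing values).
#' @return a `group_comparison` list: `test_name`, `statistic`, `p_value`,
#'   `gate`, `group_summaries`, `n_per_group`.
#' @export
compare_two_groups <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop_bcd("each group needs at least 2 observations", "bcelldyn_insufficient_data")
  }
  gate <- normality_gate(list(a, b))
  if (gate == "parametric") {
    fit <- t.test(a, b, var.equal = TRUE)
    out <- list(test_name = "t_unpaired",
                statistic = unname(fit$statistic),
                p_value = fit$p.value,
                gate = gate,
                group_summaries = c(fmt_mean_sd(a), fmt_mean_sd(b)),
                n_per_group = c(length(a), length(b)))
  } else {
    exact <- length(a) <= 20L && length(b) <= 20L && !any(duplicated(c(a, b)))
    fit <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = !exact))
    out <- list(test_name = "mann_whitney",
                statistic = unname(fit$statistic),
                p_value = fit$p.value,
                gate = gate,
                group_summaries = c(fmt_median_iqr(a), fmt_median_iqr(b)),
                n_per_group = c(length(a), length(b)))
  }
  structure(out, class = "group_comparison")
}

#' Dunn's post-hoc pairwise z-tests
#'
#' Pairwise comparisons of mean ranks after a Kruskal-Wallis test, with tie
#' correction and Bonferroni adjustment of the z-test p-values.
#'
#' @param values pooled numeric values.
#' @param groups factor/character of group membership, same length.
#' @return tibble of pairwise comparisons with raw and adjusted p-values.
#' @export
dunn_posthoc <- function(values, groups) {
  keep <- !is.na(values)
  values <- values[keep]
  groups <- as.character(groups)[keep]
  n <- length(values)
  r <- rank(values)
  lev <- unique(groups)
  mean_rank <- vapply(lev, function(g) mean(r[groups == g]), numeric(1))
  n_g <- vapply(lev, function(g) sum(groups == g), numeric(1))
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  rows <- lapply(pairs, function(p) {
    i <- p[1]; j <- p[2]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / n_g[i] + 1 / n_g[j]))
    z <- (mean_rank[i] - mean_rank[j]) / se
    tibble::tibble(group1 = i, group2 = j, z = unname(z),
                   p_raw = unname(2 * pnorm(-abs(z))))
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- pmin(1, out$p_raw * nrow(out))
  out$method <- "dunn"
  out
}

#' Multi-timepoint comparison with normality gating
#'
#' Normality-gated one-way ANOVA (with Bonferroni pairwise post-tests,
#' adjusted p = min(1, raw x m) over the m pairs) or Kruskal-Wallis (with
#' Dunn's pairwise z-tests, Bonferroni-adjusted).
#'
#' @param samples_by_month named list mapping timepoint to numeric sample
#'   (>= 3 groups with n >= 2 each).
#' @return a `group_comparison` list with a `posthoc` tibble.
#' @export
compare_timepoints <- function(samples_by_month) {
  samples_by_month <- lapply(samples_by_month, function(g) g[!is.na(g)])
  if (length(samples_by_month) < 3L) {
    stop_bcd("at least 3 timepoints are required", "bcelldyn_parameter_error")
  }
  if (any(vapply(samples_by_month, length, integer(1)) < 2L)) {
    stop_bcd("each timepoint needs at least 2 observations", "bcelldyn_insufficient_data")
  }
  values <- unlist(samples_by_month, use.names = FALSE)
  groups <- rep(names(samples_by_month), vapply(samples_by_month, length, integer(1)))
  gate <- normality_gate(samples_by_month)
  if (gate == "parametric") {
    fit <- aov(values ~ factor(groups))
    tab <- summary(fit)[[1]]
    lev <- unique(groups)
    pairs <- utils::combn(lev, 2, simplify = FALSE)
    rows <- lapply(pairs, function(p) {
      tt <- t.test(values[groups == p[1]], values[groups == p[2]], var.equal = TRUE)
      tibble::tibble(group1 = p[1], group2 = p[2], p_raw = tt$p.value)
    })
    posthoc <- dplyr::bind_rows(rows)
    posthoc$p_adjusted <- pmin(1, posthoc$p_raw * nrow(posthoc))
    posthoc$method <- "bonferroni"
    out <- list(test_name = "anova_oneway",
                statistic = tab[["F value"]][1],
                p_value = tab[["Pr(>F)"]][1],
                gate = gate, posthoc = posthoc,
                group_summaries = vapply(samples_by_month, fmt_mean_sd, character(1)),
                n_per_group = vapply(samples_by_month, length, integer(1)))
  } else {
    fit <- kruskal.test(values, factor(groups))
    out <- list(test_name = "kruskal_wallis",
                statistic = unname(fit$statistic),
                p_value = fit$p.value,
                gate = gate, posthoc = dunn_posthoc(values, groups),
                group_summaries = vapply(samples_by_month, fmt_median_iqr, character(1)),
                n_per_group = vapply(samples_by_month, length, integer(1)))
  }
  structure(out, class = "group_comparison")
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric tail probabilities for a 2x2 contingency table with
#' all margins positive. The one-sided p-value is the tail in the enrichment
#' direction of the observed table (upper tail of the top-left cell when the
#' sample odds ratio exceeds 1, lower tail otherwise); the two-sided p-value
#' sums the probabilities of all tables, under fixed margins, whose point
#' probability does not exceed the observed one (within a small relative
#' slack for floating-point safety).
#'
#' @param table 2x2 matrix of non-negative integers.
#' @param sided `"two"` or `"one"`.
#' @return a `group_comparison` list with `p_value`, `odds_ratio` (sample
#'   cross-product ratio), and the observed table.
#' @export
fisher_exact_2x2 <- function(table, sided = c("two", "one")) {
  sided <- match.arg(sided)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)) || any(table < 0) || anyNA(table)) {
    stop_bcd("`table` must be a 2x2 matrix of non-negative counts", "bcelldyn_validation_error")
  }
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  if (any(c(r1, r2, c1, c2) == 0)) {
    stop_bcd("degenerate table: all margins must be positive", "bcelldyn_degenerate_table")
  }
  n <- r1 + r2
  klo <- max(0, c1 - r2)
  khi <- min(c1, r1)
  k <- klo:khi
  pk <- dhyper(k, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  if (sided == "one") {
    p <- if (a * d >= b * c_) sum(pk[k >= a]) else sum(pk[k <= a])
  } else {
    p <- sum(pk[pk <= p_obs * (1 + 1e-7)])
  }
  structure(list(test_name = paste0("fisher_exact_", sided, "sided"),
                 p_value = min(1, p),
                 odds_ratio = (a * d) / (b * c_),
                 table = table,
                 n_per_group = c(r1, r2)),
            class = "group_comparison")
}

#' Change in DAS28 between two scheduled visits
#'
#' `das28(to) - das28(from)` per patient; missing whenever either score is
#' missing, so that incomplete timepoints are excluded from downstream
#' tests rather than imputed.
#'
#' @param clinical clinical visit tibble.
#' @param from_month,to_month scheduled visit months.
#' @return tibble with `patient_id` and `delta_das28`.
#' @export
delta_das28 <- function(clinical, from_month, to_month) {
  sched <- unique(clinical$visit_month)
  if (!(from_month %in% sched) || !(to_month %in% sched)) {
    stop_bcd("both months must be scheduled visit months", "bcelldyn_parameter_error")
  }
  from <- clinical[clinical$visit_month == from_month, c("patient_id", "das28")]
  to <- clinical[clinical$visit_month == to_month, c("patient_id", "das28")]
  merged <- dplyr::left_join(from, to, by = "patient_id", suffix = c("_from", "_to"))
  tibble::tibble(patient_id = merged$patient_id,
                 delta_das28 = merged$das28_to - merged$das28_from)
}

#' EULAR response classification
#'
#' Standard EULAR grid on (improvement, attained DAS28): `good` needs an
#' improvement above 1.2 ending at or below 3.2; `none` is an improvement of
#' at most 0.6, or at most 1.2 ending above 5.1; everything else is
#' `moderate`.
#'
#' @param baseline,endpoint DAS28 scores in `[0, 10]` (vectorized).
#' @return tibble with `das28_baseline`, `das28_endpoint`, `improvement`,
#'   `category`.
#' @export
eular_response <- function(baseline, endpoint) {
  if (any(baseline < 0 | baseline > 10 | endpoint < 0 | endpoint > 10, na.rm = TRUE)) {
    stop_bcd("DAS28 scores must lie in [0, 10]", "bcelldyn_validation_error")
  }
  # round to clear floating-point fuzz at the grid boundaries (DAS28 is
  # reported to far fewer decimals than double precision)
  improvement <- round(baseline - endpoint, 10)
  category <- ifelse(
    improvement > 1.2 & endpoint <= 3.2, "good",
    ifelse(improvement <= 0.6 | (improvement <= 1.2 & endpoint > 5.1),
           "none", "moderate")
  )
  tibble::tibble(das28_baseline = baseline, das28_endpoint = endpoint,
                 improvement = improvement, category = category)
}

run_contrast <- function(label, x_by_class, variant) {
  classes <- names(x_by_class)
  if (any(vapply(x_by_class, function(v) sum(!is.na(v)), integer(1)) < 2L)) {
    return(tibble::tibble(
      contrast = label, include_imputed = variant[1], include_retreated = variant[2],
      test_name = NA_character_, gate = NA_character_,
      group1 = classes[1], group2 = classes[2],
      n1 = sum(!is.na(x_by_class[[1]])), n2 = sum(!is.na(x_by_class[[2]])),
      mean1 = NA_real_, mean2 = NA_real_,
      summary1 = NA_character_, summary2 = NA_character_,
      statistic = NA_real_, p_value = NA_real_,
      skipped = "fewer than 2 observations in a class"
    ))
  }
  cmp <- compare_two_groups(x_by_class[[1]], x_by_class[[2]])
  tibble::tibble(
    contrast = label, include_imputed = variant[1], include_retreated = variant[2],
    test_name = cmp$test_name, gate = cmp$gate,
    group1 = classes[1], group2 = classes[2],
    n1 = cmp$n_per_group[1], n2 = cmp$n_per_group[2],
    mean1 = mean(x_by_class[[1]], na.rm = TRUE),
    mean2 = mean(x_by_class[[2]], na.rm = TRUE),
    summary1 = cmp$group_summaries[1], summary2 = cmp$group_summaries[2],
    statistic = cmp$statistic, p_value = cmp$p_value,
    skipped = NA_character_
  )
}

#' Endpoint-outcome association report
#'
#' Produces the headline clinical contrasts: change in DAS28 from baseline
#' to months 1 and 3 by depleter class, change from month 6 to 12 by
#' repopulator class, and the ADA-by-repopulation-within-12-months
#' contingency (both Fisher sidednesses). Each contrast is run on the full
#' cohort and, as sensitivity variants, excluding patients whose endpoint
#' call used imputed samples and/or patients retreated during follow-up.
#'
#' @param clinical clinical visit tibble (with `ada_positive_within_12m` and
#'   `retreated`).
#' @param endpoints endpoint `calls` tibble from [call_endpoints()].
#' @param variants if `FALSE`, only the full-cohort analysis is run.
#' @return tibble of contrasts (one row per contrast x sensitivity variant,
#'   plus Fisher rows with `odds_ratio` and both sided p-values).
#' @export
associate_endpoints <- function(clinical, endpoints, variants = TRUE) {
  patient_retreated <- tapply(clinical$retreated, clinical$patient_id, any)
  variant_grid <- if (variants) {
    list(c(TRUE, TRUE), c(FALSE, TRUE), c(TRUE, FALSE), c(FALSE, FALSE))
  } else list(c(TRUE, TRUE))

  out <- list()
  for (v in variant_grid) {
    keep <- endpoints$patient_id
    if (!v[1]) keep <- setdiff(keep, endpoints$patient_id[endpoints$used_imputation])
    if (!v[2]) keep <- setdiff(keep, names(patient_retreated)[patient_retreated])
    ep <- endpoints[endpoints$patient_id %in% keep, , drop = FALSE]
    cl <- clinical[clinical$patient_id %in% keep, , drop = FALSE]

    for (spec in list(c("delta_das28_0_1", 0, 1, "depleter_class"),
                      c("delta_das28_0_3", 0, 3, "depleter_class"),
                      c("delta_das28_6_12", 6, 12, "repopulator_class"))) {
      dd <- delta_das28(cl, as.integer(spec[2]), as.integer(spec[3]))
      cls <- ep[[spec[4]]][match(dd$patient_id, ep$patient_id)]
      by_class <- list(early = dd$delta_das28[cls == "early"],
                       late = dd$delta_das28[cls == "late"])
      out[[length(out) + 1L]] <- run_contrast(spec[1], by_class, v)
    }

    # ADA x repopulation within 12 months
    ada <- tapply(cl$ada_positive_within_12m, cl$patient_id, function(z) z[1])
    ada <- ada[ep$patient_id]
    repop <- !is.na(ep$repopulation_month)
    known <- !is.na(ada)
    tab <- matrix(c(sum(ada[known] & repop[known]), sum(ada[known] & !repop[known]),
                    sum(!ada[known] & repop[known]), sum(!ada[known] & !repop[known])),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("ada_pos", "ada_neg"), c("repop", "no_repop")))
    for (sided in c("one", "two")) {
      fisher_row <- tryCatch({
        ft <- fisher_exact_2x2(tab, sided)
        tibble::tibble(
          contrast = paste0("ada_x_repop_", sided, "sided"),
          include_imputed = v[1], include_retreated = v[2],
          test_name = ft$test_name, gate = NA_character_,
          group1 = "ada_pos", group2 = "ada_neg",
          n1 = ft$n_per_group[1], n2 = ft$n_per_group[2],
          mean1 = tab[1, 1] / sum(tab[1, ]), mean2 = tab[2, 1] / sum(tab[2, ]),
          summary1 = sprintf("%d/%d repopulated", tab[1, 1], sum(tab[1, ])),
          summary2 = sprintf("%d/%d repopulated", tab[2, 1], sum(tab[2, ])),
          statistic = ft$odds_ratio, p_value = ft$p_value,
          skipped = NA_character_
        )
      }, bcelldyn_degenerate_table = function(e) {
        tibble::tibble(
          contrast = paste0("ada_x_repop_", sided, "sided"),
          include_imputed = v[1], include_retreated = v[2],
          test_name = NA_character_, gate = NA_character_,
          group1 = "ada_pos", group2 = "ada_neg",
          n1 = sum(tab[1, ]), n2 = sum(tab[2, ]),
          mean1 = NA_real_, mean2 = NA_real_,
          summary1 = NA_character_, summary2 = NA_character_,
          statistic = NA_real_, p_value = NA_real_,
          skipped = "degenerate contingency table"
        )
      })
      out[[length(out) + 1L]] <- fisher_row
    }
  }
  dplyr::bind_rows(out)
}
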