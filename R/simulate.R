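# Synthetic longitudinal cohort generator.
#
# The generator plants, per patient, a depletion/repopulation trajectory of
# the percent-unmutated statistic, DAS28 trajectories whose month-6->12
# change differs by repopulation group, ADA status tied to repopulation, and
# missing/failed samples; per visit it then emits an AIRR-style rearrangement
# table whose realized repertoire metrics (Gini, Shannon, mutation load,
# percent unmutated) match per-sample targets by construction. Solvers match
# the Gini and Shannon targets by bisection on the shape of a rank-abundance
# family; percent-unmutated parents are moment-matched so the cohort means of
# the *available* samples reproduce the configured summaries.

BASES <- c("A", "C", "G", "T")

.calib_cache <- new.env(parent = emptyenv())

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

tnorm_moments <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- pnorm(b) - pnorm(a)
  if (!is.finite(z) || z < 1e-14) {
    # essentially all mass beyond one bound: the truncation collapses there
    return(list(mean = if (mu < lo) lo else hi, sd = 0))
  }
  mean <- mu + sd * (dnorm(a) - dnorm(b)) / z
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z -
                 ((dnorm(a) - dnorm(b)) / z)^2)
  list(mean = mean, sd = sqrt(pmax(v, 0)))
}

rtnorm <- function(n, mu, sd, lo, hi) {
  if (sd <= 0) return(rep(clamp(mu, lo, hi), n))
  plo <- pnorm(lo, mu, sd)
  phi <- pnorm(hi, mu, sd)
  clamp(qnorm(runif(n, plo, phi), mu, sd), lo, hi)
}

# Symmetric-truncation jitter: draws N(mean, sd) truncated to
# [mean - h, mean + h] with h = min(mean - lo, hi - mean), so the draw mean
# stays exactly `mean` while respecting the metric's valid range.
jitter_sym <- function(n, mean, sd, lo, hi) {
  h <- min(mean - lo, hi - mean)
  if (!is.finite(h) || h <= 0) return(rep(clamp(mean, lo, hi), n))
  rtnorm(n, mean, sd, mean - h, mean + h)
}

# Solve the parent Normal(mu, sigma) whose [lo, hi]-truncation has the given
# mean and SD (the reference baseline summary was computed over samples that
# all lie above the threshold, so the parent is slightly wider/lower).
calib_truncated_parent <- function(target_mean, target_sd, lo, hi) {
  key <- paste("parent", target_mean, target_sd, lo, hi)
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  obj <- function(par) {
    m <- tnorm_moments(par[1], exp(par[2]), lo, hi)
    (m$mean - target_mean)^2 + (m$sd - target_sd)^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj,
               control = list(reltol = 1e-14, maxit = 2000))
  out <- list(mu = fit$par[1], sd = exp(fit$par[2]))
  .calib_cache[[key]] <- out
  out
}

# Solve the month-1 parent mean so that the mixture of below-threshold
# (depleted) and above-threshold (not-yet-depleted) truncations, weighted by
# the planted composition, has the configured month-1 mean.
calib_mixture_mean <- function(target_mean, sd, thr, w_below) {
  key <- paste("mix", target_mean, sd, thr, w_below)
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  f <- function(mu) {
    w_below * tnorm_moments(mu, sd, 0, thr)$mean +
      (1 - w_below) * tnorm_moments(mu, sd, thr, 100)$mean - target_mean
  }
  mu <- uniroot(f, c(-50, 60), tol = 1e-10)$root
  .calib_cache[[key]] <- mu
  mu
}

# Rank-abundance solvers ------------------------------------------------

#' Solve UMI counts matching a Gini target
#'
#' Discretized power-law rank-abundance curve with a count floor (the floor
#' mirrors the upstream >= 3-UMI consensus filter): rank `i` of `n` receives
#' `max(floor, round(floor * (n/i)^alpha))` UMIs. The shape `alpha` is
#' solved by bisection so the realized Gini of the rounded counts matches
#' `gini_target` within `tol`.
#'
#' @param n_clonotypes number of clonotypes.
#' @param gini_target target Gini in `[0, 1)`.
#' @param count_floor minimum UMI count (default 3).
#' @param tol solver tolerance (default 1e-3).
#' @return integer counts, descending by rank.
#' @export
solve_gini_counts <- function(n_clonotypes, gini_target, count_floor = 3L, tol = 1e-3) {
  assert_scalar_number(gini_target, "gini_target", lower = 0, upper = 1)
  counts_for <- function(alpha) {
    as.integer(pmax(count_floor, round(count_floor * (n_clonotypes / seq_len(n_clonotypes))^alpha)))
  }
  if (gini_target < tol) return(counts_for(0))
  # cap the shape so the top-rank count stays within integer range
  alpha_max <- min(4, log(2^30 / count_floor) / log(max(n_clonotypes, 2)))
  g_hi <- gini_expansion(counts_for(alpha_max))
  if (g_hi + tol < gini_target) {
    stop_bcd(sprintf("Gini target %.3f unreachable for %d clonotypes (max %.3f)",
                     gini_target, n_clonotypes, g_hi),
             "bcelldyn_infeasible_target")
  }
  lo <- 0; hi <- alpha_max
  best <- counts_for(0); best_diff <- abs(gini_expansion(best) - gini_target)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    cm <- counts_for(mid)
    g <- gini_expansion(cm)
    if (abs(g - gini_target) < best_diff) { best <- cm; best_diff <- abs(g - gini_target) }
    if (best_diff <= tol / 4) break
    if (g < gini_target) lo <- mid else hi <- mid
  }
  if (best_diff > tol) {
    stop_bcd(sprintf("Gini solver did not reach target %.3f (best %.4f off)",
                     gini_target, best_diff),
             "bcelldyn_infeasible_target")
  }
  best
}

#' Solve lineage sizes matching a Shannon target
#'
#' Allocates `n_clonotypes` over `n_lineages` lineages (each at least 1)
#' with a power-law weight profile whose shape is solved by bisection so the
#' Shannon entropy of the clonotypes-per-lineage distribution matches
#' `shannon_target`. Targets above the `ln(n_lineages)` ceiling are clamped
#' to the maximum attainable entropy.
#'
#' @param n_lineages,n_clonotypes allocation dimensions
#'   (`n_clonotypes >= n_lineages >= 1`).
#' @param shannon_target target entropy in nats.
#' @param tol solver tolerance (default 1e-3).
#' @return integer sizes summing to `n_clonotypes`.
#' @export
solve_lineage_sizes <- function(n_lineages, n_clonotypes, shannon_target, tol = 1e-3) {
  if (n_clonotypes < n_lineages || n_lineages < 1) {
    stop_bcd("need n_clonotypes >= n_lineages >= 1", "bcelldyn_parameter_error")
  }
  extra <- n_clonotypes - n_lineages
  sizes_for <- function(beta) {
    if (extra == 0L) return(rep(1L, n_lineages))
    w <- (n_lineages / seq_len(n_lineages))^beta
    quota <- extra * w / sum(w)
    alloc <- floor(quota)
    rem <- extra - sum(alloc)
    if (rem > 0) {
      frac_order <- order(quota - alloc, decreasing = TRUE)
      alloc[frac_order[seq_len(rem)]] <- alloc[frac_order[seq_len(rem)]] + 1
    }
    as.integer(1L + alloc)
  }
  h_max <- shannon_lineage_diversity(sizes_for(0))
  target <- min(shannon_target, h_max)
  lo <- 0; hi <- 10
  best <- sizes_for(0); best_diff <- abs(h_max - target)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    sm <- sizes_for(mid)
    h <- shannon_lineage_diversity(sm)
    if (abs(h - target) < best_diff) { best <- sm; best_diff <- abs(h - target) }
    if (best_diff <= tol / 4) break
    if (h > target) lo <- mid else hi <- mid
  }
  if (best_diff > 0.2) {
    stop_bcd(sprintf("Shannon solver %.3f away from target %.3f", best_diff, shannon_target),
             "bcelldyn_infeasible_target")
  }
  best
}

# Configuration ----------------------------------------------------------

#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic cohort generator.
#' Defaults are the study-scale cohort summaries: 23 patients seen at 0, 1,
#' 3, 6 and 12 months; baseline percent-unmutated 40.0 +/- 17.8 against
#' month-1 4.33 +/- 3.98 (2.54 +/- 3.38 at later depleted visits,
#' 23.1 +/- 26.5 after repopulation); Gini 0.27 -> 0.52 and Shannon
#' 7.53 -> 4.75 from baseline to month 1; mutation load 0.04 -> 0.07
#' mutations/bp; depletion months distributed 14/5/4 over months 1/3/6 and
#' repopulation 2/5/... per the joint composition (9 patients never
#' repopulate within follow-up); early/late repopulators differ in their
#' month-6->12 DAS28 change (-1.17 +/- 0.96 vs 0.18 +/- 0.67); ADA status
#' is planted conditional on repopulation within 12 months (P = 10/14 vs
#' 4/13); 5% of follow-up samples go missing (failed amplification at
#' depleted visits, not collected otherwise).
#'
#' @param n_patients cohort size (default 23).
#' @param visit_months visit schedule in months since first infusion.
#' @param seed RNG seed for [simulate_cohort()].
#' @param clonotypes_per_sample,n_lineages_baseline baseline repertoire
#'   size; later visits scale from these (see the month profile in
#'   [simulate_cohort()] details).
#' @param ... any other configuration field (see `sim_config()` source for
#'   the full default list).
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_patients = 23L, visit_months = c(0L, 1L, 3L, 6L, 12L),
                       seed = 1L, clonotypes_per_sample = 5000L,
                       n_lineages_baseline = 2500L, ...) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    visit_months = as.integer(visit_months),
    seed = as.integer(seed),
    baseline_unmutated_mean = 40.0, baseline_unmutated_sd = 17.8,
    month1_unmutated_mean = 4.33, month1_unmutated_sd = 3.98,
    depleted_unmutated_mean = 2.54, depleted_unmutated_sd = 3.38,
    repop_unmutated_mean = 23.1, repop_unmutated_sd = 26.5,
    baseline_gini_target = 0.27, baseline_gini_sd = 0.14,
    month1_gini_target = 0.52, month1_gini_sd = 0.08,
    baseline_shannon_target = 7.53, baseline_shannon_sd = 0.49,
    month1_shannon_target = 4.75, month1_shannon_sd = 1.06,
    month12_shannon_target = 5.93, month12_shannon_sd = 1.20,
    baseline_mutload_mean = 0.04, baseline_mutload_sd = 0.01,
    month1_mutload_mean = 0.07, month1_mutload_sd = 0.01,
    month12_mutload_mean = 0.06, month12_mutload_sd = 0.02,
    depletion_month_probs = c(`1` = 14, `3` = 5, `6` = 4) / 23,
    repopulation_month_probs = c(`3` = 2, `6` = 7, `12` = 5, never = 9) / 23,
    das28_baseline_early_dep_mean = 4.1, das28_baseline_early_dep_sd = 1.1,
    das28_baseline_late_dep_mean = 4.6, das28_baseline_late_dep_sd = 0.9,
    delta_das28_0to1_early_mean = 0.0, delta_das28_0to1_early_sd = 0.6,
    delta_das28_0to1_late_mean = -0.9, delta_das28_0to1_late_sd = 0.8,
    delta_das28_0to3_early_mean = -0.5, delta_das28_0to3_early_sd = 1.1,
    delta_das28_0to3_late_mean = -1.5, delta_das28_0to3_late_sd = 0.8,
    das28_month6_early_repop_mean = 3.36, das28_month6_early_repop_sd = 0.89,
    das28_month6_late_repop_mean = 3.42, das28_month6_late_repop_sd = 1.53,
    delta_das28_6to12_early_mean = -1.17, delta_das28_6to12_early_sd = 0.96,
    delta_das28_6to12_late_mean = 0.18, delta_das28_6to12_late_sd = 0.67,
    p_ada_given_repop = 10 / 14, p_ada_given_no_repop = 4 / 13,
    p_retreat = 6 / 28,
    missing_sample_rate = 0.05,
    das28_missing_rate = 0.05,
    clonotypes_per_sample = as.integer(clonotypes_per_sample),
    n_lineages_baseline = as.integer(n_lineages_baseline),
    v_region_length = 312L,
    n_v_genes = 40L, n_d_genes = 25L, n_j_genes = 6L,
    junction_lengths = seq(30L, 87L, 3L),
    junction_distance_threshold = 0.15,
    umi_floor = 3L,
    split_record_rate = 0.05,
    p_d_call_missing = 0.03,
    p_esr_basis = 0.15
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop_bcd(sprintf("unknown configuration field(s): %s", paste(unknown, collapse = ", ")),
             "bcelldyn_validation_error")
  }
  cfg[names(dots)] <- dots
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$missing_sample_rate, cfg$das28_missing_rate, cfg$p_retreat,
             cfg$p_ada_given_repop, cfg$p_ada_given_no_repop,
             cfg$split_record_rate, cfg$p_d_call_missing, cfg$p_esr_basis)
  if (any(probs < 0 | probs > 1)) {
    stop_bcd("all probabilities must lie in [0, 1]", "bcelldyn_validation_error")
  }
  for (dist in list(cfg$depletion_month_probs, cfg$repopulation_month_probs)) {
    if (any(dist < 0) || abs(sum(dist) - 1) > 1e-9) {
      stop_bcd("month probability distributions must be non-negative and sum to 1",
               "bcelldyn_validation_error")
    }
  }
  for (g in c(cfg$baseline_gini_target, cfg$month1_gini_target)) {
    assert_scalar_number(g, "gini target", lower = 0, upper = 1)
  }
  if (cfg$n_patients < 1 || cfg$clonotypes_per_sample < cfg$n_lineages_baseline ||
      cfg$n_lineages_baseline < 1) {
    stop_bcd("need n_patients >= 1 and clonotypes_per_sample >= n_lineages_baseline >= 1",
             "bcelldyn_validation_error")
  }
  sds <- c(cfg$baseline_unmutated_sd, cfg$month1_unmutated_sd,
           cfg$baseline_shannon_sd, cfg$month1_shannon_sd,
           cfg$baseline_mutload_sd, cfg$month1_mutload_sd)
  if (any(!is.finite(sds) | sds < 0)) {
    stop_bcd("all SDs must be finite and non-negative", "bcelldyn_validation_error")
  }
  invisible(cfg)
}

#' Canonical threshold implied by a configuration
#'
#' `max(0, baseline mean - 2 x baseline SD)` of the configured baseline
#' percent-unmutated distribution: the planted population value of the
#' depletion/repopulation threshold (4.4 at the defaults).
#'
#' @param config a `sim_config`.
#' @export
planted_threshold <- function(config) {
  max(0, config$baseline_unmutated_mean - 2 * config$baseline_unmutated_sd)
}

# Per-visit repertoire shape profile. Month 0/1 values are the configured
# summaries; months 3-12 interpolate the reversion toward baseline reported
# for the follow-up period (month 3 mirrors month 1, where the dip is
# deepest; month 12 uses the configured month-12 diversity and mutation
# summaries). Sizes scale with the configured baseline sizes.
month_profile <- function(cfg, month) {
  ncl <- cfg$clonotypes_per_sample
  nlin <- cfg$n_lineages_baseline
  prof <- switch(as.character(month),
    "0" = list(gini = cfg$baseline_gini_target, gini_sd = cfg$baseline_gini_sd,
               shannon = cfg$baseline_shannon_target, shannon_sd = cfg$baseline_shannon_sd,
               mut = cfg$baseline_mutload_mean, mut_sd = cfg$baseline_mutload_sd,
               n_clono = ncl, n_lin = nlin),
    "1" = list(gini = cfg$month1_gini_target, gini_sd = cfg$month1_gini_sd,
               shannon = cfg$month1_shannon_target, shannon_sd = cfg$month1_shannon_sd,
               mut = cfg$month1_mutload_mean, mut_sd = cfg$month1_mutload_sd,
               n_clono = max(20L, as.integer(round(0.2 * ncl))),
               n_lin = max(5L, as.integer(round(0.16 * nlin)))),
    "3" = list(gini = cfg$month1_gini_target, gini_sd = cfg$month1_gini_sd,
               shannon = cfg$month1_shannon_target, shannon_sd = cfg$month1_shannon_sd,
               mut = cfg$month1_mutload_mean, mut_sd = cfg$month1_mutload_sd,
               n_clono = max(20L, as.integer(round(0.2 * ncl))),
               n_lin = max(5L, as.integer(round(0.16 * nlin)))),
    "6" = list(gini = 0.45, gini_sd = 0.12,
               shannon = 5.3, shannon_sd = 1.1,
               mut = 0.065, mut_sd = 0.015,
               n_clono = max(20L, as.integer(round(0.4 * ncl))),
               n_lin = max(5L, as.integer(round(0.32 * nlin)))),
    "12" = list(gini = 0.35, gini_sd = 0.14,
                shannon = cfg$month12_shannon_target, shannon_sd = cfg$month12_shannon_sd,
                mut = cfg$month12_mutload_mean, mut_sd = cfg$month12_mutload_sd,
                n_clono = max(20L, as.integer(round(0.6 * ncl))),
                n_lin = max(5L, as.integer(round(0.48 * nlin)))),
    # unscheduled month: baseline-like
    list(gini = cfg$baseline_gini_target, gini_sd = cfg$baseline_gini_sd,
         shannon = cfg$baseline_shannon_target, shannon_sd = cfg$baseline_shannon_sd,
         mut = cfg$baseline_mutload_mean, mut_sd = cfg$baseline_mutload_sd,
         n_clono = ncl, n_lin = nlin)
  )
  prof$n_lin <- min(prof$n_lin, prof$n_clono)
  prof
}

largest_remainder <- function(total, weights) {
  if (sum(weights) == 0) return(rep(0L, length(weights)))
  quota <- total * weights / sum(weights)
  alloc <- floor(quota)
  rem <- total - sum(alloc)
  if (rem > 0) {
    ord <- order(quota - alloc, decreasing = TRUE)
    alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1
  }
  as.integer(alloc)
}

# Joint (depletion month, repopulation month) composition: both configured
# marginals are realized exactly (largest-remainder rounding), then each
# repopulation stratum is spread over the depletion months it can legally
# follow (r > d), proportionally to the remaining depletion counts. At the
# defaults this reproduces the study-scale joint table.
joint_endpoint_counts <- function(cfg) {
  n <- cfg$n_patients
  d_months <- as.integer(names(cfg$depletion_month_probs))
  n_d <- largest_remainder(n, cfg$depletion_month_probs)
  r_names <- names(cfg$repopulation_month_probs)
  n_r <- largest_remainder(n, cfg$repopulation_month_probs)
  remaining <- n_d
  counts <- integer(0)
  r_numeric <- suppressWarnings(as.integer(r_names))
  ord <- order(is.na(r_numeric), r_numeric) # restrictive strata first, never last
  for (k in ord) {
    r <- r_numeric[k]
    eligible <- if (is.na(r)) seq_along(d_months) else which(d_months < r)
    if (sum(remaining[eligible]) < n_r[k]) {
      stop_bcd("repopulation-month distribution is incompatible with the depletion-month distribution",
               "bcelldyn_validation_error")
    }
    take <- largest_remainder(n_r[k], remaining[eligible])
    remaining[eligible] <- remaining[eligible] - take
    lab <- sprintf("d%d_r%s", d_months[eligible], if (is.na(r)) "N" else r)
    counts[lab] <- take
  }
  counts[counts > 0]
}

parse_endpoint_class <- function(cls) {
  parts <- regmatches(cls, regexec("^d(\\d+)_r(\\d+|N)$", cls))[[1]]
  list(d = as.integer(parts[2]),
       r = if (parts[3] == "N") NA_integer_ else as.integer(parts[3]))
}

# Planted trajectory state of a patient at a visit month.
visit_state <- function(month, d, r) {
  if (month == 0L) "baseline"
  else if (month < d) "pre"
  else if (is.na(r) || month < r) "depleted"
  else "repop"
}

build_germline_pools <- function(cfg) {
  fam <- rep(1:7, length.out = cfg$n_v_genes)
  num <- as.integer(stats::ave(fam, fam, FUN = seq_along))
  v_labels <- sprintf("IGHV%d-%d*01", fam, num)
  d_fam <- rep(1:7, length.out = cfg$n_d_genes)
  d_num <- as.integer(stats::ave(d_fam, d_fam, FUN = seq_along))
  list(
    v_labels = v_labels,
    v_germ = cpp_random_seqs(cfg$n_v_genes, cfg$v_region_length),
    j_labels = sprintf("IGHJ%d*01", seq_len(cfg$n_j_genes)),
    d_labels = sprintf("IGHD%d-%d*01", d_fam, d_num)
  )
}

#' Generate one synthetic repertoire sample
#'
#' Emits AIRR-style rearrangement records whose realized metrics match the
#' supplied targets: UMI counts from the Gini-solved rank-abundance curve,
#' lineage sizes from the Shannon-solved allocation, exactly `n_unmutated`
#' clonotypes with a germline-identical IGHV segment, and Poisson mismatch
#' counts on the rest scaled so the expected per-sample mean mutation
#' frequency equals `mutload_target`. Lineage members share V/J gene and
#' junction length and sit within the clustering threshold of their lineage
#' ancestor, so lineage clustering recovers the planted partition.
#'
#' @param n_clonotypes,n_lineages repertoire dimensions.
#' @param n_unmutated number of clonotypes with zero IGHV mismatches.
#' @param gini_target,shannon_target,mutload_target per-sample targets.
#' @param pools germline pools from the cohort generator.
#' @param patient_id,visit_month identifiers stamped on the records.
#' @param cfg a `sim_config`.
#' @return tibble of rearrangement records.
#' @export
generate_repertoire <- function(n_clonotypes, n_lineages, n_unmutated,
                                gini_target, shannon_target, mutload_target,
                                pools, patient_id, visit_month, cfg) {
  if (n_clonotypes < n_lineages || n_lineages < 1) {
    stop_bcd("need n_clonotypes >= n_lineages >= 1", "bcelldyn_parameter_error")
  }
  if (n_unmutated < 0 || n_unmutated > n_clonotypes) {
    stop_bcd("n_unmutated must lie in [0, n_clonotypes]", "bcelldyn_parameter_error")
  }
  lv <- cfg$v_region_length
  counts <- sample(solve_gini_counts(n_clonotypes, gini_target, cfg$umi_floor))
  sizes <- solve_lineage_sizes(n_lineages, n_clonotypes, shannon_target)

  v_idx <- sample.int(length(pools$v_labels), n_lineages, replace = TRUE)
  j_idx <- sample.int(length(pools$j_labels), n_lineages, replace = TRUE)
  jl <- sample(cfg$junction_lengths, n_lineages, replace = TRUE)
  anc <- character(n_lineages)
  for (L in unique(jl)) {
    sel <- which(jl == L)
    anc[sel] <- cpp_random_seqs(length(sel), L)
  }

  lineage_of <- rep(seq_len(n_lineages), sizes)
  junction <- cpp_junction_variants(anc, lineage_of, cfg$junction_distance_threshold)

  # IGHV mismatches: exactly n_unmutated germline-identical clonotypes; the
  # rest draw Poisson counts whose mean is scaled by 1/(1 - unmutated
  # fraction) so the sample mean mutation frequency is centred on the target.
  n <- n_clonotypes
  mut_count <- integer(n)
  mutated <- rep(TRUE, n)
  if (n_unmutated > 0) mutated[sample.int(n, n_unmutated)] <- FALSE
  n_mut <- sum(mutated)
  if (n_mut > 0) {
    lambda <- mutload_target * lv / (n_mut / n)
    mut_count[mutated] <- pmin(lv, pmax(1L, rpois(n_mut, lambda)))
  }

  allele_of <- v_idx[lineage_of]
  v_str <- cpp_build_v_sequences(pools$v_germ, allele_of, mut_count)

  seq_alignment <- paste0(v_str, junction)
  germ_alignment <- paste0(pools$v_germ[allele_of], anc[lineage_of])
  d_call <- sample(pools$d_labels, n, replace = TRUE)
  d_call[runif(n) < cfg$p_d_call_missing] <- ""

  rec <- tibble::tibble(
    sequence_id = sprintf("%s_M%02d_%05d", patient_id, visit_month, seq_len(n)),
    patient_id = patient_id,
    visit_month = as.integer(visit_month),
    v_call = pools$v_labels[allele_of],
    d_call = d_call,
    j_call = pools$j_labels[j_idx[lineage_of]],
    junction = junction,
    sequence_alignment = seq_alignment,
    germline_alignment = germ_alignment,
    consensus_count = as.integer(counts),
    productive = TRUE
  )

  # split a small fraction of well-supported clonotypes into two consensus
  # records (same rearrangement, UMIs divided), exercising the collapse step
  splittable <- rec$consensus_count >= 2L * cfg$umi_floor
  split_sel <- which(splittable & runif(n) < cfg$split_record_rate)
  if (length(split_sel)) {
    twin <- rec[split_sel, , drop = FALSE]
    c1 <- rec$consensus_count[split_sel] %/% 2L
    rec$consensus_count[split_sel] <- c1
    twin$consensus_count <- twin$consensus_count - c1
    twin$sequence_id <- paste0(twin$sequence_id, "b")
    rec <- dplyr::bind_rows(rec, twin)
  }
  rec
}

#' Simulate a synthetic longitudinal cohort
#'
#' Plants per-patient depletion/repopulation truth, DAS28 trajectories, ADA
#' status and missing samples, then emits an AIRR-style repertoire for every
#' available visit. Identical configuration and seed give identical output.
#'
#' @param config a [sim_config()].
#' @param months visit months for which repertoires are generated (default
#'   all scheduled months); the clinical table and planted truth always
#'   cover the full schedule.
#' @param repertoires if `FALSE`, only clinical table, truth and planted
#'   trajectories are produced (fast path for endpoint/DAS28 studies that
#'   do not touch sequence-level data).
#' @return a `bcr_cohort_sim` (also a `bcr_cohort`): list with `clinical`,
#'   `repertoires`, `truth`, `planted`, `threshold` (planted population
#'   threshold), and `config`.
#' @export
simulate_cohort <- function(config, months = NULL, repertoires = TRUE) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  patients <- sprintf("P%02d", seq_len(n))
  thr <- planted_threshold(config)
  if (is.null(months)) months <- config$visit_months

  joint <- joint_endpoint_counts(config)
  cls <- sample(rep(names(joint), joint))
  dr <- lapply(cls, parse_endpoint_class)
  d <- vapply(dr, function(x) x$d, integer(1))
  r <- vapply(dr, function(x) x$r, integer(1))
  repop12 <- !is.na(r)
  early_repop <- !is.na(r) & r <= 6L

  ada <- ifelse(repop12,
                runif(n) < config$p_ada_given_repop,
                runif(n) < config$p_ada_given_no_repop)
  retreated6 <- runif(n) < config$p_retreat

  truth <- tibble::tibble(
    patient_id = patients,
    true_depletion_month = d,
    true_repopulation_month = r,
    depleter_class_true = ifelse(d == 1L, "early", "late"),
    repopulator_class_true = ifelse(early_repop, "early", "late"),
    ada_positive = ada
  )

  # DAS28 trajectories anchored on the planted group summaries: baseline and
  # month-1/3 changes differ by depleter class, month 6 and the 6->12 change
  # by repopulator class. Anchoring month 6 directly (rather than walking
  # from month 3) keeps its spread at the configured group SDs so that the
  # [0, 10] clamp at month 12 stays a rare event.
  early_dep <- d == 1L
  das0 <- clamp(ifelse(early_dep,
                       rnorm(n, config$das28_baseline_early_dep_mean, config$das28_baseline_early_dep_sd),
                       rnorm(n, config$das28_baseline_late_dep_mean, config$das28_baseline_late_dep_sd)),
                0, 10)
  d01 <- ifelse(early_dep,
                rnorm(n, config$delta_das28_0to1_early_mean, config$delta_das28_0to1_early_sd),
                rnorm(n, config$delta_das28_0to1_late_mean, config$delta_das28_0to1_late_sd))
  d03 <- ifelse(early_dep,
                rnorm(n, config$delta_das28_0to3_early_mean, config$delta_das28_0to3_early_sd),
                rnorm(n, config$delta_das28_0to3_late_mean, config$delta_das28_0to3_late_sd))
  das1 <- clamp(das0 + d01, 0, 10)
  das3 <- clamp(das0 + d03, 0, 10)
  das6 <- clamp(ifelse(early_repop,
                       rnorm(n, config$das28_month6_early_repop_mean, config$das28_month6_early_repop_sd),
                       rnorm(n, config$das28_month6_late_repop_mean, config$das28_month6_late_repop_sd)),
                0, 10)
  d612 <- ifelse(early_repop,
                 rnorm(n, config$delta_das28_6to12_early_mean, config$delta_das28_6to12_early_sd),
                 rnorm(n, config$delta_das28_6to12_late_mean, config$delta_das28_6to12_late_sd))
  das12 <- clamp(das6 + d612, 0, 10)
  das_by_month <- cbind(`0` = das0, `1` = das1, `3` = das3, `6` = das6, `12` = das12)

  mu_base <- calib_truncated_parent(config$baseline_unmutated_mean,
                                    config$baseline_unmutated_sd, thr, 100)
  w_below_m1 <- unname(config$depletion_month_probs["1"])
  mu_m1 <- calib_mixture_mean(config$month1_unmutated_mean,
                              config$month1_unmutated_sd, thr, w_below_m1)

  visit_rows <- list()
  for (i in seq_len(n)) {
    for (m in config$visit_months) {
      st <- visit_state(m, d[i], r[i])
      if (m == 0L) {
        status <- "ok"
      } else if (runif(1) < config$missing_sample_rate) {
        status <- if (st == "depleted") "failed_amplification" else "not_collected"
      } else {
        status <- "ok"
      }
      prof <- month_profile(config, m)
      pct <- NA_real_
      k <- NA_integer_
      if (status == "ok") {
        raw <- switch(st,
          baseline = rtnorm(1, mu_base$mu, mu_base$sd, thr, 100),
          pre = rtnorm(1, mu_m1, config$month1_unmutated_sd, thr, 100),
          depleted = if (m == 1L) {
            rtnorm(1, mu_m1, config$month1_unmutated_sd, 0, thr)
          } else {
            rtnorm(1, config$depleted_unmutated_mean, config$depleted_unmutated_sd, 0, thr)
          },
          repop = rtnorm(1, config$repop_unmutated_mean, config$repop_unmutated_sd, thr, 100)
        )
        nc <- prof$n_clono
        kthr <- as.integer(ceiling(thr * nc / 100 - 1e-9))
        k <- as.integer(round(raw * nc / 100))
        if (st == "depleted") {
          k <- min(k, max(kthr - 1L, 0L))
        } else {
          k <- max(k, min(kthr, nc))
        }
        k <- clamp(k, 0L, nc)
        pct <- 100 * k / nc
      }
      das <- das_by_month[i, as.character(m)]
      if (runif(1) < config$das28_missing_rate) das <- NA_real_
      visit_rows[[length(visit_rows) + 1L]] <- tibble::tibble(
        patient_id = patients[i], visit_month = m,
        das28 = round(das, 2),
        das28_basis = if (runif(1) < config$p_esr_basis) "ESR" else "CRP",
        sample_status = status,
        retreated = (m == 6L && retreated6[i]),
        ada_positive_within_12m = ada[i],
        state = st, planted_pct = pct, n_unmutated = k,
        n_clonotypes = if (status == "ok") prof$n_clono else NA_integer_
      )
    }
  }
  planted <- dplyr::bind_rows(visit_rows)
  clinical <- planted[, c("patient_id", "visit_month", "das28", "das28_basis",
                          "sample_status", "retreated", "ada_positive_within_12m")]

  reps <- list()
  if (repertoires) {
    pools <- build_germline_pools(config)
    for (i in seq_len(n)) {
      for (m in intersect(config$visit_months, months)) {
        row <- planted[planted$patient_id == patients[i] & planted$visit_month == m, ]
        if (row$sample_status != "ok") next
        prof <- month_profile(config, m)
        gini_t <- jitter_sym(1, prof$gini, prof$gini_sd, 0.02, 0.95)
        sh_max <- log(prof$n_lin) * 0.999
        sh_t <- jitter_sym(1, min(prof$shannon, sh_max), prof$shannon_sd, 0.2, sh_max)
        mut_t <- jitter_sym(1, prof$mut, prof$mut_sd, 0.002, 0.5)
        reps[[paste(patients[i], m, sep = "|")]] <- generate_repertoire(
          prof$n_clono, prof$n_lin, row$n_unmutated,
          gini_t, sh_t, mut_t, pools, patients[i], m, config
        )
      }
    }
  }

  structure(
    list(clinical = clinical, repertoires = reps, truth = truth,
         planted = planted, threshold = thr, config = config,
         exclusions = tibble::tibble(patient_id = character(), reason = character())),
    class = c("bcr_cohort_sim", "bcr_cohort")
  )
}

#' Write a simulated cohort to disk
#'
#' One AIRR TSV per available (patient, visit) repertoire, plus
#' `clinical.csv` and `truth.csv`.
#'
#' @param sim a `bcr_cohort_sim` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, a manifest tibble (`patient_id`, `visit_month`, `path`).
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  keys <- names(sim$repertoires)
  manifest <- lapply(keys, function(k) {
    rec <- sim$repertoires[[k]]
    path <- file.path(dir, sprintf("%s_M%02d.tsv", rec$patient_id[1], rec$visit_month[1]))
    write_rearrangements(rec, path)
    tibble::tibble(patient_id = rec$patient_id[1],
                   visit_month = rec$visit_month[1], path = path)
  })
  readr::write_csv(sim$clinical, file.path(dir, "clinical.csv"), na = "", progress = FALSE)
  write_truth_table(sim$truth, file.path(dir, "truth.csv"))
  invisible(dplyr::bind_rows(manifest))
}

#' Generate a cohort directly to disk
#'
#' [simulate_cohort()] followed by [write_cohort()]; validation errors are
#' raised before any file is written.
#'
#' @param config a `sim_config`.
#' @param out_dir output directory.
#' @return invisibly, the in-memory `bcr_cohort_sim`.
#' @export
generate_cohort <- function(config, out_dir) {
  validate_sim_config(config)
  sim <- simulate_cohort(config)
  write_cohort(sim, out_dir)
  invisible(sim)
}

#' Write / read the planted truth table
#'
#' CSV with one row per patient; a patient who never repopulated has an
#' empty `true_repopulation_month` cell, not a sentinel number.
#'
#' @param truth truth tibble from [simulate_cohort()].
#' @param path CSV path.
#' @export
write_truth_table <- function(truth, path) {
  if (anyNA(truth$patient_id)) {
    stop_bcd("truth must be populated for all patients", "bcelldyn_validation_error")
  }
  readr::write_csv(truth, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    patient_id = readr::col_character(),
                    true_depletion_month = readr::col_integer(),
                    true_repopulation_month = readr::col_integer(),
                    depleter_class_true = readr::col_character(),
                    repopulator_class_true = readr::col_character(),
                    ada_positive = readr::col_logical()
                  ))
}
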