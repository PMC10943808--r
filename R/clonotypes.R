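#' Filter rearrangements by UMI support
#'
#' Keeps consensus sequences represented by at least `min_umis` distinct
#' UMIs, the final quality gate applied before repertoire statistics.
#'
#' @param records rearrangement data frame with a `consensus_count` column.
#' @param min_umis minimum number of distinct UMIs (default 3).
#' @return the filtered data frame, row order preserved.
#' @export
filter_by_umi_support <- function(records, min_umis = 3L) {
  if (!is.numeric(min_umis) || length(min_umis) != 1L || min_umis < 1) {
    stop_bcd("`min_umis` must be a single integer >= 1", "bcelldyn_parameter_error")
  }
  if (is.null(records$consensus_count) || anyNA(records$consensus_count)) {
    stop_bcd("`consensus_count` must be present on all records", "bcelldyn_validation_error")
  }
  records[records$consensus_count >= min_umis, , drop = FALSE]
}

#' Collapse rearrangement records into clonotypes
#'
#' A clonotype is a unique IGHV-IGHD-IGHJ rearrangement at the nucleotide
#' sequence level: records sharing `v_call`, `d_call`, `j_call` and the
#' ungapped rearrangement sequence collapse into one clonotype whose
#' `umi_count` is the summed `consensus_count`. IGHV mutation statistics are
#' taken from a single representative record per clonotype — the member with
#' the highest `consensus_count`, ties broken by lexicographically smallest
#' `sequence_id` — by counting mismatches between `sequence_alignment` and
#' `germline_alignment` over comparable (non-gap) positions within the first
#' `v_region_end` gapped positions, i.e. the IGHV region up to the end of
#' FWR3 in the IMGT frame.
#'
#' @param records UMI-filtered rearrangement data frame from one sample.
#' @param v_region_end last gapped position of the IGHV region (default 312,
#'   the IMGT V-REGION nucleotide length through FWR3).
#' @return a tibble with one row per clonotype: the key fields, `umi_count`,
#'   `abundance_pct` (percent of sample UMIs), `mutation_count`,
#'   `ighv_aligned_length`, `mutation_freq`, `representative_id`, and a
#'   `lineage_id` column initialised to `NA` (see [cluster_lineages()]).
#' @export
assign_clonotypes <- function(records, v_region_end = 312L) {
  if (NROW(records) == 0L) {
    return(tibble::tibble(
      v_call = character(), d_call = character(), j_call = character(),
      sequence = character(), junction = character(), umi_count = integer(),
      abundance_pct = numeric(), mutation_count = integer(),
      ighv_aligned_length = integer(), mutation_freq = numeric(),
      representative_id = character(), lineage_id = integer()
    ))
  }
  seq_ungapped <- gsub("[.\\-]", "", records$sequence_alignment)
  key <- paste(records$v_call, records$d_call, records$j_call, seq_ungapped, sep = "\r")
  grp <- match(key, unique(key))

  ord <- order(grp, -records$consensus_count, records$sequence_id)
  first_of_grp <- ord[!duplicated(grp[ord])]
  rep_rows <- first_of_grp[order(grp[first_of_grp])]

  umi <- as.integer(rowsum(as.integer(records$consensus_count), grp)[, 1])
  mm <- cpp_ighv_mismatch(records$sequence_alignment[rep_rows],
                          records$germline_alignment[rep_rows],
                          as.integer(v_region_end))
  if (any(mm[, "comparable_length"] == 0L)) {
    bad <- records$sequence_id[rep_rows][mm[, "comparable_length"] == 0L]
    stop_bcd(sprintf("no comparable IGHV positions for record(s): %s",
                     paste(head(bad, 3), collapse = ", ")),
             "bcelldyn_validation_error")
  }
  tibble::tibble(
    v_call = records$v_call[rep_rows],
    d_call = records$d_call[rep_rows],
    j_call = records$j_call[rep_rows],
    sequence = seq_ungapped[rep_rows],
    junction = records$junction[rep_rows],
    umi_count = umi,
    abundance_pct = 100 * umi / sum(umi),
    mutation_count = unname(mm[, "mutations"]),
    ighv_aligned_length = unname(mm[, "comparable_length"]),
    mutation_freq = unname(mm[, "mutations"] / mm[, "comparable_length"]),
    representative_id = records$sequence_id[rep_rows],
    lineage_id = NA_integer_
  )
}

strip_allele <- function(call) {
  sub("\\*.*$", "", sub(",.*$", "", call))
}

#' Cluster clonotypes into clonal lineages
#'
#' Clonotypes sharing the same V gene (allele stripped), J gene and junction
#' length are candidates for a common lineage; within each candidate group,
#' single-linkage clustering on the normalized Hamming distance between
#' junctions merges clonotypes at distance `<= junction_distance_threshold`.
#' Lineage ids are dense integers assigned in order of first member
#' appearance.
#'
#' @param clonotypes tibble from [assign_clonotypes()].
#' @param junction_distance_threshold normalized Hamming distance cut
#'   (default 0.15, the conventional heavy-chain junction cut-off).
#' @return the input tibble with `lineage_id` filled in.
#' @export
cluster_lineages <- function(clonotypes, junction_distance_threshold = 0.15) {
  if (!is.numeric(junction_distance_threshold) ||
      length(junction_distance_threshold) != 1L ||
      junction_distance_threshold < 0 || junction_distance_threshold > 1) {
    stop_bcd("`junction_distance_threshold` must be in [0, 1]", "bcelldyn_parameter_error")
  }
  n <- NROW(clonotypes)
  if (n == 0L) return(clonotypes)
  if (anyNA(clonotypes$junction) || any(!nzchar(clonotypes$junction))) {
    stop_bcd("junctions must be non-empty for lineage clustering", "bcelldyn_validation_error")
  }
  grp_key <- paste(strip_allele(clonotypes$v_call), strip_allele(clonotypes$j_call),
                   nchar(clonotypes$junction), sep = "\r")
  grp <- match(grp_key, unique(grp_key))
  labels <- numeric(n)
  for (idx in split(seq_len(n), grp)) {
    sub_lab <- cpp_cluster_junctions(clonotypes$junction[idx], junction_distance_threshold)
    labels[idx] <- grp[idx[1]] * 1e6 + sub_lab
  }
  first_seen <- labels[!duplicated(labels)]
  clonotypes$lineage_id <- match(labels, first_seen)
  clonotypes
}

#' Compute all per-sample repertoire metrics
#'
#' Runs the full per-sample pipeline — UMI-support filter, clonotype
#' assignment, lineage clustering — and evaluates the four repertoire
#' indices. A sample with no record surviving the UMI filter yields a row
#' with `defined = FALSE` and missing metrics; downstream endpoint calling
#' treats such samples like failed amplifications.
#'
#' @param records rearrangement data frame for one (patient, visit).
#' @param min_umis UMI-support threshold (default 3).
#' @param junction_distance_threshold lineage clustering cut (default 0.15).
#' @param v_region_end IGHV region end in the gapped frame (default 312).
#' @param max_mutations unmutated-clonotype cut (default 0 mismatches).
#' @param lineages if `FALSE`, skip lineage clustering and report `shannon`
#'   and `n_lineages` as missing (useful when only mutation-based metrics
#'   are needed).
#' @return one-row tibble of sample metrics.
#' @export
compute_sample_metrics <- function(records, min_umis = 3L,
                                   junction_distance_threshold = 0.15,
                                   v_region_end = 312L, max_mutations = 0L,
                                   lineages = TRUE) {
  patient_id <- if (NROW(records)) records$patient_id[1] else NA_character_
  visit_month <- if (NROW(records)) records$visit_month[1] else NA_integer_
  kept <- filter_by_umi_support(records, min_umis)
  if (NROW(kept) == 0L) {
    return(tibble::tibble(
      patient_id = patient_id, visit_month = visit_month,
      n_records = NROW(records), n_clonotypes = 0L, n_lineages = NA_integer_,
      total_umis = 0L, gini = NA_real_, shannon = NA_real_,
      mean_mutation_freq = NA_real_, pct_unmutated = NA_real_,
      defined = FALSE, reason = "no records with sufficient UMI support"
    ))
  }
  cl <- assign_clonotypes(kept, v_region_end = v_region_end)
  n_lin <- NA_integer_
  shannon <- NA_real_
  if (lineages) {
    cl <- cluster_lineages(cl, junction_distance_threshold)
    per_lineage <- tabulate(cl$lineage_id)
    n_lin <- length(per_lineage)
    shannon <- shannon_lineage_diversity(per_lineage)
  }
  tibble::tibble(
    patient_id = patient_id, visit_month = visit_month,
    n_records = NROW(records), n_clonotypes = NROW(cl), n_lineages = n_lin,
    total_umis = sum(cl$umi_count),
    gini = gini_expansion(cl$umi_count),
    shannon = shannon,
    mean_mutation_freq = mutation_load(cl),
    pct_unmutated = pct_unmutated(cl, max_mutations),
    defined = TRUE, reason = NA_character_
  )
}

#' Per-sample metrics for a whole cohort
#'
#' Applies [compute_sample_metrics()] to every repertoire in a cohort object
#' (as returned by [assemble_cohort()] or [simulate_cohort()]).
#'
#' @param cohort a `bcr_cohort` object.
#' @param months optional subset of visit months to process.
#' @inheritParams compute_sample_metrics
#' @return tibble with one row per available sample.
#' @export
cohort_metrics <- function(cohort, months = NULL, min_umis = 3L,
                           junction_distance_threshold = 0.15,
                           v_region_end = 312L, max_mutations = 0L,
                           lineages = TRUE) {
  keys <- names(cohort$repertoires)
  rows <- lapply(keys, function(k) {
    rec <- cohort$repertoires[[k]]
    if (!is.null(months) && !(rec$visit_month[1] %in% months)) return(NULL)
    compute_sample_metrics(rec, min_umis, junction_distance_threshold,
                           v_region_end, max_mutations, lineages)
  })
  dplyr::bind_rows(rows)
}
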