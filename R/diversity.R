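#' Gini index of clonal expansion
#'
#' Lorenz-curve inequality coefficient of the distribution of distinct UMIs
#' per clonotype. A perfectly even repertoire scores 0; a repertoire
#' dominated by a few expanded clones approaches 1. With counts sorted
#' ascending \eqn{x_1 \le \dots \le x_n},
#' \deqn{G = \frac{2 \sum_i i\,x_i}{n \sum_i x_i} - \frac{n+1}{n}.}
#' This is the abundance-inequality Gini, not the Gini-Simpson diversity
#' \eqn{1 - \sum p_i^2}; on repertoires of thousands of clonotypes only the
#' former takes mid-range values like those reported for peripheral blood.
#'
#' @param umi_counts positive integer vector, distinct-UMI count per clonotype.
#' @return Gini coefficient in `[0, 1)`.
#' @seealso [shannon_lineage_diversity()]
#' @export
#' @examples
#' gini_expansion(c(5, 5, 5, 5)) # 0: perfect equality
#' gini_expansion(c(1, 1, 1, 97))
gini_expansion <- function(umi_counts) {
  if (length(umi_counts) == 0L) {
    stop_bcd("Gini index is undefined for an empty sample", "bcelldyn_undefined_metric")
  }
  if (anyNA(umi_counts) || any(umi_counts <= 0)) {
    stop_bcd("all UMI counts must be positive", "bcelldyn_validation_error")
  }
  x <- sort(as.numeric(umi_counts))
  n <- length(x)
  (2 * sum(seq_len(n) * x)) / (n * sum(x)) - (n + 1) / n
}

#' Shannon index of lineage diversity
#'
#' Shannon entropy (natural-log units) of the distribution of clonotypes per
#' clonal lineage: \eqn{H = -\sum_i p_i \ln p_i} with
#' \eqn{p_i = n_i / \sum_j n_j}. A repertoire collapsed into a single
#' lineage scores 0; `ln(n)` is attained when all lineages hold equally many
#' clonotypes.
#'
#' @param clonotypes_per_lineage positive integer vector, one entry per lineage.
#' @return entropy in nats, `>= 0`.
#' @export
#' @examples
#' shannon_lineage_diversity(c(1, 1, 1, 1)) # log(4)
shannon_lineage_diversity <- function(clonotypes_per_lineage) {
  if (length(clonotypes_per_lineage) == 0L) {
    stop_bcd("Shannon index requires at least one lineage", "bcelldyn_undefined_metric")
  }
  if (anyNA(clonotypes_per_lineage) || any(clonotypes_per_lineage <= 0)) {
    stop_bcd("all lineage counts must be positive", "bcelldyn_validation_error")
  }
  p <- clonotypes_per_lineage / sum(clonotypes_per_lineage)
  -sum(p * log(p))
}

#' Mean IGHV mutation load
#'
#' Unweighted mean over clonotypes of the per-clonotype somatic
#' hypermutation frequency (IGHV mismatches divided by the number of
#' comparable germline-aligned IGHV positions), in mutations per base pair.
#'
#' @param clonotypes data frame from [assign_clonotypes()].
#' @return mean mutation frequency (mutations/bp).
#' @export
mutation_load <- function(clonotypes) {
  if (NROW(clonotypes) == 0L) {
    stop_bcd("mutation load is undefined for an empty sample", "bcelldyn_undefined_metric")
  }
  mean(clonotypes$mutation_freq)
}

#' Percent unmutated clonotypes
#'
#' Percentage of clonotypes carrying at most `max_mutations` IGHV
#' mismatches. The statistic is clonotype-weighted: every clonotype counts
#' once, irrespective of its UMI abundance, so it tracks the breadth of the
#' unmutated (naive-like) compartment rather than its transcriptional
#' output.
#'
#' @param clonotypes data frame from [assign_clonotypes()].
#' @param max_mutations largest IGHV mismatch count still called unmutated
#'   (default 0, i.e. an exact germline V segment).
#' @return percent in `[0, 100]`.
#' @export
pct_unmutated <- function(clonotypes, max_mutations = 0L) {
  if (NROW(clonotypes) == 0L) {
    stop_bcd("percent unmutated is undefined for an empty sample", "bcelldyn_undefined_metric")
  }
  assert_scalar_number(max_mutations, "max_mutations", lower = 0)
  100 * mean(clonotypes$mutation_count <= max_mutations)
}
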