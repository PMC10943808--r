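# Fixtures and independent oracles shared across the suite.

# A minimal rearrangement table built in code. `v_mut` plants that many
# mismatches at the start of the 30-nt V segment (gapped positions 1..30
# are treated as the V region in these fixtures via v_region_end = 30).
make_records <- function(n = 3, v_mut = rep(0, n), counts = rep(5, n),
                         junction = NULL, v_call = rep("IGHV1-1*01", n),
                         d_call = rep("IGHD1-1*01", n),
                         j_call = rep("IGHJ4*01", n),
                         ids = sprintf("seq%02d", seq_len(n)),
                         patient_id = "P01", visit_month = 0L) {
  germ_v <- strrep("ACGTA", 6) # 30 nt; fixtures use v_region_end = 30
  if (is.null(junction)) junction <- rep(strrep("TGTGCG", 5), n)
  seqs <- vapply(seq_len(n), function(i) {
    ch <- strsplit(germ_v, "")[[1]]
    if (v_mut[i] > 0) {
      pos <- seq_len(v_mut[i])
      ch[pos] <- chartr("ACGT", "CATG", ch[pos])
    }
    paste0(paste(ch, collapse = ""), junction[i])
  }, character(1))
  tibble::tibble(
    sequence_id = ids,
    patient_id = patient_id,
    visit_month = visit_month,
    v_call = v_call, d_call = d_call, j_call = j_call,
    junction = junction,
    sequence_alignment = seqs,
    germline_alignment = paste0(germ_v, junction),
    consensus_count = as.integer(counts),
    productive = TRUE
  )
}

tiny_config <- function(seed = 1, ...) {
  sim_config(seed = seed, clonotypes_per_sample = 400,
             n_lineages_baseline = 200, ...)
}

# Fast config for endpoint/DAS28 studies: repertoire sizes scaled down,
# which leaves percent-unmutated and DAS28 structure unchanged.
desk_config <- function(seed = 1, ...) {
  sim_config(seed = seed, clonotypes_per_sample = 1000,
             n_lineages_baseline = 500, ...)
}

# --- independent oracles -------------------------------------------------

# Gini as mean absolute difference: sum_ij |x_i - x_j| / (2 n^2 mean(x))
gini_mad_oracle <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

# Exhaustive hypergeometric enumeration via choose(), no dhyper.
fisher_oracle <- function(tab, sided) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_
  n <- r1 + r2
  k <- max(0, c1 - r2):min(c1, r1)
  pk <- choose(r1, k) * choose(r2, c1 - k) / choose(n, c1)
  p_obs <- choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  if (sided == "one") {
    if (a * d >= b * c_) sum(pk[k >= a]) else sum(pk[k <= a])
  } else {
    sum(pk[pk <= p_obs * (1 + 1e-7)])
  }
}

# Two-sided exact Mann-Whitney p by full enumeration of group assignments.
mann_whitney_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, u_of)
  p <- if (u_obs > n1 * n2 / 2) 2 * mean(u_all >= u_obs) else 2 * mean(u_all <= u_obs)
  min(1, p)
}

# Lineage partition by transitive closure of <=-threshold junction pairs,
# computed with plain R string handling and igraph components.
lineage_closure_oracle <- function(v_call, j_call, junction, threshold) {
  n <- length(junction)
  strip <- function(x) sub("\\*.*$", "", sub(",.*$", "", x))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) adj[i, i] <- TRUE
  for (i in seq_len(max(0, n - 1))) {
    for (j in seq(i + 1, n)) {
      if (strip(v_call[i]) != strip(v_call[j])) next
      if (strip(j_call[i]) != strip(j_call[j])) next
      if (nchar(junction[i]) != nchar(junction[j])) next
      ci <- strsplit(junction[i], "")[[1]]
      cj <- strsplit(junction[j], "")[[1]]
      if (mean(ci != cj) <= threshold) adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  unname(igraph::components(g)$membership)
}

# Two partitions describe the same clustering (up to label permutation)?
same_partition <- function(p1, p2) {
  identical(match(p1, unique(p1)), match(p2, unique(p2)))
}

write_airr_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write_rearrangements(df, path)
  path
}
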