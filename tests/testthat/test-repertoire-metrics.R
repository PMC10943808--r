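test_that("UMI-support filter keeps exactly the well-supported records", {
  df <- make_records(4, counts = c(1, 2, 3, 5))
  expect_equal(filter_by_umi_support(df)$sequence_id, c("seq03", "seq04"))
  expect_equal(filter_by_umi_support(df, min_umis = 1), df)
  expect_equal(nrow(filter_by_umi_support(df[0, ])), 0)
  expect_error(filter_by_umi_support(df, min_umis = 0), class = "bcelldyn_parameter_error")
})

test_that("clonotype collapse follows the nucleotide-level V-D-J definition", {
  # identical rearrangement, two consensus records: one clonotype, summed UMIs
  df <- make_records(2, counts = c(4, 6))
  cl <- assign_clonotypes(df, v_region_end = 30)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$umi_count, 10L)
  expect_equal(cl$abundance_pct, 100)

  # a single nucleotide difference separates clonotypes
  df2 <- make_records(2, v_mut = c(0, 1), counts = c(5, 15))
  cl2 <- assign_clonotypes(df2, v_region_end = 30)
  expect_equal(nrow(cl2), 2)
  expect_equal(sort(cl2$abundance_pct), c(25, 75))
  expect_equal(sort(cl2$mutation_count), c(0L, 1L))

  # representative = highest consensus count, ties to smallest sequence_id
  df3 <- make_records(3, counts = c(7, 7, 3), ids = c("b", "a", "c"))
  cl3 <- assign_clonotypes(df3, v_region_end = 30)
  expect_equal(cl3$representative_id, "a")
})

test_that("gap positions are excluded from mutation counting", {
  df <- make_records(1)
  # plant a gap pair and one mismatch inside the V region
  substr(df$sequence_alignment, 1, 1) <- "."
  substr(df$germline_alignment, 1, 1) <- "."
  substr(df$sequence_alignment, 5, 5) <- "T" # germline has A at position 5
  cl <- assign_clonotypes(df, v_region_end = 30)
  expect_equal(cl$mutation_count, 1L)
  expect_equal(cl$ighv_aligned_length, 29L) # 30 minus the gapped position

  # no comparable positions at all is a validation error
  df2 <- make_records(1)
  df2$sequence_alignment <- paste0(strrep(".", 30), df2$junction)
  expect_error(assign_clonotypes(df2, v_region_end = 30),
               class = "bcelldyn_validation_error")
})

test_that("Gini matches its closed form and the mean-absolute-difference oracle", {
  expect_equal(gini_expansion(c(5, 5, 5, 5)), 0)
  expect_equal(gini_expansion(c(1, 1, 1, 97)), 0.72)
  expect_error(gini_expansion(integer(0)), class = "bcelldyn_undefined_metric")
  expect_error(gini_expansion(c(3, 0)), class = "bcelldyn_validation_error")

  set.seed(11)
  for (i in 1:200) {
    x <- sample.int(500, sample.int(200, 1), replace = TRUE)
    expect_equal(gini_expansion(x), gini_mad_oracle(x), tolerance = 1e-10)
    # scale invariance
    expect_equal(gini_expansion(x * 7), gini_expansion(x), tolerance = 1e-12)
  }

  # transfer principle: moving UMIs from a poorer to a richer clonotype
  # increases inequality
  x <- c(10, 20, 30, 40)
  expect_gt(gini_expansion(c(5, 20, 30, 45)), gini_expansion(x))
})

test_that("Shannon lineage diversity is the natural-log entropy", {
  expect_equal(shannon_lineage_diversity(10), 0)
  expect_equal(shannon_lineage_diversity(c(1, 1, 1, 1)), log(4))
  expect_equal(shannon_lineage_diversity(c(2, 1, 1)), 1.5 * log(2))
  expect_error(shannon_lineage_diversity(numeric(0)), class = "bcelldyn_undefined_metric")
  expect_error(shannon_lineage_diversity(c(1, 0)), class = "bcelldyn_validation_error")

  set.seed(12)
  for (i in 1:50) {
    x <- sample.int(50, sample.int(30, 1) + 1, replace = TRUE)
    # permutation invariance and agreement with vegan
    expect_equal(shannon_lineage_diversity(sample(x)), shannon_lineage_diversity(x))
    expect_equal(shannon_lineage_diversity(x),
                 unname(vegan::diversity(x, index = "shannon")), tolerance = 1e-12)
    # maximal iff equal counts
    expect_lte(shannon_lineage_diversity(x), log(length(x)) + 1e-12)
  }
  expect_equal(shannon_lineage_diversity(rep(3, 17)), log(17))
})

test_that("mutation load and percent unmutated are clonotype-weighted", {
  cl <- tibble::tibble(mutation_count = c(0L, 0L, 3L, 5L, 7L),
                       ighv_aligned_length = 300L,
                       mutation_freq = c(0, 0, 3, 5, 7) / 300,
                       umi_count = c(100L, 1L, 1L, 1L, 1L))
  expect_equal(pct_unmutated(cl), 40)
  expect_equal(mutation_load(cl), mean(c(0, 0, 3, 5, 7) / 300))
  expect_equal(pct_unmutated(cl[1:2, ]), 100)
  expect_equal(mutation_load(tibble::tibble(mutation_freq = 15 / 300)), 0.05)
  # invariant to UMI counts by design
  cl2 <- cl; cl2$umi_count <- rep(1L, 5)
  expect_equal(pct_unmutated(cl2), pct_unmutated(cl))
  expect_error(mutation_load(cl[0, ]), class = "bcelldyn_undefined_metric")
})

test_that("lineage clustering is single linkage over V/J/junction-length groups", {
  # identical junctions, same V/J: one lineage
  cl <- assign_clonotypes(make_records(3, v_mut = c(0, 1, 2)), v_region_end = 30)
  cl <- cluster_lineages(cl)
  expect_equal(cl$lineage_id, rep(1L, 3))

  # junctions differing everywhere: distinct lineages
  j <- c(strrep("A", 10), strrep("C", 10), strrep("G", 10))
  cl2 <- cluster_lineages(assign_clonotypes(make_records(3, junction = j), v_region_end = 30))
  expect_equal(cl2$lineage_id, 1:3)

  # chain A-B 0.1, B-C 0.1, A-C 0.2 at threshold 0.15: one lineage
  ja <- strrep("A", 10)
  jb <- paste0("C", strrep("A", 9))           # d(A,B) = 0.1
  jc <- paste0("CT", strrep("A", 8))          # d(B,C) = 0.1, d(A,C) = 0.2
  cl3 <- cluster_lineages(assign_clonotypes(make_records(3, junction = c(ja, jb, jc)),
                                            v_region_end = 30))
  expect_equal(cl3$lineage_id, rep(1L, 3))
  expect_equal(cl3$lineage_id,
               lineage_closure_oracle(cl3$v_call, cl3$j_call, cl3$junction, 0.15))

  # alleles of the same V gene cluster together; different genes never do
  cl4 <- cluster_lineages(assign_clonotypes(
    make_records(3, v_mut = c(0, 1, 2),
                 v_call = c("IGHV1-1*01", "IGHV1-1*02", "IGHV3-7*01")),
    v_region_end = 30))
  expect_equal(cl4$lineage_id, c(1L, 1L, 2L))

  expect_error(cluster_lineages(cl, junction_distance_threshold = 1.5),
               class = "bcelldyn_parameter_error")
})

test_that("single-linkage clustering agrees with transitive closure on random instances", {
  skip_if_not_installed("igraph")
  set.seed(21)
  for (i in 1:40) {
    n <- sample.int(30, 1) + 1
    vg <- sample(c("IGHV1-1*01", "IGHV1-1*02", "IGHV2-5*01"), n, replace = TRUE)
    jg <- sample(c("IGHJ4*01", "IGHJ6*01"), n, replace = TRUE)
    len <- sample(c(9, 12), n, replace = TRUE)
    junc <- vapply(len, function(L) paste(sample(c("A", "C"), L, replace = TRUE), collapse = ""),
                   character(1))
    cl <- tibble::tibble(v_call = vg, j_call = jg, junction = junc)
    got <- cluster_lineages(cl, 0.34)
    want <- lineage_closure_oracle(vg, jg, junc, 0.34)
    expect_true(same_partition(got$lineage_id, want))
  }
})

test_that("per-sample metrics compose and flag empty samples as undefined", {
  # 4 equal-abundance unmutated clonotypes in one lineage
  j <- strrep("TGTGCG", 5)
  jv <- c(j, paste0("A", substr(j, 2, 30)), paste0("C", substr(j, 2, 30)),
          paste0("G", substr(j, 2, 30)))
  df <- make_records(4, junction = jv, counts = rep(5, 4))
  m <- compute_sample_metrics(df, v_region_end = 30)
  expect_equal(m$n_clonotypes, 4L)
  expect_equal(m$n_lineages, 1L)
  expect_equal(m$gini, 0)
  expect_equal(m$shannon, 0)
  expect_equal(m$mean_mutation_freq, 0)
  expect_equal(m$pct_unmutated, 100)
  expect_true(m$defined)

  # nothing survives the UMI filter: undefined metrics with a reason
  df2 <- make_records(3, counts = c(1, 2, 2))
  m2 <- compute_sample_metrics(df2, v_region_end = 30)
  expect_false(m2$defined)
  expect_true(is.na(m2$pct_unmutated))
  expect_match(m2$reason, "UMI")
})
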