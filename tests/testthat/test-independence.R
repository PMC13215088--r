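test_that("gap_distance handles disjoint, overlapping, touching and cross-chromosome pairs", {
  expect_equal(gap_distance("chr1", 100, 200, "chr1", 300, 400), 100)
  expect_equal(gap_distance("chr1", 100, 300, "chr1", 200, 400), 0)
  expect_equal(gap_distance("chr1", 100, 200, "chr1", 200, 300), 0)
  expect_true(is.na(gap_distance("chr1", 100, 200, "chr2", 300, 400)))
  # symmetry
  expect_equal(gap_distance("chr1", 5, 9, "chr1", 20, 31),
               gap_distance("chr1", 20, 31, "chr1", 5, 9))
})

test_that("gap_distance agrees with base-enumeration oracle on random pairs", {
  withr::local_seed(41)
  for (i in 1:300) {
    s1 <- sample(0:300, 1); e1 <- s1 + sample(1:80, 1)
    s2 <- sample(0:300, 1); e2 <- s2 + sample(1:80, 1)
    expect_equal(gap_distance("c", s1, e1, "c", s2, e2),
                 oracle_gap(s1, e1, s2, e2))
  }
})

test_that("find_neighbor_pairs keeps exactly the in-window same-chromosome hervRNA-gene pairs", {
  loci <- tibble::tibble(
    feature_id = c("h1", "g_near", "g_far", "g_other"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(0, 1000900, 2500000, 1000900),
    end = c(1000, 1001000, 2501000, 1001000),
    score = 0, strand = "+",
    feature_class = c("hervRNA", rep("coding_gene", 3)))
  pairs <- find_neighbor_pairs(loci, filter_config())
  expect_equal(pairs$gene_id, "g_near")
  expect_equal(pairs$gap_bp, 999900)

  # hervRNA-hervRNA pairs never emitted
  loci2 <- loci
  loci2$feature_class <- c("hervRNA", "hervRNA", "hervRNA", "hervRNA")
  expect_equal(nrow(find_neighbor_pairs(loci2, filter_config())), 0)
})

test_that("find_neighbor_pairs equals the all-pairs oracle on random layouts", {
  withr::local_seed(42)
  cfg <- filter_config(window_bp = 1e6)
  for (i in 1:25) {
    loci <- random_loci(if (i == 1) 50 else sample(6:20, 1))
    got <- find_neighbor_pairs(loci, cfg)
    want <- oracle_neighbor_pairs(loci, cfg$window_bp)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("paired signed-rank test matches hand-enumerated and degenerate cases", {
  y <- c(3, 5, 1, 8, 2)
  res <- paired_wilcoxon_greater(y + 1, y)
  expect_equal(res$p_value, 1 / 32)
  expect_false(res$degenerate)

  tie <- paired_wilcoxon_greater(c(2, 2, 2, 2, 2), c(2, 2, 2, 2, 2))
  expect_equal(tie$p_value, 1)
  expect_true(tie$degenerate)

  # uniformly lower x gives no evidence for "greater"
  low <- paired_wilcoxon_greater(y - 1, y)
  expect_equal(low$p_value, 1)
})

test_that("exact signed-rank p agrees with full sign enumeration (with ties and zeros)", {
  withr::local_seed(43)
  for (i in 1:200) {
    n <- sample(5:12, 1)
    x <- sample(0:6, n, replace = TRUE)
    y <- sample(0:6, n, replace = TRUE)
    if (all(x == y)) x[1] <- y[1] + 1
    expect_equal(paired_wilcoxon_greater(x, y)$p_value,
                 oracle_signed_rank_p(x, y), tolerance = 1e-9)
  }
})

test_that("exact signed-rank p matches wilcox.test when ties and zeros are absent", {
  withr::local_seed(44)
  for (i in 1:25) {
    n <- sample(6:15, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(paired_wilcoxon_greater(x, y)$p_value,
                 wilcox.test(x, y, paired = TRUE, alternative = "greater",
                             exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("normal approximation is close to the exact tail above the cutover", {
  withr::local_seed(45)
  x <- rnorm(30); y <- x - 0.4 + rnorm(30, sd = 0.5)
  approx <- paired_wilcoxon_greater(x, y)$p_value
  exact <- paired_wilcoxon_greater(x, y, exact_max_n = 40)$p_value
  expect_equal(approx, exact, tolerance = 0.01)
})

test_that("driver rule needs both co-expression above 0.4 and higher gene expression", {
  withr::local_seed(46)
  n <- 30
  base <- rnorm(n)
  mk <- function(target_r) base * target_r + rnorm(n) * sqrt(1 - target_r^2)
  herv <- 2 + base            # sd 1, mean 2
  build <- function(gene_vals) {
    tpm <- rbind(h1 = pmax(herv, 0.01), gA = pmax(gene_vals, 0.01))
    colnames(tpm) <- sprintf("s%02d", 1:n)
    herv_expr(tpm, c("hervRNA", "coding_gene"))
  }
  pairs <- tibble::tibble(herv_id = "h1", gene_id = "gA", gap_bp = 100)

  # strongly correlated, higher gene -> driven
  da <- assign_drivers(build(20 + 10 * mk(0.9)), pairs)
  expect_equal(da$status[da$herv_id == "h1"], "driven")
  expect_equal(da$driver_gene_id[1], "gA")

  # r below 0.4 -> independent even with tiny wilcoxon p
  weak <- assign_drivers(build(20 + 10 * mk(0.05)), pairs)
  expect_equal(weak$status[1], "independent")

  # r = 0.9 but gene uniformly lower -> independent
  lower <- assign_drivers(build(herv - 1), pairs)
  expect_equal(lower$status[1], "independent")

  # constant gene vector: r undefined, cannot qualify
  flat <- assign_drivers(build(rep(10, n)), pairs)
  expect_equal(flat$status[1], "independent")
})

test_that("r threshold is strict: r just above 0.4 drives, at/below does not", {
  # constructed pair with known sample correlation via orthogonal residual
  withr::local_seed(47)
  n <- 20
  b <- scale(rnorm(n))[, 1]
  e <- stats::resid(lm(rnorm(n) ~ b)); e <- e / sqrt(sum(e^2) / (n - 1))
  mk_expr <- function(r) {
    g <- 50 + 5 * (r * b + sqrt(1 - r^2) * e)
    tpm <- rbind(h1 = 5 + b, gA = g)
    colnames(tpm) <- sprintf("s%02d", 1:n)
    herv_expr(tpm, c("hervRNA", "coding_gene"))
  }
  pairs <- tibble::tibble(herv_id = "h1", gene_id = "gA", gap_bp = 1)
  expect_equal(assign_drivers(mk_expr(0.41), pairs)$status, "driven")
  expect_equal(assign_drivers(mk_expr(0.39), pairs)$status, "independent")
  # strictness at the boundary: a pair whose r equals the threshold
  # exactly never qualifies
  ex <- mk_expr(0.6)
  r_obs <- assign_drivers(ex, pairs)$r
  expect_equal(assign_drivers(ex, pairs,
                              filter_config(r_threshold = r_obs))$status,
               "independent")
  expect_equal(assign_drivers(ex, pairs,
                              filter_config(r_threshold = r_obs - 1e-9))$status,
               "driven")
})

test_that("every hervRNA is exactly one of driven or independent", {
  withr::local_seed(48)
  cfg <- sim_config(seed = 48, n_per_subgroup = 8, n_hervs = 120,
                    n_genes = 60, n_marker_clusters = 1,
                    markers_per_cluster = 1)
  co <- simulate_cohort(cfg, methylation = FALSE)
  drv <- filter_independent(co$expr, co$loci)
  hervs <- names(co$expr$feature_class)[co$expr$feature_class == "hervRNA"]
  expect_setequal(drv$herv_id, hervs)
  expect_true(all(drv$status %in% c("driven", "independent")))
  expect_equal(anyDuplicated(drv$herv_id), 0L)
})

test_that("shrinking the window or raising the r threshold never creates drivers", {
  withr::local_seed(49)
  cfg <- sim_config(seed = 49, n_per_subgroup = 8, n_hervs = 150,
                    n_genes = 80, n_marker_clusters = 1,
                    markers_per_cluster = 1)
  co <- simulate_cohort(cfg, methylation = FALSE)
  base <- filter_independent(co$expr, co$loci, filter_config())
  narrow <- filter_independent(co$expr, co$loci,
                               filter_config(window_bp = 3e5))
  strict <- filter_independent(co$expr, co$loci,
                               filter_config(r_threshold = 0.7))
  driven_of <- function(d) d$herv_id[d$status == "driven"]
  expect_true(all(driven_of(narrow) %in% driven_of(base)))
  expect_true(all(driven_of(strict) %in% driven_of(base)))
})
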