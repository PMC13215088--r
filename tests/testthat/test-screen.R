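test_that("binarize uses a strict threshold and is idempotent", {
  m <- matrix(c(1.0, 1.0001, 0.2, 7), 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  b <- binarize(m, 1)
  expect_identical(as.vector(b), c(0L, 1L, 0L, 1L))
  expect_identical(binarize(binarize(m, 1), 0.5), binarize(m, 1))
})

test_that("fisher_exact_2x2 reproduces enumerated and degenerate tables", {
  # support a in 0..3, probabilities {1, 9, 9, 1}/20 -> two-sided p = 0.1
  expect_equal(fisher_exact_2x2(matrix(c(3, 0, 0, 3), 2)), 0.1)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  # zero margin carries no information
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 4, 6), 2, byrow = TRUE)), 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 0, 0, 3), 2)), "non-negative")
})

test_that("fisher_exact_2x2 matches stats::fisher.test on random tables", {
  withr::local_seed(50)
  for (i in 1:500) {
    n <- sample(4:40, 1)
    cells <- as.vector(stats::rmultinom(1, n, prob = runif(4, 0.05, 1)))
    tab <- matrix(cells, 2)
    if (sum(tab[1, ]) == 0 || sum(tab[2, ]) == 0 ||
        sum(tab[, 1]) == 0 || sum(tab[, 2]) == 0) next
    expect_equal(fisher_exact_2x2(tab), stats::fisher.test(tab)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("bh_adjust reproduces the step-up formula and matches p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.007), 0.007)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  withr::local_seed(51)
  for (i in 1:200) {
    p <- runif(sample(1:30, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"), tolerance = 1e-12)
  }
  # permutation equivariance
  p <- runif(12)
  perm <- sample(12)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
})

test_that("score_candidate computes specificity, fold change and the four gates", {
  fix <- planted_marker_expr(n_per = 10, on_tpm = 12, off_tpm = 0.2)
  sc <- score_candidate(fix$expr, fix$labels, "mk_Group3", "Group3")
  expect_equal(sc$specificity, 1)
  expect_equal(sc$mean_tpm_target, 12)
  expect_equal(sc$mean_tpm_others_max, 0.2)
  expect_equal(sc$log2fc_mean_tpm, log2(12.01 / 0.21))
  expect_true(sc$passed)

  # expressed in 6 of 30 non-target samples -> specificity exactly 0.8,
  # which fails the strict > 0.8 gate
  tpm <- fix$expr$tpm
  off <- which(fix$labels$subgroup != "Group3")
  tpm["mk_Group3", off[1:6]] <- 1.5
  expr2 <- herv_expr(tpm, unname(fix$expr$feature_class))
  sc2 <- score_candidate(expr2, fix$labels, "mk_Group3", "Group3")
  expect_equal(sc2$specificity, 0.8)
  expect_false(sc2$crit_spec)
  expect_false(sc2$passed)
})

test_that("mean-TPM rule can gate on each subgroup or on the pooled rest", {
  fix <- planted_marker_expr(n_per = 6)
  tpm <- fix$expr$tpm
  # high in Group3 (target) and moderately high in WNT only
  tpm["mk_Group3", fix$labels$subgroup == "WNT"] <- 8
  expr <- herv_expr(tpm, unname(fix$expr$feature_class))
  each <- score_candidate(expr, fix$labels, "mk_Group3", "Group3",
                          screen_config(others_rule = "each"))
  pooled <- score_candidate(expr, fix$labels, "mk_Group3", "Group3",
                            screen_config(others_rule = "pooled"))
  expect_false(each$crit_mean)    # WNT mean 8 >= 5
  expect_true(pooled$crit_mean)   # pooled others mean (8 + .2 + .2)/3 < 5
})

test_that("run_screen agrees with per-candidate scoring and recovers planted markers", {
  fix <- planted_marker_expr(n_per = 8)
  res <- run_screen(fix$expr, fix$labels, keep_all = TRUE)
  expect_equal(nrow(res), 4 * 4)  # every (herv, subgroup) hypothesis
  passed <- res[res$passed, ]
  expect_setequal(passed$herv_id, rownames(fix$expr$tpm))
  expect_equal(passed$target_subgroup, sub("mk_", "", passed$herv_id))
  # BH is joint: adjusted p of each passing candidate uses all 16 tests
  one <- res[res$herv_id == "mk_WNT" & res$target_subgroup == "WNT", ]
  expect_equal(one$fisher_p_adj, bh_adjust(res$fisher_p)[
    which(res$herv_id == "mk_WNT" & res$target_subgroup == "WNT")])
  sc <- score_candidate(fix$expr, fix$labels, "mk_WNT", "WNT",
                        fisher_p_adj = one$fisher_p_adj)
  expect_equal(one$fisher_p, sc$fisher_p)
  expect_equal(one$specificity, sc$specificity)
  expect_equal(one$log2fc_mean_tpm, sc$log2fc_mean_tpm)
  expect_equal(one$passed, sc$passed)
})

test_that("screen statistics are invariant to sample order", {
  withr::local_seed(52)
  fix <- planted_marker_expr(n_per = 6)
  perm <- sample(ncol(fix$expr$tpm))
  expr_p <- herv_expr(fix$expr$tpm[, perm], unname(fix$expr$feature_class))
  a <- run_screen(fix$expr, fix$labels, keep_all = TRUE)
  b <- run_screen(expr_p, fix$labels, keep_all = TRUE)
  expect_equal(a, b)
})

test_that("tightening any screen threshold never grows the passing set", {
  withr::local_seed(53)
  cfg <- sim_config(seed = 53, n_per_subgroup = 8, n_hervs = 300,
                    n_genes = 100, n_marker_clusters = 3)
  co <- simulate_cohort(cfg, methylation = FALSE)
  base <- run_screen(co$expr, co$labels, screen_config())
  tighter <- list(
    screen_config(adj_p_max = 0.001),
    screen_config(mean_tpm_on = 8),
    screen_config(log2fc_min = 4),
    screen_config(specificity_min = 0.95),
    screen_config(threshold_tpm = 3))
  key <- function(d) paste(d$herv_id, d$target_subgroup)
  for (cf in tighter) {
    sub <- suppressWarnings(run_screen(co$expr, co$labels, cf))
    expect_true(all(key(sub) %in% key(base)))
  }
  # restricting to a subset never adds candidates
  some <- sample(unique(base$herv_id), ceiling(nrow(base) / 2))
  restr <- suppressWarnings(
    run_screen(co$expr, co$labels, screen_config(), restrict_to = some))
  expect_true(all(key(restr) %in% key(base)))
})

test_that("label permutation almost never yields passing classifiers", {
  withr::local_seed(54)
  cfg <- sim_config(seed = 54, n_per_subgroup = 10, n_hervs = 400,
                    n_genes = 100, n_marker_clusters = 3)
  co <- simulate_cohort(cfg, methylation = FALSE)
  n_pass <- replicate(30, {
    lab <- co$labels
    lab$subgroup <- sample(lab$subgroup)
    nrow(suppressWarnings(run_screen(co$expr, lab, screen_config())))
  })
  expect_gte(mean(n_pass == 0), 0.95)
})
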