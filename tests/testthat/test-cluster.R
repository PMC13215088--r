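cand_tbl <- function(start, end, chrom = "chr1", subgroup = "Group3") {
  tibble::tibble(herv_id = sprintf("h%02d", seq_along(start)),
                 target_subgroup = subgroup, chrom = chrom,
                 start = start, end = end)
}

test_that("single-linkage chaining merges through consecutive gaps", {
  # gaps of 150 kbp both sides: one cluster even though the end-to-end
  # span exceeds 200 kbp
  cand <- cand_tbl(start = c(0, 151e3, 302e3),
                   end = c(1e3, 152e3, 303e3))
  cl <- cluster_by_distance(cand, 2e5)
  expect_equal(dplyr::n_distinct(cl$cluster_id), 1)
  expect_equal(unique(cl$cluster_start), 0)
  expect_equal(unique(cl$cluster_end), 303e3)

  # a gap above the threshold splits
  cand2 <- cand_tbl(start = c(0, 250e3), end = c(1e3, 251e3))
  expect_equal(dplyr::n_distinct(cluster_by_distance(cand2, 2e5)$cluster_id), 2)

  # complete linkage refuses the chain when far members exceed the bound
  cl_complete <- cluster_by_distance(cand, 2e5, linkage = "complete")
  expect_equal(dplyr::n_distinct(cl_complete$cluster_id), 2)
})

test_that("clusters never span chromosomes or subgroups", {
  cand <- dplyr::bind_rows(
    cand_tbl(c(0, 10e3), c(1e3, 11e3), chrom = "chr1"),
    cand_tbl(c(0, 10e3), c(1e3, 11e3), chrom = "chr2"))
  cand$herv_id <- sprintf("h%02d", 1:4)
  cl <- cluster_by_distance(cand, 2e5)
  expect_equal(dplyr::n_distinct(cl$cluster_id), 2)

  cand$chrom <- "chr1"
  cand$target_subgroup <- c("WNT", "WNT", "SHH", "SHH")
  cl2 <- cluster_by_distance(cand, 2e5)
  expect_equal(
    nrow(dplyr::distinct(cl2, cluster_id, target_subgroup)),
    dplyr::n_distinct(cl2$cluster_id))
  expect_equal(dplyr::n_distinct(cl2$cluster_id), 2)
})

test_that("clustering equals the transitive closure of the pairwise relation", {
  withr::local_seed(60)
  for (i in 1:60) {
    n <- sample(3:16, 1)
    start <- sort(sample(0:2e6, n))
    cand <- tibble::tibble(
      herv_id = sprintf("h%02d", seq_len(n)),
      target_subgroup = sample(c("A", "B"), n, replace = TRUE),
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      start = start, end = start + sample(100:5e4, n, replace = TRUE))
    gap <- sample(c(5e4, 2e5, 5e5), 1)
    got <- cluster_by_distance(cand, gap)
    expect_equal(partition_sets(got$herv_id, got$cluster_id),
                 unname(sort(vapply(oracle_cluster_partition(cand, gap),
                                    function(v) paste(sort(v), collapse = "|"),
                                    character(1)))))
  }
})

test_that("clustering is a partition invariant to input order, and larger gaps only merge", {
  withr::local_seed(61)
  start <- sort(sample(0:3e6, 12))
  cand <- cand_tbl(start, start + 2e3)
  cl <- cluster_by_distance(cand, 2e5)
  expect_setequal(cl$herv_id, cand$herv_id)
  expect_equal(anyDuplicated(cl$herv_id), 0L)
  shuffled <- cluster_by_distance(cand[sample(nrow(cand)), ], 2e5)
  expect_equal(dplyr::arrange(cl, herv_id), dplyr::arrange(shuffled, herv_id))

  small <- cluster_by_distance(cand, 1e5)
  big <- cluster_by_distance(cand, 5e5)
  # every small cluster is contained in one big cluster
  map <- dplyr::inner_join(small, big, by = "herv_id",
                           suffix = c("_s", "_b"))
  expect_true(all(tapply(map$cluster_id_b, map$cluster_id_s,
                         function(v) length(unique(v))) == 1))
})

test_that("panel JSON round-trips members, spans and config", {
  cand <- cand_tbl(c(0, 50e3, 900e3), c(1e3, 51e3, 901e3))
  panel <- build_panel(cand, 2e5, cohort_id = "fixture")
  dir <- withr::local_tempdir()
  p <- file.path(dir, "panel.json")
  write_panel_json(panel, p)
  back <- read_panel_json(p)
  expect_equal(back$cluster_gap_bp, 2e5)
  expect_equal(back$cohort_id, "fixture")
  expect_equal(
    dplyr::arrange(back$clusters[, c("cluster_id", "herv_id")], herv_id),
    dplyr::arrange(panel$clusters[, c("cluster_id", "herv_id")], herv_id))
})

test_that("cluster positivity is any-member-expressed and monotone", {
  cand <- cand_tbl(c(0, 50e3, 100e3), c(1e3, 51e3, 101e3))
  panel <- build_panel(cand)
  bin <- matrix(0L, 3, 2, dimnames = list(cand$herv_id, c("s1", "s2")))
  bin["h02", "s1"] <- 1L
  pos <- cluster_positivity(bin, panel)
  expect_true(pos["s1", 1])
  expect_false(pos["s2", 1])
  # flipping any member 0 -> 1 never turns a cluster off
  bin2 <- bin; bin2["h03", "s1"] <- 1L; bin2["h01", "s2"] <- 1L
  pos2 <- cluster_positivity(bin2, panel)
  expect_true(all(pos2 >= pos))
  # absent member tolerated with a warning
  expect_warning(cluster_positivity(bin[1:2, , drop = FALSE], panel),
                 "absent")
})

test_that("classification votes by highest cluster expression rate with honest ties", {
  members <- dplyr::bind_rows(
    cand_tbl(c(0, 1e6, 2e6, 3e6), c(1e3, 1e6 + 1e3, 2e6 + 1e3, 3e6 + 1e3),
             subgroup = "Group3"),
    cand_tbl(c(0, 1e6), c(1e3, 1e6 + 1e3), chrom = "chr2", subgroup = "WNT"))
  members$herv_id <- sprintf("h%02d", 1:6)
  panel <- build_panel(members, 2e5)
  bin <- matrix(0L, 6, 3, dimnames = list(members$herv_id,
                                          c("g3", "none", "tie")))
  bin[c("h01", "h02", "h03"), "g3"] <- 1L   # 3/4 Group3, 0/2 WNT
  bin[c("h01", "h02", "h05"), "tie"] <- 1L  # 2/4 Group3, 1/2 WNT: rate tie
  calls <- classify_samples(bin, panel)
  expect_equal(calls$call[calls$sample_id == "g3"], "Group3")
  expect_equal(calls$rate_Group3[calls$sample_id == "g3"], 0.75)
  expect_equal(calls$call[calls$sample_id == "none"], "unclassified")
  # 0.5 vs 0.5 rate tie broken by absolute positive count (2 > 1)
  expect_equal(calls$call[calls$sample_id == "tie"], "Group3")
  expect_true(calls$tie[calls$sample_id == "tie"])
  expect_error(classify_samples(bin, structure(list(clusters = members[0, ]),
                                               class = "herv_panel")),
               "empty panel")
})

test_that("evaluation counts unclassified as wrong and tabulates confusion", {
  labels <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                           subgroup = c("WNT", "WNT", "SHH", "SHH",
                                        "Group3", "Group4"))
  calls <- tibble::tibble(
    sample_id = labels$sample_id,
    call = c("WNT", "WNT", "SHH", "SHH", "Group4", "Group4"),
    tie = FALSE)
  ev <- evaluate_calls(calls, labels)
  expect_equal(ev$accuracy, 5 / 6)
  expect_equal(ev$confusion["Group3", "Group4"], c(Group3 = 1),
               ignore_attr = TRUE)

  all_un <- calls; all_un$call <- "unclassified"
  expect_equal(evaluate_calls(all_un, labels)$accuracy, 0)
})

test_that("leave-one-out is deterministic, leak-free and accurate on planted cohorts", {
  cfg <- sim_config(seed = 62, n_per_subgroup = 10, n_hervs = 200,
                    n_genes = 80, n_marker_clusters = 4)
  co <- simulate_cohort(cfg, methylation = FALSE)
  cv1 <- crossvalidate(co$expr, co$loci, co$labels)
  cv2 <- crossvalidate(co$expr, co$loci, co$labels)
  expect_identical(cv1$calls, cv2$calls)
  expect_gte(cv1$accuracy, 0.9)
  expect_equal(cv1$n_excluded, 0)
  lab1 <- co$labels
  lab1$subgroup[which(lab1$subgroup == "WNT")[1:9]] <- "SHH"
  expect_error(crossvalidate(co$expr, co$loci, lab1), ">= 2 samples")
})
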