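#' Group classifier hervRNAs into genomic clusters
#'
#' Classifiers of the same target subgroup on the same chromosome are
#' chained into clusters whenever the interval gap between an element and
#' the elements already in the cluster is at most `cluster_gap_bp`
#' (single linkage: sorted by start, an element opens a new cluster when
#' its gap to the running maximum end exceeds the threshold). This equals
#' the connected components of the pairwise gap-at-most relation. Clusters
#' never span chromosomes or target subgroups.
#'
#' @param candidates tibble with at least `herv_id`, `target_subgroup`,
#'   `chrom`, `start`, `end` (e.g. [run_screen()] output joined with loci).
#' @param cluster_gap_bp maximum gap in bp between chained elements
#'   (default 200000, the published rule).
#' @param linkage `"single"` (default, adjacent-gap chaining) or
#'   `"complete"` (every pair within a cluster must satisfy the gap bound;
#'   greedy left-to-right variant).
#' @return tibble with one row per member: `cluster_id`, `target_subgroup`,
#'   `herv_id`, `chrom`, `start`, `end`, plus per-cluster `cluster_start`,
#'   `cluster_end`. Cluster ids are deterministic, ordered by
#'   (subgroup, chrom, start).
#' @export
cluster_by_distance <- function(candidates, cluster_gap_bp = 2e5,
                                linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  needed <- c("herv_id", "target_subgroup", "chrom", "start", "end")
  miss <- setdiff(needed, names(candidates))
  if (length(miss) > 0) {
    stop("candidates lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cand <- dplyr::arrange(candidates, .data$target_subgroup, .data$chrom,
                         .data$start, .data$end, .data$herv_id)
  cand <- dplyr::group_by(cand, .data$target_subgroup, .data$chrom)
  cand <- dplyr::mutate(cand, .cl = chain_clusters(.data$start, .data$end,
                                                   cluster_gap_bp, linkage))
  cand <- dplyr::ungroup(cand)
  cand <- dplyr::group_by(cand, .data$target_subgroup, .data$chrom, .data$.cl)
  cand <- dplyr::mutate(cand, cluster_start = min(.data$start),
                        cluster_end = max(.data$end))
  cand <- dplyr::ungroup(cand)
  key <- dplyr::distinct(cand, .data$target_subgroup, .data$chrom, .data$.cl,
                         .data$cluster_start)
  key <- dplyr::arrange(key, .data$target_subgroup, .data$chrom,
                        .data$cluster_start, .data$.cl)
  key$cluster_id <- sprintf("%s_c%03d", key$target_subgroup,
                            stats::ave(rep(1, nrow(key)), key$target_subgroup,
                                       FUN = cumsum))
  out <- dplyr::left_join(cand, key,
                          by = c("target_subgroup", "chrom", ".cl",
                                 "cluster_start"))
  dplyr::select(out, "cluster_id", "target_subgroup", "herv_id", "chrom",
                "start", "end", "cluster_start", "cluster_end")
}

# cluster index per element within one (subgroup, chrom) block,
# inputs sorted by start
chain_clusters <- function(start, end, gap_bp, linkage) {
  n <- length(start)
  if (n == 0) return(integer(0))
  cl <- integer(n)
  cl[1] <- 1L
  if (n == 1) return(cl)
  if (linkage == "single") {
    run_max_end <- end[1]
    for (i in 2:n) {
      gap <- max(0, start[i] - run_max_end)
      if (gap > gap_bp) {
        cl[i] <- cl[i - 1] + 1L
        run_max_end <- end[i]
      } else {
        cl[i] <- cl[i - 1]
        run_max_end <- max(run_max_end, end[i])
      }
    }
  } else {
    # complete linkage, greedy: the new element must be within gap_bp of
    # every current member, i.e. of the member with the smallest end
    min_end <- end[1]
    for (i in 2:n) {
      gap <- max(0, start[i] - min_end)
      if (gap > gap_bp) {
        cl[i] <- cl[i - 1] + 1L
        min_end <- end[i]
      } else {
        cl[i] <- cl[i - 1]
        min_end <- min(min_end, end[i])
      }
    }
  }
  cl
}

#' Build a classifier panel from screened candidates
#'
#' Bundles [cluster_by_distance()] output with its configuration into a
#' serializable panel object used by [classify_samples()].
#'
#' @param candidates passing candidates carrying coordinates (from
#'   [run_screen()] with `loci` supplied).
#' @param cluster_gap_bp,linkage see [cluster_by_distance()].
#' @param cohort_id free-text provenance label.
#' @return an object of class `herv_panel`: list with `clusters` (member
#'   tibble), `subgroups`, `cluster_gap_bp`, `linkage`, `cohort_id`,
#'   `version`.
#' @export
build_panel <- function(candidates, cluster_gap_bp = 2e5,
                        linkage = "single", cohort_id = "unspecified") {
  if (nrow(candidates) == 0) stop("no candidates to build a panel from",
                                  call. = FALSE)
  members <- cluster_by_distance(candidates, cluster_gap_bp, linkage)
  structure(list(clusters = members,
                 subgroups = sort(unique(members$target_subgroup)),
                 cluster_gap_bp = cluster_gap_bp, linkage = linkage,
                 cohort_id = cohort_id, version = "1"),
            class = "herv_panel")
}

#' @export
print.herv_panel <- function(x, ...) {
  per <- table(dplyr::distinct(x$clusters, .data$cluster_id,
                               .data$target_subgroup)$target_subgroup)
  cat("<herv_panel> ", dplyr::n_distinct(x$clusters$cluster_id),
      " clusters / ", nrow(x$clusters), " classifier hervRNAs\n", sep = "")
  cat("  clusters per subgroup: ",
      paste(names(per), per, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Serialize / deserialize a classifier panel as JSON
#'
#' @param panel a [build_panel()] object.
#' @param path output path.
#' @return `write_panel_json()` returns `path` invisibly;
#'   `read_panel_json()` returns the `herv_panel`.
#' @export
write_panel_json <- function(panel, path) {
  clusters <- panel$clusters |>
    dplyr::group_by(.data$cluster_id, .data$target_subgroup, .data$chrom,
                    .data$cluster_start, .data$cluster_end) |>
    dplyr::summarise(members = list(.data$herv_id), .groups = "drop") |>
    dplyr::arrange(.data$cluster_id)
  obj <- list(
    version = panel$version,
    config = list(cluster_gap_bp = panel$cluster_gap_bp,
                  linkage = panel$linkage, cohort_id = panel$cohort_id),
    clusters = purrr::pmap(clusters, function(cluster_id, target_subgroup,
                                              chrom, cluster_start,
                                              cluster_end, members) {
      list(id = cluster_id, subgroup = target_subgroup, chrom = chrom,
           start = cluster_start, end = cluster_end, members = members)
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_panel_json
#' @export
read_panel_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  members <- purrr::map_dfr(obj$clusters, function(cl) {
    tibble::tibble(cluster_id = cl$id, target_subgroup = cl$subgroup,
                   herv_id = unlist(cl$members), chrom = cl$chrom,
                   start = NA_real_, end = NA_real_,
                   cluster_start = cl$start, cluster_end = cl$end)
  })
  structure(list(clusters = members,
                 subgroups = sort(unique(members$target_subgroup)),
                 cluster_gap_bp = obj$config$cluster_gap_bp,
                 linkage = obj$config$linkage,
                 cohort_id = obj$config$cohort_id,
                 version = obj$version),
            class = "herv_panel")
}

#' Per-sample cluster positivity
#'
#' A cluster is positive in a sample when at least one of its member
#' hervRNAs is expressed (binary value 1). Members absent from the binary
#' matrix are tolerated with a warning and treated as unexpressed.
#'
#' @param binary a [binarize()] matrix (features x samples).
#' @param panel a `herv_panel`.
#' @return logical matrix, samples x clusters.
#' @export
cluster_positivity <- function(binary, panel) {
  members <- panel$clusters
  absent <- setdiff(members$herv_id, rownames(binary))
  if (length(absent) > 0) {
    warning(length(absent), " panel member(s) absent from expression; ",
            "treated as unexpressed")
    members <- members[!members$herv_id %in% absent, , drop = FALSE]
  }
  ids <- sort(unique(panel$clusters$cluster_id))
  out <- matrix(FALSE, nrow = ncol(binary), ncol = length(ids),
                dimnames = list(colnames(binary), ids))
  for (cid in unique(members$cluster_id)) {
    mem <- members$herv_id[members$cluster_id == cid]
    out[, cid] <- colSums(binary[mem, , drop = FALSE]) > 0
  }
  out
}

#' Classify samples by cluster-positivity voting
#'
#' For each sample and subgroup, the cluster expression rate is the
#' fraction of that subgroup's clusters that are positive. The call is the
#' subgroup with the strictly highest rate; rate ties are broken by the
#' larger absolute count of positive clusters, and remaining ties give
#' `"unclassified"` with the tie flag set. A sample with all rates zero is
#' `"unclassified"`.
#'
#' @param binary a [binarize()] matrix, or a [herv_expr] (binarized at
#'   TPM > 1).
#' @param panel a `herv_panel` with at least one cluster.
#' @return tibble of class `herv_calls`: `sample_id`, one `rate_<subgroup>`
#'   column per subgroup, `call`, `tie`.
#' @export
classify_samples <- function(binary, panel) {
  if (inherits(binary, "herv_expr")) binary <- binarize(binary)
  if (nrow(panel$clusters) == 0) stop("empty panel", call. = FALSE)
  pos <- cluster_positivity(binary, panel)
  cl_sub <- dplyr::distinct(panel$clusters, .data$cluster_id,
                            .data$target_subgroup)
  groups <- panel$subgroups
  n_cl <- vapply(groups, function(g)
    sum(cl_sub$target_subgroup == g), numeric(1))
  counts <- vapply(groups, function(g) {
    cid <- cl_sub$cluster_id[cl_sub$target_subgroup == g]
    rowSums(pos[, cid, drop = FALSE])
  }, numeric(nrow(pos)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
                                             dimnames = list(rownames(pos),
                                                             groups))
  rates <- sweep(counts, 2, n_cl, "/")
  call <- character(nrow(rates)); tie <- logical(nrow(rates))
  for (i in seq_len(nrow(rates))) {
    r <- rates[i, ]
    if (all(r == 0)) { call[i] <- "unclassified"; next }
    top <- which(r == max(r))
    if (length(top) == 1) { call[i] <- groups[top]; next }
    cnt <- counts[i, top]
    best <- which(cnt == max(cnt))
    if (length(best) == 1) {
      call[i] <- groups[top[best]]
      tie[i] <- TRUE
    } else {
      call[i] <- "unclassified"
      tie[i] <- TRUE
    }
  }
  colnames(rates) <- paste0("rate_", groups)
  out <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(pos)),
                          tibble::as_tibble(rates))
  out$call <- call
  out$tie <- tie
  class(out) <- c("herv_calls", class(out))
  out
}

#' Evaluate subgroup calls against reference labels
#'
#' Accuracy counts `"unclassified"` as incorrect. The confusion matrix has
#' truth in rows and calls in columns.
#'
#' @param calls a [classify_samples()] tibble.
#' @param labels tibble (`sample_id`, `subgroup`).
#' @return list with `accuracy`, `n_correct`, `n_total`, and `confusion`
#'   (a base table, truth x call).
#' @export
evaluate_calls <- function(calls, labels) {
  truth <- labels$subgroup[match(calls$sample_id, labels$sample_id)]
  if (anyNA(truth)) stop("labels missing for some called samples", call. = FALSE)
  lev_t <- sort(unique(truth))
  lev_c <- union(lev_t, sort(unique(calls$call)))
  conf <- table(factor(truth, levels = lev_t),
                factor(calls$call, levels = lev_c))
  names(dimnames(conf)) <- c("truth", "call")
  n_correct <- sum(calls$call == truth)
  list(accuracy = n_correct / length(truth), n_correct = n_correct,
       n_total = length(truth), confusion = conf)
}

#' Leave-one-out cross-validation of the full classifier
#'
#' For each fold the classifier panel is re-selected on the training
#' samples only (screen, then clustering), and the held-out sample is
#' classified with that frozen panel; labels never leak into the fold's
#' panel. Folds whose training set loses a whole subgroup are flagged and
#' excluded from the aggregate.
#'
#' @param expr a [herv_expr].
#' @param loci loci tibble covering the hervRNAs.
#' @param labels tibble (`sample_id`, `subgroup`), >= 2 samples per
#'   subgroup.
#' @param screen_cfg a [screen_config()].
#' @param cluster_gap_bp panel clustering gap (default 200 kbp).
#' @param restrict_to optional hervRNA id set passed to [run_screen()].
#' @return object of class `herv_cv`: list with `calls` (per-fold tibble
#'   including `excluded` flag), `accuracy`, `n_excluded`, `confusion`.
#' @export
crossvalidate <- function(expr, loci, labels,
                          screen_cfg = screen_config(),
                          cluster_gap_bp = 2e5, restrict_to = NULL) {
  samples <- colnames(expr$tpm)
  sg <- labels$subgroup[match(samples, labels$sample_id)]
  if (anyNA(sg)) stop("labels missing for some samples", call. = FALSE)
  if (any(table(sg) < 2)) stop("need >= 2 samples per subgroup", call. = FALSE)
  binary_all <- binarize(expr, screen_cfg$threshold_tpm)
  folds <- purrr::map(seq_along(samples), function(i) {
    train <- samples[-i]
    lab_tr <- labels[labels$sample_id %in% train, ]
    if (length(unique(lab_tr$subgroup)) < length(unique(sg))) {
      return(tibble::tibble(sample_id = samples[i], call = NA_character_,
                            tie = NA, excluded = TRUE))
    }
    expr_tr <- herv_expr(expr$tpm[, train, drop = FALSE],
                         unname(expr$feature_class))
    cand <- suppressWarnings(
      run_screen(expr_tr, lab_tr, screen_cfg, loci = loci,
                 restrict_to = restrict_to))
    if (nrow(cand) == 0) {
      return(tibble::tibble(sample_id = samples[i], call = "unclassified",
                            tie = FALSE, excluded = FALSE))
    }
    panel <- build_panel(cand, cluster_gap_bp)
    call_i <- classify_samples(binary_all[, samples[i], drop = FALSE], panel)
    tibble::tibble(sample_id = samples[i], call = call_i$call,
                   tie = call_i$tie, excluded = FALSE)
  })
  calls <- dplyr::bind_rows(folds)
  kept <- calls[!calls$excluded, ]
  truth <- labels$subgroup[match(kept$sample_id, labels$sample_id)]
  acc <- if (nrow(kept) > 0) mean(kept$call == truth) else NA_real_
  conf <- if (nrow(kept) > 0) {
    evaluate_calls(tibble::tibble(sample_id = kept$sample_id,
                                  call = kept$call, tie = kept$tie),
                   labels)$confusion
  } else NULL
  structure(list(calls = calls, accuracy = acc,
                 n_excluded = sum(calls$excluded), confusion = conf),
            class = "herv_cv")
}

#' @export
print.herv_cv <- function(x, ...) {
  cat("<herv_cv> leave-one-out: accuracy ",
      sprintf("%.3f", x$accuracy), " over ",
      sum(!x$calls$excluded), " folds (", x$n_excluded, " excluded)\n",
      sep = "")
  invisible(x)
}
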