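#' Configuration for the independent-expression filter
#'
#' Defaults follow the published filter: gene candidates within a 1 Mbp
#' window of the hervRNA body, a driver gene must be co-expressed at Pearson
#' r > 0.4 (strict) and higher-expressed by a one-sided paired signed-rank
#' test.
#'
#' @param window_bp maximum hervRNA-gene interval gap in bp (default 1e6).
#' @param r_threshold Pearson correlation a driver must strictly exceed
#'   (default 0.4).
#' @param wilcoxon_alpha significance level for the one-sided paired
#'   signed-rank test of "gene higher than hervRNA" (default 0.05; the
#'   published filter states no alpha, so it is exposed here).
#' @param log_tpm if `TRUE`, correlate log2(TPM + 1) instead of raw TPM
#'   (default `FALSE`: the published rule correlates TPM).
#' @return a list of class `herv_filter_config`.
#' @export
filter_config <- function(window_bp = 1e6, r_threshold = 0.4,
                          wilcoxon_alpha = 0.05, log_tpm = FALSE) {
  stopifnot(window_bp > 0, r_threshold > 0, r_threshold < 1,
            wilcoxon_alpha > 0, wilcoxon_alpha < 1)
  structure(list(window_bp = window_bp, r_threshold = r_threshold,
                 wilcoxon_alpha = wilcoxon_alpha, log_tpm = log_tpm),
            class = "herv_filter_config")
}

#' Gap between two genomic intervals
#'
#' Vectorised bp gap between 0-based half-open intervals on the same
#' chromosome: 0 when the intervals overlap or touch, otherwise the number
#' of bases strictly between them. Pairs on different chromosomes are not
#' comparable and yield `NA`.
#'
#' @param chrom_a,start_a,end_a first interval (vectors recycle).
#' @param chrom_b,start_b,end_b second interval.
#' @return numeric vector of gaps in bp (`NA` across chromosomes).
#' @export
#' @examples
#' gap_distance("chr1", 100, 200, "chr1", 300, 400) # 100
#' gap_distance("chr1", 100, 300, "chr1", 200, 400) # 0 (overlap)
#' gap_distance("chr1", 100, 200, "chr2", 300, 400) # NA
gap_distance <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  gap <- pmax(start_a, start_b) - pmin(end_a, end_b)
  gap <- pmax(gap, 0)
  gap[chrom_a != chrom_b] <- NA_real_
  gap
}

#' Enumerate hervRNA-gene neighbor pairs within a window
#'
#' Every (hervRNA, gene) pair on the same chromosome whose interval gap is
#' at most `config$window_bp`. Genes are all features whose class is not
#' `"hervRNA"`. hervRNA-hervRNA pairs are never emitted.
#'
#' @param loci loci tibble (see [read_loci_bed()]) with a `feature_class`
#'   column, or pass `classes` separately.
#' @param config a [filter_config()].
#' @param classes optional named character vector of feature classes, used
#'   when `loci` has no `feature_class` column.
#' @return tibble with columns `herv_id`, `gene_id`, `gap_bp`.
#' @export
find_neighbor_pairs <- function(loci, config = filter_config(),
                                classes = NULL) {
  if (!"feature_class" %in% names(loci)) {
    if (is.null(classes)) {
      stop("loci need a `feature_class` column or a `classes` vector",
           call. = FALSE)
    }
    loci$feature_class <- unname(classes[loci$feature_id])
  }
  hervs <- dplyr::filter(loci, .data$feature_class == "hervRNA")
  genes <- dplyr::filter(loci, .data$feature_class != "hervRNA")
  if (nrow(hervs) == 0) stop("no hervRNA features in loci", call. = FALSE)
  if (nrow(genes) == 0) {
    return(tibble::tibble(herv_id = character(), gene_id = character(),
                          gap_bp = numeric()))
  }
  pairs <- dplyr::inner_join(
    dplyr::select(hervs, herv_id = "feature_id", chrom = "chrom",
                  h_start = "start", h_end = "end"),
    dplyr::select(genes, gene_id = "feature_id", chrom = "chrom",
                  g_start = "start", g_end = "end"),
    by = "chrom", relationship = "many-to-many")
  pairs$gap_bp <- gap_distance(pairs$chrom, pairs$h_start, pairs$h_end,
                               pairs$chrom, pairs$g_start, pairs$g_end)
  pairs <- dplyr::filter(pairs, .data$gap_bp <= config$window_bp)
  dplyr::arrange(
    dplyr::select(pairs, "herv_id", "gene_id", "gap_bp"),
    .data$herv_id, .data$gene_id)
}

#' One-sided paired Wilcoxon signed-rank test (greater)
#'
#' Tests whether paired differences x - y tend to be positive
#' (alternative: median(x - y) > 0). Zero differences are removed before
#' ranking; ties receive midranks. For up to `exact_max_n` non-zero
#' differences the null distribution of the rank sum is computed exactly
#' (tie-aware, by dynamic programming over doubled ranks); above that a
#' normal approximation with continuity and tie correction is used.
#'
#' @param x,y paired numeric vectors of equal length (>= 5 pairs).
#' @param exact_max_n largest number of non-zero differences for which the
#'   exact null is enumerated (default 25).
#' @return a list with `p_value`, `statistic` (the positive-rank sum W+),
#'   `n_nonzero`, and `degenerate` (`TRUE` when all differences are zero,
#'   in which case `p_value` is 1).
#' @export
#' @examples
#' paired_wilcoxon_greater(2:6 + 1, 2:6)$p_value # 1/32
paired_wilcoxon_greater <- function(x, y, exact_max_n = 25) {
  stopifnot(length(x) == length(y))
  if (length(x) < 5) stop("need at least 5 pairs", call. = FALSE)
  d <- x - y
  d <- d[is.finite(d)]
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) {
    return(list(p_value = 1, statistic = 0, n_nonzero = 0L, degenerate = TRUE))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (m <= exact_max_n) {
    p <- signed_rank_exact_p(r, w)
  } else {
    mu <- m * (m + 1) / 4
    ties <- table(r)
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - 0.5) / sqrt(sigma2)
    p <- stats::pnorm(z, lower.tail = FALSE)
  }
  list(p_value = p, statistic = w, n_nonzero = m, degenerate = FALSE)
}

# Exact P(W+ >= w) under random signs on the observed (mid)ranks.
# Midranks are multiples of 0.5, so doubling gives integers; the null
# distribution is built by polynomial convolution over the 2^m equally
# likely sign assignments.
signed_rank_exact_p <- function(ranks, w) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  counts <- rep(0, total + 1)  # counts[k + 1] = #assignments with 2*W+ = k
  counts[1] <- 1
  for (ri in r2) {
    shifted <- c(rep(0, ri), counts[seq_len(total + 1 - ri)])
    counts <- counts + shifted
  }
  w2 <- as.integer(round(2 * w))
  sum(counts[(w2 + 1):(total + 1)]) / 2^length(r2)
}

#' Assign driver genes to hervRNAs
#'
#' A hervRNA is "driven" when at least one neighbor gene is both
#' higher-expressed (one-sided paired signed-rank p < `wilcoxon_alpha`) and
#' co-expressed with it at Pearson r strictly greater than `r_threshold`;
#' otherwise it is independently expressed. When several genes qualify the
#' one with the highest r is recorded as the driver.
#'
#' @param expr a [herv_expr].
#' @param pairs neighbor pairs from [find_neighbor_pairs()].
#' @param config a [filter_config()].
#' @return tibble with one row per hervRNA appearing in `pairs` plus every
#'   hervRNA in `expr` that had no neighbor (trivially independent):
#'   `herv_id`, `status` (`"driven"`/`"independent"`), `driver_gene_id`,
#'   `r`, `p`, `gap_bp`.
#' @export
assign_drivers <- function(expr, pairs, config = filter_config()) {
  tpm <- expr$tpm
  missing_f <- setdiff(unique(c(pairs$herv_id, pairs$gene_id)), rownames(tpm))
  if (length(missing_f) > 0) {
    stop("pair feature(s) absent from expression matrix: ",
         paste(utils::head(missing_f, 5), collapse = ", "), call. = FALSE)
  }
  val <- if (config$log_tpm) log2(tpm + 1) else tpm
  n <- ncol(val)
  feats <- unique(c(pairs$herv_id, pairs$gene_id))
  sub <- val[feats, , drop = FALSE]
  mu <- rowMeans(sub)
  sdv <- sqrt(rowSums((sub - mu)^2) / (n - 1))
  z <- (sub - mu) / ifelse(sdv > 0, sdv, NA_real_)
  # Pearson r on (possibly log) TPM; NA when either vector is constant
  r_vec <- rowSums(z[pairs$herv_id, , drop = FALSE] *
                     z[pairs$gene_id, , drop = FALSE]) / (n - 1)
  n_pairs <- nrow(pairs)
  p_vec <- rep(NA_real_, n_pairs)
  for (i in seq_len(n_pairs)) {
    p_vec[i] <- paired_wilcoxon_greater(tpm[pairs$gene_id[i], ],
                                        tpm[pairs$herv_id[i], ])$p_value
  }
  pairs$r <- r_vec
  pairs$p <- p_vec
  pairs$qualifies <- !is.na(r_vec) & r_vec > config$r_threshold &
    p_vec < config$wilcoxon_alpha
  driven <- pairs |>
    dplyr::filter(.data$qualifies) |>
    dplyr::arrange(.data$herv_id, dplyr::desc(.data$r), .data$gene_id) |>
    dplyr::distinct(.data$herv_id, .keep_all = TRUE) |>
    dplyr::transmute(.data$herv_id, status = "driven",
                     driver_gene_id = .data$gene_id,
                     r = .data$r, p = .data$p, gap_bp = .data$gap_bp)
  all_hervs <- union(features_of_class(expr, "hervRNA"),
                     unique(pairs$herv_id))
  indep <- setdiff(all_hervs, driven$herv_id)
  out <- dplyr::bind_rows(
    driven,
    tibble::tibble(herv_id = indep, status = "independent",
                   driver_gene_id = NA_character_, r = NA_real_,
                   p = NA_real_, gap_bp = NA_real_))
  dplyr::arrange(out, .data$herv_id)
}

#' Run the full independence filter
#'
#' Convenience wrapper: enumerate neighbor pairs from `loci` then call
#' [assign_drivers()].
#'
#' @inheritParams assign_drivers
#' @param loci loci tibble; feature classes are taken from `expr`.
#' @return the [assign_drivers()] tibble.
#' @export
filter_independent <- function(expr, loci, config = filter_config()) {
  pairs <- find_neighbor_pairs(loci, config, classes = expr$feature_class)
  assign_drivers(expr, pairs, config)
}
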