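#' Promoter regions around hervRNA transcription start sites
#'
#' The promoter of a feature is the window TSS +/- `flank_bp`, strand-aware
#' in 0-based half-open coordinates: on the plus strand the TSS is the
#' interval start, on the minus strand it is `end - 1`. Windows are clipped
#' at chromosome position 0.
#'
#' @param loci loci tibble (chrom, start, end, feature_id, strand).
#' @param flank_bp half-width of the window in bp (default 1000).
#' @return tibble: `herv_id`, `chrom`, `start`, `end`, `strand`, `tss`.
#' @export
#' @examples
#' loci <- tibble::tibble(chrom = "chr1", start = 10000, end = 12000,
#'                        feature_id = "h1", score = 0, strand = "+")
#' promoter_regions(loci) # [9000, 11000)
promoter_regions <- function(loci, flank_bp = 1000) {
  validate_loci(loci)
  tss <- ifelse(loci$strand == "+", loci$start, loci$end - 1)
  tibble::tibble(
    herv_id = loci$feature_id,
    chrom = loci$chrom,
    start = pmax(0, tss - flank_bp),
    end = tss + flank_bp,
    strand = loci$strand,
    tss = tss)
}

#' Summarize promoter methylation to per-sample beta values
#'
#' A CpG contributes only when its coverage is at least `min_coverage` in
#' every sample of the cohort (a CpG under-covered in one sample is dropped
#' for all). The promoter beta of a sample is the read-weighted mean over
#' retained CpGs in the window: sum(meth) / sum(total). With
#' `weighted = FALSE` the unweighted mean of per-CpG betas is used instead.
#' Promoters with no retained CpG get `NA` beta.
#'
#' @param meth methylation tibble (see [read_methylation_table()]).
#' @param promoters tibble from [promoter_regions()].
#' @param min_coverage minimum reads per CpG per sample (default 5).
#' @param samples cohort sample ids; defaults to all samples in `meth`.
#' @param weighted read-weighted (default) or plain mean of CpG betas.
#' @return tibble: `herv_id`, `sample_id`, `beta`, `n_cpgs` (complete over
#'   promoters x samples; `beta` is `NA` where no CpG was retained).
#' @export
summarize_promoter_beta <- function(meth, promoters, min_coverage = 5,
                                    samples = NULL, weighted = TRUE) {
  validate_methylation(meth)
  if (is.null(samples)) samples <- sort(unique(meth$sample_id))
  meth <- meth[meth$sample_id %in% samples, , drop = FALSE]
  # retain CpGs covered >= min_coverage in every sample
  site <- meth |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::summarise(
      n_cov = sum(.data$total_reads >= min_coverage),
      .groups = "drop")
  keep <- site[site$n_cov == length(samples), c("chrom", "pos")]
  meth_k <- dplyr::inner_join(meth, keep, by = c("chrom", "pos"))
  # map retained CpGs into promoter windows
  hits <- dplyr::inner_join(
    meth_k,
    dplyr::select(promoters, "herv_id", "chrom", p_start = "start",
                  p_end = "end"),
    by = "chrom", relationship = "many-to-many")
  hits <- dplyr::filter(hits, .data$pos >= .data$p_start,
                        .data$pos < .data$p_end)
  agg <- hits |>
    dplyr::group_by(.data$herv_id, .data$sample_id) |>
    dplyr::summarise(
      beta = if (weighted) sum(.data$meth_reads) / sum(.data$total_reads)
             else mean(.data$meth_reads / .data$total_reads),
      n_cpgs = dplyr::n_distinct(.data$chrom, .data$pos),
      .groups = "drop")
  grid <- tidyr::expand_grid(herv_id = promoters$herv_id,
                             sample_id = samples)
  out <- dplyr::left_join(grid, agg, by = c("herv_id", "sample_id"))
  out$n_cpgs[is.na(out$n_cpgs)] <- 0L
  out
}

#' Differential promoter methylation between a subgroup and the rest
#'
#' For each promoter, the methylation difference is the target-subgroup
#' mean beta minus the others' mean beta, on a 0-100 percentage scale; the
#' p-value comes from a two-sided Fisher's exact test on the pooled
#' methylated/unmethylated read counts (target vs rest) over the retained
#' CpGs; q-values are BH over all promoters with a defined result. The
#' hypomethylated flag requires `meth_diff <= -diff_min` and `q <= q_max`.
#'
#' @param meth methylation tibble.
#' @param promoters tibble from [promoter_regions()].
#' @param labels tibble (`sample_id`, `subgroup`).
#' @param target subgroup tested for hypomethylation.
#' @param diff_min minimum absolute difference in percentage points
#'   (default 25).
#' @param q_max BH q-value cutoff (default 0.01).
#' @param min_coverage per-CpG coverage filter (default 5).
#' @return tibble: `herv_id`, `target_subgroup`, `meth_diff`, `p`, `q`,
#'   `hypomethylated`. Promoters with no defined beta in a whole group are
#'   dropped.
#' @export
differential_methylation <- function(meth, promoters, labels, target,
                                     diff_min = 25, q_max = 0.01,
                                     min_coverage = 5) {
  samples <- sort(unique(meth$sample_id))
  sg <- labels$subgroup[match(samples, labels$sample_id)]
  if (anyNA(sg)) stop("labels missing for methylation samples", call. = FALSE)
  if (sum(sg == target) < 2 || sum(sg != target) < 2) {
    stop("need >= 2 samples per compared group", call. = FALSE)
  }
  pm <- summarize_promoter_beta(meth, promoters, min_coverage,
                                samples = samples)
  pm$in_target <- sg[match(pm$sample_id, samples)] == target
  betas <- pm |>
    dplyr::filter(!is.na(.data$beta)) |>
    dplyr::group_by(.data$herv_id, .data$in_target) |>
    dplyr::summarise(mean_beta = mean(.data$beta), n = dplyr::n(),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "in_target",
                       values_from = c("mean_beta", "n"))
  if (!all(c("mean_beta_TRUE", "mean_beta_FALSE") %in% names(betas))) {
    return(tibble::tibble(herv_id = character(),
                          target_subgroup = character(),
                          meth_diff = numeric(), p = numeric(),
                          q = numeric(), hypomethylated = logical()))
  }
  betas <- dplyr::filter(betas, !is.na(.data$mean_beta_TRUE),
                         !is.na(.data$mean_beta_FALSE))
  # pooled counts per promoter x group from retained CpGs in the window
  counts <- pooled_promoter_counts(meth, promoters, min_coverage, samples)
  counts$in_target <- sg[match(counts$sample_id, samples)] == target
  pooled <- counts |>
    dplyr::group_by(.data$herv_id, .data$in_target) |>
    dplyr::summarise(meth = sum(.data$meth_reads),
                     total = sum(.data$total_reads), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "in_target",
                       values_from = c("meth", "total"))
  res <- dplyr::inner_join(betas, pooled, by = "herv_id")
  res$p <- vapply(seq_len(nrow(res)), function(i) {
    fisher_exact_2x2(matrix(c(res$meth_TRUE[i],
                              res$total_TRUE[i] - res$meth_TRUE[i],
                              res$meth_FALSE[i],
                              res$total_FALSE[i] - res$meth_FALSE[i]),
                            nrow = 2, byrow = TRUE))
  }, numeric(1))
  out <- tibble::tibble(
    herv_id = res$herv_id,
    target_subgroup = target,
    meth_diff = 100 * (res$mean_beta_TRUE - res$mean_beta_FALSE),
    p = res$p,
    q = bh_adjust(res$p))
  out$hypomethylated <- out$meth_diff <= -diff_min & out$q <= q_max
  dplyr::arrange(out, .data$herv_id)
}

# per (herv, sample): pooled read counts over retained CpGs in the window
pooled_promoter_counts <- function(meth, promoters, min_coverage, samples) {
  meth <- meth[meth$sample_id %in% samples, , drop = FALSE]
  site <- meth |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::summarise(n_cov = sum(.data$total_reads >= min_coverage),
                     .groups = "drop")
  keep <- site[site$n_cov == length(samples), c("chrom", "pos")]
  meth_k <- dplyr::inner_join(meth, keep, by = c("chrom", "pos"))
  hits <- dplyr::inner_join(
    meth_k,
    dplyr::select(promoters, "herv_id", "chrom", p_start = "start",
                  p_end = "end"),
    by = "chrom", relationship = "many-to-many")
  hits <- dplyr::filter(hits, .data$pos >= .data$p_start,
                        .data$pos < .data$p_end)
  hits |>
    dplyr::group_by(.data$herv_id, .data$sample_id) |>
    dplyr::summarise(meth_reads = sum(.data$meth_reads),
                     total_reads = sum(.data$total_reads), .groups = "drop")
}

#' Correlate promoter methylation with hervRNA expression
#'
#' Pearson correlation between per-sample promoter beta and TPM across the
#' samples with a defined beta, with a two-sided t-distribution p-value.
#' A hervRNA is flagged when r is strictly below `r_neg` and p strictly
#' below `p_max` (defaults r < -0.6, p < 0.05, the published rule).
#'
#' @param pm promoter beta tibble from [summarize_promoter_beta()].
#' @param expr a [herv_expr] holding the matching samples.
#' @param r_neg correlation flag threshold (default -0.6, strict).
#' @param p_max p-value flag threshold (default 0.05, strict).
#' @param min_samples minimum samples with defined beta (default 5).
#' @return tibble: `herv_id`, `r`, `p`, `n`, `flagged`. `r` is `NA` (never
#'   flagged) when either vector is constant or `n < min_samples`.
#' @export
methylation_expression_correlation <- function(pm, expr, r_neg = -0.6,
                                               p_max = 0.05,
                                               min_samples = 5) {
  tpm <- expr$tpm
  pm <- pm[!is.na(pm$beta) & pm$sample_id %in% colnames(tpm), , drop = FALSE]
  pm <- pm[pm$herv_id %in% rownames(tpm), , drop = FALSE]
  out <- pm |>
    dplyr::group_by(.data$herv_id) |>
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      x <- df$beta
      y <- tpm[key$herv_id[[1]], df$sample_id]
      if (n < min_samples || stats::sd(x) == 0 || stats::sd(y) == 0) {
        return(tibble::tibble(r = NA_real_, p = NA_real_, n = n))
      }
      ct <- stats::cor.test(x, y, method = "pearson",
                            alternative = "two.sided")
      tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = n)
    }) |>
    dplyr::ungroup()
  out$flagged <- !is.na(out$r) & out$r < r_neg & out$p < p_max
  dplyr::arrange(out, .data$herv_id)
}
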