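#' Configuration for the binary classifier screen
#'
#' Defaults are the published selection criteria: binarize at TPM = 1
#' (strictly greater), Fisher association with subgroup at BH-adjusted
#' P < 0.01, mean TPM > 5 in the target subgroup and < 5 in the others,
#' log2 fold change of mean TPM > 2, and classification specificity > 0.8.
#'
#' @param threshold_tpm TPM binarization threshold (default 1).
#' @param adj_p_max BH-adjusted Fisher p gate (default 0.01).
#' @param mean_tpm_on mean-TPM gate: strictly above in the target subgroup,
#'   strictly below in others (default 5).
#' @param log2fc_min log2 fold-change gate, target over pooled others
#'   (default 2).
#' @param specificity_min specificity gate, strictly exceeded (default 0.8).
#' @param pseudocount TPM pseudocount for the fold change (default 0.01).
#' @param others_rule `"each"` (default): mean TPM must be < `mean_tpm_on`
#'   within every non-target subgroup; `"pooled"`: on the pooled non-target
#'   mean only.
#' @return a list of class `herv_screen_config`.
#' @export
screen_config <- function(threshold_tpm = 1, adj_p_max = 0.01,
                          mean_tpm_on = 5, log2fc_min = 2,
                          specificity_min = 0.8, pseudocount = 0.01,
                          others_rule = c("each", "pooled")) {
  others_rule <- match.arg(others_rule)
  stopifnot(threshold_tpm > 0, adj_p_max > 0, adj_p_max < 1,
            mean_tpm_on > 0, log2fc_min > 0,
            specificity_min > 0, specificity_min < 1, pseudocount > 0)
  structure(list(threshold_tpm = threshold_tpm, adj_p_max = adj_p_max,
                 mean_tpm_on = mean_tpm_on, log2fc_min = log2fc_min,
                 specificity_min = specificity_min, pseudocount = pseudocount,
                 others_rule = others_rule),
            class = "herv_screen_config")
}

#' Binarize an expression matrix at a TPM threshold
#'
#' A feature is "expressed" in a sample when its TPM strictly exceeds the
#' threshold. Idempotent: re-binarizing a 0/1 matrix at any threshold < 1
#' returns it unchanged, and `binarize` applied to its own output with the
#' default threshold of 1 yields an all-zero change only when values equal 1.
#'
#' @param expr a [herv_expr] or a numeric matrix.
#' @param threshold_tpm threshold (default 1, strictly greater).
#' @return integer 0/1 matrix with the same dimnames.
#' @export
binarize <- function(expr, threshold_tpm = 1) {
  m <- if (inherits(expr, "herv_expr")) expr$tpm else expr
  out <- (m > threshold_tpm) + 0L
  dimnames(out) <- dimnames(m)
  out
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' The two-sided p-value is the total hypergeometric probability of all
#' tables (with the observed margins) whose probability does not exceed
#' that of the observed table, using the conventional relative tolerance
#' of 1e-7 for the comparison. A table with any zero margin carries no
#' information and returns p = 1.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return the two-sided p-value.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(3, 0, 0, 3), 2)) # 0.1
fisher_exact_2x2 <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2, 2)))
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table must hold non-negative integers", call. = FALSE)
  }
  fisher_p_scalar(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
}

# p for table [[a, b], [c, d]] by hypergeometric enumeration
fisher_p_scalar <- function(a, b, c, d) {
  m <- a + c      # column 1 total
  n <- b + d      # column 2 total
  k <- a + b      # row 1 total
  if (m == 0 || n == 0 || k == 0 || c + d == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# vectorised over (a, b) with fixed group sizes: a of n1 target samples
# expressed, b of n2 others expressed; memoised over unique tables
fisher_p_expressed <- function(a, b, n1, n2) {
  key <- paste(a, b, n1, n2)
  uk <- !duplicated(key)
  pu <- mapply(function(a, b, n1, n2) {
    fisher_p_scalar(a, n1 - a, b, n2 - b)
  }, a[uk], b[uk], n1[uk], n2[uk])
  unname(pu[match(key, key[uk])])
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up FDR adjustment with enforced monotonicity; the output is
#' in the same order as the input.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values (q-values), same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric())
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  n <- length(p)
  o <- order(p, decreasing = TRUE, na.last = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n / (n:1) * p[o]))[ro]
  q[is.na(p)] <- NA_real_
  q
}

#' Score one (hervRNA, subgroup) classifier candidate
#'
#' Evaluates the four selection criteria for a single candidate:
#' subgroup association (two-sided Fisher's exact on expressed/not x
#' target/rest), mean TPM above `mean_tpm_on` in the target subgroup and
#' below it in the others, log2 fold change of mean TPM above `log2fc_min`,
#' and specificity (fraction of non-target samples not expressing the
#' hervRNA) above `specificity_min`. BH adjustment is defined jointly over
#' all tested hypotheses, so a standalone call gates on the raw Fisher p
#' unless `fisher_p_adj` is supplied; [run_screen()] performs the joint
#' adjustment.
#'
#' @param expr a [herv_expr].
#' @param labels tibble (`sample_id`, `subgroup`) covering all samples.
#' @param herv_id feature to score.
#' @param target target subgroup.
#' @param config a [screen_config()].
#' @param binary optional precomputed [binarize()] matrix.
#' @param fisher_p_adj optional BH-adjusted p for this candidate.
#' @return one-row tibble with the candidate's statistics, per-criterion
#'   flags and the overall `passed` flag.
#' @export
score_candidate <- function(expr, labels, herv_id, target,
                            config = screen_config(), binary = NULL,
                            fisher_p_adj = NULL) {
  tpm <- expr$tpm
  if (!herv_id %in% rownames(tpm)) stop("unknown feature: ", herv_id, call. = FALSE)
  sg <- labels$subgroup[match(colnames(tpm), labels$sample_id)]
  if (anyNA(sg)) stop("labels missing for some samples", call. = FALSE)
  if (!target %in% sg) stop("no samples in target subgroup ", target, call. = FALSE)
  if (any(table(sg) == 0)) stop("subgroup with 0 samples", call. = FALSE)
  if (is.null(binary)) binary <- binarize(expr, config$threshold_tpm)
  x <- tpm[herv_id, ]
  b <- binary[herv_id, ]
  in_t <- sg == target
  a_ct <- sum(b[in_t]); b_ct <- sum(b[!in_t])
  fisher_p <- fisher_p_scalar(a_ct, sum(in_t) - a_ct, b_ct, sum(!in_t) - b_ct)
  mean_t <- mean(x[in_t])
  means_other <- tapply(x[!in_t], sg[!in_t], mean)
  mean_others_pooled <- mean(x[!in_t])
  pc <- config$pseudocount
  log2fc <- log2((mean_t + pc) / (mean_others_pooled + pc))
  specificity <- 1 - b_ct / sum(!in_t)
  precision <- if (a_ct + b_ct > 0) a_ct / (a_ct + b_ct) else NA_real_
  p_gate <- if (is.null(fisher_p_adj)) fisher_p else fisher_p_adj
  crit_assoc <- p_gate < config$adj_p_max
  crit_mean <- mean_t > config$mean_tpm_on &&
    (if (config$others_rule == "each") all(means_other < config$mean_tpm_on)
     else mean_others_pooled < config$mean_tpm_on)
  crit_fc <- log2fc > config$log2fc_min
  crit_spec <- specificity > config$specificity_min
  tibble::tibble(
    herv_id = herv_id, target_subgroup = target,
    fisher_p = fisher_p,
    fisher_p_adj = if (is.null(fisher_p_adj)) NA_real_ else fisher_p_adj,
    mean_tpm_target = mean_t,
    mean_tpm_others_max = max(means_other),
    log2fc_mean_tpm = log2fc,
    specificity = specificity, precision = precision,
    crit_assoc = crit_assoc, crit_mean = crit_mean,
    crit_fc = crit_fc, crit_spec = crit_spec,
    passed = crit_assoc && crit_mean && crit_fc && crit_spec)
}

#' Screen all hervRNAs for subgroup-specific binary classifiers
#'
#' Tests every (hervRNA, subgroup) pair against the four selection criteria.
#' The Fisher tests are BH-adjusted jointly across all tested hypotheses.
#' Candidates are ordered by (target subgroup, chrom, start) when loci are
#' supplied, else by (target, herv_id).
#'
#' @param expr a [herv_expr].
#' @param labels tibble (`sample_id`, `subgroup`).
#' @param config a [screen_config()].
#' @param loci optional loci tibble used for deterministic genomic ordering
#'   (and carried into the result for clustering).
#' @param restrict_to optional character vector of hervRNA ids to screen
#'   (e.g. the independently expressed set); default all hervRNAs.
#' @param keep_all if `TRUE` return all scored candidates with their flags;
#'   default returns passing candidates only.
#' @return tibble of classifier candidates (see [score_candidate()] for
#'   columns), plus `chrom`/`start`/`end`/`strand` when `loci` given.
#' @export
run_screen <- function(expr, labels, config = screen_config(), loci = NULL,
                       restrict_to = NULL, keep_all = FALSE) {
  tpm <- expr$tpm
  hervs <- features_of_class(expr, "hervRNA")
  if (!is.null(restrict_to)) hervs <- intersect(hervs, restrict_to)
  if (length(hervs) == 0) {
    warning("no hervRNAs to screen")
    return(tibble::tibble())
  }
  sg <- labels$subgroup[match(colnames(tpm), labels$sample_id)]
  if (anyNA(sg)) stop("labels missing for some samples", call. = FALSE)
  groups <- sort(unique(sg))
  design <- vapply(groups, function(g) as.numeric(sg == g),
                   numeric(length(sg)))          # samples x groups
  n_g <- colSums(design)
  if (any(n_g == 0)) stop("subgroup with 0 samples", call. = FALSE)
  tpm_h <- tpm[hervs, , drop = FALSE]
  bin_h <- (tpm_h > config$threshold_tpm) + 0
  mean_g <- sweep(tpm_h %*% design, 2, n_g, "/")   # hervs x groups
  colnames(mean_g) <- groups
  expr_ct <- bin_h %*% design                      # expressed per group
  colnames(expr_ct) <- groups
  n_total <- length(sg)
  total_mean <- rowMeans(tpm_h)
  total_expr <- rowSums(bin_h)
  pc <- config$pseudocount

  scored <- purrr::map_dfr(groups, function(g) {
    n1 <- n_g[[g]]
    n2 <- n_total - n1
    a <- expr_ct[, g]
    b <- total_expr - a
    mean_t <- mean_g[, g]
    mean_others_pooled <- (total_mean * n_total - mean_t * n1) / n2
    others <- mean_g[, setdiff(groups, g), drop = FALSE]
    mean_others_max <- apply(others, 1, max)
    crit_mean_others <- if (config$others_rule == "each") {
      mean_others_max < config$mean_tpm_on
    } else {
      mean_others_pooled < config$mean_tpm_on
    }
    tibble::tibble(
      herv_id = hervs, target_subgroup = g,
      fisher_p = fisher_p_expressed(a, b, rep(n1, length(a)),
                                    rep(n2, length(a))),
      mean_tpm_target = unname(mean_t),
      mean_tpm_others_max = unname(mean_others_max),
      log2fc_mean_tpm = unname(log2((mean_t + pc) /
                                      (mean_others_pooled + pc))),
      specificity = unname(1 - b / n2),
      precision = ifelse(a + b > 0, a / (a + b), NA_real_),
      crit_mean = unname(mean_t > config$mean_tpm_on & crit_mean_others))
  })
  scored$fisher_p_adj <- bh_adjust(scored$fisher_p)
  scored$crit_assoc <- scored$fisher_p_adj < config$adj_p_max
  scored$crit_fc <- scored$log2fc_mean_tpm > config$log2fc_min
  scored$crit_spec <- scored$specificity > config$specificity_min
  scored$passed <- scored$crit_assoc & scored$crit_mean &
    scored$crit_fc & scored$crit_spec
  if (!is.null(loci)) {
    scored <- dplyr::left_join(
      scored,
      dplyr::select(loci, herv_id = "feature_id", "chrom", "start", "end",
                    "strand"),
      by = "herv_id")
    scored <- dplyr::arrange(scored, .data$target_subgroup, .data$chrom,
                             .data$start, .data$herv_id)
  } else {
    scored <- dplyr::arrange(scored, .data$target_subgroup, .data$herv_id)
  }
  out <- if (keep_all) scored else dplyr::filter(scored, .data$passed)
  if (!keep_all && nrow(out) == 0) warning("no classifier candidates passed")
  out
}
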