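#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a classifier panel into one row per member hervRNA
#'
#' @param x a `herv_panel`.
#' @param ... unused.
#' @return tibble: `cluster_id`, `target_subgroup`, `herv_id`, `chrom`,
#'   `start`, `end`, `cluster_start`, `cluster_end`.
#' @export
tidy.herv_panel <- function(x, ...) {
  tibble::as_tibble(x$clusters)
}

#' One-row summary of a classifier panel
#'
#' @param x a `herv_panel`.
#' @param ... unused.
#' @return tibble with `n_clusters`, `n_members`, `n_subgroups`,
#'   `cluster_gap_bp`, `linkage`.
#' @export
glance.herv_panel <- function(x, ...) {
  tibble::tibble(
    n_clusters = dplyr::n_distinct(x$clusters$cluster_id),
    n_members = nrow(x$clusters),
    n_subgroups = length(x$subgroups),
    cluster_gap_bp = x$cluster_gap_bp,
    linkage = x$linkage)
}

#' Tidy cross-validation results into per-fold calls
#'
#' @param x a `herv_cv`.
#' @param ... unused.
#' @return the per-fold calls tibble (`sample_id`, `call`, `tie`,
#'   `excluded`).
#' @export
tidy.herv_cv <- function(x, ...) {
  tibble::as_tibble(x$calls)
}

#' One-row summary of a cross-validation run
#'
#' @param x a `herv_cv`.
#' @param ... unused.
#' @return tibble with `accuracy`, `n_folds`, `n_excluded`.
#' @export
glance.herv_cv <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy,
                 n_folds = sum(!x$calls$excluded),
                 n_excluded = x$n_excluded)
}

#' Heatmap of per-sample cluster expression rates
#'
#' Tiles samples by subgroup rate, annotated with the final call, the way
#' cluster-positivity voting is usually eyeballed.
#'
#' @param object a [classify_samples()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.herv_calls <- function(object, ...) {
  long <- tidyr::pivot_longer(object,
                              dplyr::starts_with("rate_"),
                              names_to = "subgroup", values_to = "rate",
                              names_prefix = "rate_")
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$sample_id, y = .data$subgroup, fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#b2182b",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "cluster\nexpression rate") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' Scatter plot of promoter methylation against expression
#'
#' @param pm promoter beta tibble from [summarize_promoter_beta()].
#' @param expr a [herv_expr].
#' @param herv_id feature to plot.
#' @param labels optional labels tibble to colour points by subgroup.
#' @return a ggplot object.
#' @export
plot_meth_expr <- function(pm, expr, herv_id, labels = NULL) {
  df <- pm[pm$herv_id == herv_id & !is.na(pm$beta), , drop = FALSE]
  if (nrow(df) == 0) stop("no defined promoter beta for ", herv_id,
                          call. = FALSE)
  df$tpm <- expr$tpm[herv_id, df$sample_id]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$beta, y = .data$tpm))
  if (!is.null(labels)) {
    df$subgroup <- labels$subgroup[match(df$sample_id, labels$sample_id)]
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$beta, y = .data$tpm,
                                          colour = .data$subgroup))
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(x = "promoter beta", y = "TPM", title = herv_id) +
    ggplot2::theme_minimal()
}

#' Genomic map of classifier candidates
#'
#' Positions of passing classifier hervRNAs along the synthetic (or real)
#' genome, coloured by target subgroup — the clustered layout that the
#' 200 kbp grouping exploits.
#'
#' @param candidates [run_screen()] output carrying `chrom` and `start`.
#' @return a ggplot object.
#' @export
plot_candidate_map <- function(candidates) {
  stopifnot(all(c("chrom", "start", "target_subgroup") %in%
                  names(candidates)))
  ggplot2::ggplot(candidates, ggplot2::aes(
    x = .data$start / 1e6, y = .data$chrom,
    colour = .data$target_subgroup)) +
    ggplot2::geom_point(shape = 124, size = 4) +
    ggplot2::labs(x = "position (Mbp)", y = NULL, colour = "subgroup") +
    ggplot2::theme_minimal()
}
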