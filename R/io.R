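#' Expression matrix container
#'
#' A light matrix-backed container for locus-level TPM expression: a numeric
#' matrix (features x samples) plus a per-feature class label. Feature classes
#' distinguish hervRNAs from the gene annotation used as driver-gene
#' candidates.
#'
#' @param tpm numeric matrix, features x samples, with unique row and column
#'   names. Values are TPM and must be finite and non-negative.
#' @param feature_class character vector (or named vector) giving one class
#'   per feature, in the same order as `rownames(tpm)`. Allowed classes are
#'   `"hervRNA"`, `"coding_gene"`, `"lncRNA"`, `"other_gene"`.
#' @return An object of class `herv_expr`: a list with elements `tpm`
#'   (the validated matrix) and `feature_class` (named character vector).
#' @export
#' @examples
#' m <- matrix(c(1, 0, 2.5, 3, 0, 0.2), nrow = 3,
#'             dimnames = list(c("h1", "h2", "g1"), c("s1", "s2")))
#' herv_expr(m, c("hervRNA", "hervRNA", "coding_gene"))
herv_expr <- function(tpm, feature_class) {
  if (!is.matrix(tpm) || !is.numeric(tpm)) {
    stop("`tpm` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(tpm)) || is.null(colnames(tpm))) {
    stop("`tpm` must carry feature (row) and sample (column) names", call. = FALSE)
  }
  dup_f <- unique(rownames(tpm)[duplicated(rownames(tpm))])
  if (length(dup_f) > 0) {
    stop("duplicate feature ids: ", paste(dup_f, collapse = ", "), call. = FALSE)
  }
  dup_s <- unique(colnames(tpm)[duplicated(colnames(tpm))])
  if (length(dup_s) > 0) {
    stop("duplicate sample ids: ", paste(dup_s, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(tpm) | tpm < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("negative or non-finite TPM at [",
         rownames(tpm)[bad[1, 1]], ", ", colnames(tpm)[bad[1, 2]], "]",
         call. = FALSE)
  }
  feature_class <- unname(feature_class)
  if (length(feature_class) != nrow(tpm)) {
    stop("`feature_class` must give exactly one class per feature", call. = FALSE)
  }
  ok <- feature_class %in% c("hervRNA", "coding_gene", "lncRNA", "other_gene")
  if (!all(ok)) {
    stop("unknown feature class(es): ",
         paste(unique(feature_class[!ok]), collapse = ", "), call. = FALSE)
  }
  names(feature_class) <- rownames(tpm)
  structure(list(tpm = tpm, feature_class = feature_class),
            class = "herv_expr")
}

#' @export
print.herv_expr <- function(x, ...) {
  cls <- table(x$feature_class)
  cat("<herv_expr> ", nrow(x$tpm), " features x ", ncol(x$tpm), " samples\n",
      sep = "")
  cat("  classes: ", paste(names(cls), cls, sep = "=", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.herv_expr <- function(x) dim(x$tpm)

#' Feature ids of a given class
#'
#' @param expr a [herv_expr] object.
#' @param class feature class to select, e.g. `"hervRNA"`.
#' @return character vector of feature ids.
#' @export
features_of_class <- function(expr, class = "hervRNA") {
  names(expr$feature_class)[expr$feature_class %in% class]
}

#' Read / write a TPM expression matrix with a feature-class sidecar
#'
#' The matrix file is a TSV with a header row of sample ids and a first
#' column of feature ids; the sidecar is a two-column TSV
#' (`feature_id`, `feature_class`). Lines starting with `#` are ignored.
#' Values are written with 6 significant digits, so a write/read round trip
#' is exact to that precision.
#'
#' @param path path to the matrix TSV.
#' @param class_path path to the feature-class TSV.
#' @return `read_expression_matrix()` returns a [herv_expr];
#'   `write_expression_matrix()` returns `path` invisibly.
#' @export
read_expression_matrix <- function(path, class_path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (ncol(tab) < 2) stop("expression matrix needs >= 1 sample column", call. = FALSE)
  ids <- as.character(tab[[1]])
  body <- tab[, -1, drop = FALSE]
  not_num <- names(body)[!vapply(body, is.numeric, logical(1))]
  if (length(not_num) > 0) {
    stop("non-numeric expression column(s): ", paste(not_num, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  classes <- readr::read_tsv(class_path, comment = "#", show_col_types = FALSE,
                             progress = FALSE,
                             col_types = readr::cols(.default = "c"))
  names(classes)[1:2] <- c("feature_id", "feature_class")
  missing <- setdiff(ids, classes$feature_id)
  if (length(missing) > 0) {
    stop("feature(s) absent from class sidecar: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  cls <- classes$feature_class[match(ids, classes$feature_id)]
  herv_expr(m, cls)
}

#' @rdname read_expression_matrix
#' @param expr a [herv_expr] object to write.
#' @export
write_expression_matrix <- function(expr, path, class_path) {
  m <- signif(expr$tpm, 6)
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble::tibble(feature_id = rownames(m)), out)
  readr::write_tsv(out, path, progress = FALSE)
  readr::write_tsv(
    tibble::tibble(feature_id = names(expr$feature_class),
                   feature_class = unname(expr$feature_class)),
    class_path, progress = FALSE)
  invisible(path)
}

#' Read / write genomic feature loci as BED6
#'
#' Coordinates are 0-based half-open (BED convention) throughout the package.
#'
#' @param path path to a BED6 file (chrom, start, end, name, score, strand).
#' @return `read_loci_bed()` returns a tibble with columns `chrom`, `start`,
#'   `end`, `feature_id`, `score`, `strand`; `write_loci_bed()` returns
#'   `path` invisibly.
#' @export
read_loci_bed <- function(path) {
  loci <- readr::read_tsv(
    path, comment = "#", progress = FALSE,
    col_names = c("chrom", "start", "end", "feature_id", "score", "strand"),
    col_types = readr::cols(
      chrom = "c", start = "d", end = "d",
      feature_id = "c", score = "d", strand = "c"))
  validate_loci(loci)
  loci
}

#' @rdname read_loci_bed
#' @param loci a loci tibble as returned by [read_loci_bed()].
#' @export
write_loci_bed <- function(loci, path) {
  validate_loci(loci)
  readr::write_tsv(
    loci[, c("chrom", "start", "end", "feature_id", "score", "strand")],
    path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

validate_loci <- function(loci) {
  needed <- c("chrom", "start", "end", "feature_id", "strand")
  miss <- setdiff(needed, names(loci))
  if (length(miss) > 0) {
    stop("loci table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- loci$feature_id[loci$start < 0 | loci$start >= loci$end]
  if (length(bad) > 0) {
    stop("invalid interval (need 0 <= start < end) for: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad_strand <- unique(loci$strand[!loci$strand %in% c("+", "-")])
  if (length(bad_strand) > 0) {
    stop("unknown strand symbol(s): ", paste(bad_strand, collapse = ", "),
         call. = FALSE)
  }
  dup <- unique(loci$feature_id[duplicated(loci$feature_id)])
  if (length(dup) > 0) {
    stop("duplicate feature ids in loci: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  invisible(loci)
}

#' Read / write a long-format per-CpG methylation count table
#'
#' Columns: `chrom`, `pos` (0-based bp), `sample_id`, `meth_reads`,
#' `total_reads`. No coverage filtering happens at read time; filters are
#' explicit downstream operations.
#'
#' @param path path to the TSV.
#' @return `read_methylation_table()` returns a validated tibble;
#'   `write_methylation_table()` returns `path` invisibly.
#' @export
read_methylation_table <- function(path) {
  meth <- readr::read_tsv(
    path, comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      chrom = "c", pos = "d", sample_id = "c",
      meth_reads = "d", total_reads = "d"))
  validate_methylation(meth)
  meth
}

#' @rdname read_methylation_table
#' @param meth a methylation tibble.
#' @export
write_methylation_table <- function(meth, path) {
  validate_methylation(meth)
  readr::write_tsv(
    meth[, c("chrom", "pos", "sample_id", "meth_reads", "total_reads")],
    path, progress = FALSE)
  invisible(path)
}

validate_methylation <- function(meth) {
  needed <- c("chrom", "pos", "sample_id", "meth_reads", "total_reads")
  miss <- setdiff(needed, names(meth))
  if (length(miss) > 0) {
    stop("methylation table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(meth$meth_reads < 0 | meth$total_reads < 0)) {
    stop("negative read counts in methylation table", call. = FALSE)
  }
  bad <- which(meth$meth_reads > meth$total_reads)
  if (length(bad) > 0) {
    stop("meth_reads > total_reads at row ", bad[1], " (",
         meth$chrom[bad[1]], ":", meth$pos[bad[1]], ", ",
         meth$sample_id[bad[1]], ")", call. = FALSE)
  }
  invisible(meth)
}

#' Read / write sample metadata (subgroup labels)
#'
#' @param path path to a two-column TSV (`sample_id`, `subgroup`).
#' @return `read_sample_labels()` returns a tibble;
#'   `write_sample_labels()` returns `path` invisibly.
#' @export
read_sample_labels <- function(path) {
  labels <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                            progress = FALSE,
                            col_types = readr::cols(.default = "c"))
  names(labels)[1:2] <- c("sample_id", "subgroup")
  dup <- unique(labels$sample_id[duplicated(labels$sample_id)])
  if (length(dup) > 0) {
    stop("duplicate sample ids in labels: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  labels
}

#' @rdname read_sample_labels
#' @param labels a labels tibble (`sample_id`, `subgroup`).
#' @export
write_sample_labels <- function(labels, path) {
  readr::write_tsv(labels[, c("sample_id", "subgroup")], path,
                   progress = FALSE)
  invisible(path)
}
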