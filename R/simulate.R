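#' Configuration for the synthetic medulloblastoma hervRNA cohort
#'
#' Defaults emulate the statistical structure of the study cohort the
#' pipeline was designed for: four molecular subgroups of roughly 63
#' samples in total; sparse low-level hervRNA expression (mean TPM about
#' 1.36) against much higher protein-coding gene expression (mean TPM
#' about 24.3); about half the hervRNAs passively co-transcribed with a
#' gene within 1 Mbp at a target Pearson correlation of 0.8; a dozen
#' subgroup-specific marker clusters per subgroup whose members sit within
#' 200 kbp of each other while clusters are more than 1 Mbp apart; 30%
#' dropout of marker expression within the target subgroup; and promoter
#' CpG methylation anticorrelated with expression (r about -0.8) for a
#' subset of the Group3 markers.
#'
#' @param seed integer seed; mandatory, drives every random draw.
#' @param subgroups subgroup label set (default the four consensus
#'   medulloblastoma subgroups).
#' @param n_per_subgroup samples per subgroup: a scalar, or a vector with
#'   one count per subgroup (default 16 each, close to the 63-sample
#'   discovery cohort).
#' @param n_chromosomes,chrom_length synthetic genome shape.
#' @param n_genes number of annotated genes (class `coding_gene`).
#' @param n_hervs number of non-marker hervRNAs (driven + independent).
#' @param frac_driven fraction of `n_hervs` coupled to a neighbor gene.
#' @param coupling_r target Pearson correlation (on TPM) of driven pairs.
#' @param n_marker_clusters planted marker clusters per subgroup.
#' @param markers_per_cluster marker hervRNAs per cluster.
#' @param marker_on_mean_tpm,marker_on_sdlog log-normal "on" expression of
#'   markers in their target subgroup.
#' @param marker_baseline_tpm typical "off" TPM of markers.
#' @param marker_leak_rate probability a non-target sample expresses a
#'   marker at the on level (1 - specificity floor).
#' @param dropout probability a target-subgroup sample fails to express a
#'   marker (delta).
#' @param herv_mean_tpm,herv_sdlog background hervRNA log-normal law.
#' @param gene_mean_tpm,gene_sdlog gene log-normal law.
#' @param meth_frac_anticorrelated fraction of Group3 markers with
#'   methylation-coupled expression.
#' @param meth_target_r target Pearson correlation between promoter beta
#'   and TPM for the anticorrelated subset (default -0.8).
#' @param meth_coverage_mean mean CpG coverage (shifted Poisson, floor 5).
#' @param cpgs_per_promoter CpGs placed per promoter window.
#' @return a validated list of class `herv_sim_config`.
#' @export
sim_config <- function(seed,
                       subgroups = c("WNT", "SHH", "Group3", "Group4"),
                       n_per_subgroup = 16,
                       n_chromosomes = 12, chrom_length = 6e7,
                       n_genes = 600, n_hervs = 2000, frac_driven = 0.5,
                       coupling_r = 0.8,
                       n_marker_clusters = 12, markers_per_cluster = 3,
                       marker_on_mean_tpm = 15, marker_on_sdlog = 0.5,
                       marker_baseline_tpm = 0.05,
                       marker_leak_rate = 0.02, dropout = 0.3,
                       herv_mean_tpm = 1.36, herv_sdlog = 1.0,
                       gene_mean_tpm = 24.30, gene_sdlog = 1.2,
                       meth_frac_anticorrelated = 0.25,
                       meth_target_r = -0.8, meth_coverage_mean = 30,
                       cpgs_per_promoter = 8) {
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(length(subgroups) >= 2, all(n_per_subgroup >= 2),
            length(n_per_subgroup) %in% c(1, length(subgroups)),
            n_chromosomes >= 1, chrom_length > 3e6,
            n_genes >= 1, n_hervs >= 1,
            frac_driven >= 0, frac_driven <= 1,
            coupling_r > 0, coupling_r < 1,
            n_marker_clusters >= 1, markers_per_cluster >= 1,
            marker_on_mean_tpm > 0, marker_leak_rate >= 0,
            marker_leak_rate <= 1, dropout >= 0, dropout <= 1,
            herv_mean_tpm > 0, gene_mean_tpm > 0,
            meth_frac_anticorrelated >= 0, meth_frac_anticorrelated <= 1,
            meth_target_r > -1, meth_target_r < 0,
            meth_coverage_mean >= 5, cpgs_per_promoter >= 1)
  structure(as.list(environment()), class = "herv_sim_config")
}

#' Generate the genomic layout and ground-truth skeleton
#'
#' Genes and hervRNAs are placed on synthetic chromosomes. Driven hervRNAs
#' sit within 1 Mbp of their driver gene; marker hervRNAs form clusters
#' with intra-cluster gaps below 200 kbp, with cluster anchors spaced 3 Mbp
#' apart so distinct clusters are more than 1 Mbp apart. Deterministic
#' under the config seed.
#'
#' @param cfg a [sim_config()].
#' @return list with `loci` (tibble, BED-like, plus `feature_class`) and
#'   `truth` (per-hervRNA tibble: `herv_id`, `role`, `driver_gene_id`,
#'   `target_subgroup`, `cluster_id`, `anticorrelated`).
#' @export
simulate_layout <- function(cfg) {
  set.seed(cfg$seed)
  chroms <- sprintf("chr%02d", seq_len(cfg$n_chromosomes))

  # marker cluster anchors: one slot per (subgroup, cluster index),
  # round-robin over chromosomes, 3 Mbp between slots on a chromosome
  n_clusters <- cfg$n_marker_clusters * length(cfg$subgroups)
  slot_chrom <- (seq_len(n_clusters) - 1) %% cfg$n_chromosomes + 1
  slot_idx <- (seq_len(n_clusters) - 1) %/% cfg$n_chromosomes
  anchor <- cfg$chrom_length - 2e6 - slot_idx * 3e6
  span_max <- cfg$markers_per_cluster * (1.5e5 + 3e3)
  if (any(anchor - span_max < 0)) {
    stop("infeasible packing: too many marker clusters for chromosome length",
         call. = FALSE)
  }
  marker_zone_lo <- min(anchor) - 1e6  # genes/background stay below this
  if (marker_zone_lo - 1.1e6 < 1e5) {
    stop("infeasible packing: chromosomes too short for the marker zone",
         call. = FALSE)
  }

  genes <- tibble::tibble(
    feature_id = sprintf("gene_%04d", seq_len(cfg$n_genes)),
    chrom = sample(chroms, cfg$n_genes, replace = TRUE),
    start = floor(stats::runif(cfg$n_genes, 0, marker_zone_lo - 1.1e6)),
    len = floor(stats::runif(cfg$n_genes, 5e3, 5e4)))
  genes$end <- genes$start + genes$len

  n_driven <- round(cfg$frac_driven * cfg$n_hervs)
  n_indep <- cfg$n_hervs - n_driven
  herv_ids <- sprintf("herv_%05d", seq_len(cfg$n_hervs))

  driver_idx <- sample.int(cfg$n_genes, n_driven, replace = n_driven > cfg$n_genes)
  gap <- floor(stats::runif(n_driven, 1e4, 8e5))
  side <- sample(c(-1, 1), n_driven, replace = TRUE)
  h_len <- floor(stats::runif(n_driven, 500, 3000))
  d_start <- ifelse(side > 0, genes$end[driver_idx] + gap,
                    genes$start[driver_idx] - gap - h_len)
  d_start <- pmax(0, d_start)
  driven <- tibble::tibble(
    feature_id = herv_ids[seq_len(n_driven)],
    chrom = genes$chrom[driver_idx],
    start = d_start, end = d_start + h_len,
    driver_gene_id = genes$feature_id[driver_idx])

  i_len <- floor(stats::runif(n_indep, 500, 3000))
  i_start <- floor(stats::runif(n_indep, 0, marker_zone_lo - 1.1e6))
  indep <- tibble::tibble(
    feature_id = herv_ids[n_driven + seq_len(n_indep)],
    chrom = sample(chroms, n_indep, replace = TRUE),
    start = i_start, end = i_start + i_len,
    driver_gene_id = NA_character_)

  cluster_grid <- tidyr::expand_grid(subgroup = cfg$subgroups,
                                     k = seq_len(cfg$n_marker_clusters))
  markers <- purrr::pmap_dfr(
    list(cluster_grid$subgroup, cluster_grid$k, seq_len(n_clusters)),
    function(sg, k, slot) {
      gaps <- floor(stats::runif(cfg$markers_per_cluster, 5e3, 1.5e5))
      lens <- floor(stats::runif(cfg$markers_per_cluster, 500, 3000))
      starts <- anchor[slot] + cumsum(gaps + lens) - lens
      tibble::tibble(
        feature_id = sprintf("herv_m_%s_%02d_%d", sg, k,
                             seq_len(cfg$markers_per_cluster)),
        chrom = chroms[slot_chrom[slot]],
        start = starts, end = starts + lens,
        target_subgroup = sg,
        cluster_id = sprintf("planted_%s_%02d", sg, k))
    })

  loci <- dplyr::bind_rows(
    dplyr::transmute(genes, .data$feature_id, .data$chrom, .data$start,
                     .data$end, score = 0, strand = "+",
                     feature_class = "coding_gene"),
    dplyr::transmute(driven, .data$feature_id, .data$chrom, .data$start,
                     .data$end, score = 0, strand = "+",
                     feature_class = "hervRNA"),
    dplyr::transmute(indep, .data$feature_id, .data$chrom, .data$start,
                     .data$end, score = 0, strand = "+",
                     feature_class = "hervRNA"),
    dplyr::transmute(markers, .data$feature_id, .data$chrom, .data$start,
                     .data$end, score = 0, strand = "+",
                     feature_class = "hervRNA"))
  # alternate strands deterministically so strand-aware promoter logic is
  # exercised
  loci$strand <- rep(c("+", "-"), length.out = nrow(loci))
  validate_loci(loci)

  meth_sub <- if ("Group3" %in% cfg$subgroups) "Group3" else cfg$subgroups[1]
  g3 <- markers$feature_id[markers$target_subgroup == meth_sub]
  n_anti <- round(cfg$meth_frac_anticorrelated * length(g3))
  anti <- if (n_anti > 0) sample(g3, n_anti) else character()

  truth <- dplyr::bind_rows(
    tibble::tibble(herv_id = driven$feature_id, role = "driven",
                   driver_gene_id = driven$driver_gene_id,
                   target_subgroup = NA_character_,
                   cluster_id = NA_character_),
    tibble::tibble(herv_id = indep$feature_id, role = "independent",
                   driver_gene_id = NA_character_,
                   target_subgroup = NA_character_,
                   cluster_id = NA_character_),
    tibble::tibble(herv_id = markers$feature_id, role = "marker",
                   driver_gene_id = NA_character_,
                   target_subgroup = markers$target_subgroup,
                   cluster_id = markers$cluster_id))
  truth$anticorrelated <- truth$herv_id %in% anti
  list(loci = loci, truth = truth)
}

# latent normal correlation needed so that two log-normals with sdlogs
# s1, s2 show Pearson correlation r on the natural scale
copula_rho <- function(r, s1, s2) {
  rho <- log(1 + r * sqrt(expm1(s1^2) * expm1(s2^2))) / (s1 * s2)
  min(rho, 0.999)
}

#' Generate the synthetic expression matrix and sample labels
#'
#' Gene TPM is i.i.d. log-normal; driven hervRNAs share a Gaussian-copula
#' latent factor with their driver gene, calibrated so the TPM-scale
#' Pearson correlation matches `coupling_r`; independent hervRNAs are
#' i.i.d. log-normal at the (much lower) hervRNA level; markers are
#' expressed at the on level with probability `1 - dropout` in their
#' target subgroup and with probability `marker_leak_rate` elsewhere,
#' otherwise at baseline. Deterministic under the config seed.
#'
#' @param cfg a [sim_config()].
#' @param layout output of [simulate_layout()].
#' @return list with `expr` (a [herv_expr]) and `labels` (tibble
#'   `sample_id`, `subgroup`).
#' @export
simulate_expression <- function(cfg, layout) {
  set.seed(cfg$seed + 1L)
  n_per <- rep_len(cfg$n_per_subgroup, length(cfg$subgroups))
  n_s <- sum(n_per)
  labels <- tibble::tibble(
    sample_id = sprintf("s%03d", seq_len(n_s)),
    subgroup = rep(cfg$subgroups, times = n_per))

  loci <- layout$loci
  truth <- layout$truth
  gene_ids <- loci$feature_id[loci$feature_class != "hervRNA"]
  gene_mu <- log(cfg$gene_mean_tpm) - cfg$gene_sdlog^2 / 2
  herv_mu <- log(cfg$herv_mean_tpm) - cfg$herv_sdlog^2 / 2

  z_gene <- matrix(stats::rnorm(length(gene_ids) * n_s), ncol = n_s,
                   dimnames = list(gene_ids, labels$sample_id))
  tpm_gene <- exp(gene_mu + cfg$gene_sdlog * z_gene)

  rho <- copula_rho(cfg$coupling_r, cfg$gene_sdlog, cfg$herv_sdlog)
  drv <- truth[truth$role == "driven", ]
  z_eps <- matrix(stats::rnorm(nrow(drv) * n_s), ncol = n_s)
  z_drv <- rho * z_gene[drv$driver_gene_id, , drop = FALSE] +
    sqrt(1 - rho^2) * z_eps
  tpm_drv <- exp(herv_mu + cfg$herv_sdlog * z_drv)
  rownames(tpm_drv) <- drv$herv_id

  ind <- truth$herv_id[truth$role == "independent"]
  tpm_ind <- matrix(exp(herv_mu + cfg$herv_sdlog *
                          stats::rnorm(length(ind) * n_s)),
                    ncol = n_s, dimnames = list(ind, labels$sample_id))

  mk <- truth[truth$role == "marker", ]
  on_mu <- log(cfg$marker_on_mean_tpm) - cfg$marker_on_sdlog^2 / 2
  base_mu <- log(cfg$marker_baseline_tpm) - cfg$marker_on_sdlog^2 / 2
  in_target <- outer(mk$target_subgroup, labels$subgroup, "==")
  p_on <- ifelse(in_target, 1 - cfg$dropout, cfg$marker_leak_rate)
  on <- matrix(stats::runif(length(p_on)) < p_on, nrow = nrow(mk))
  z_mk <- matrix(stats::rnorm(length(p_on)), nrow = nrow(mk))
  tpm_mk <- exp(ifelse(on, on_mu, base_mu) + cfg$marker_on_sdlog * z_mk)
  dimnames(tpm_mk) <- list(mk$herv_id, labels$sample_id)

  tpm <- rbind(tpm_gene, tpm_drv, tpm_ind, tpm_mk)
  ord <- match(loci$feature_id, rownames(tpm))
  tpm <- tpm[ord, , drop = FALSE]
  classes <- loci$feature_class
  list(expr = herv_expr(tpm, classes), labels = labels)
}

#' Generate synthetic promoter CpG methylation counts
#'
#' CpGs are placed evenly inside the promoter window (TSS +/- 1,000 bp) of
#' every marker hervRNA. For the anticorrelated subset the per-sample
#' promoter beta is generated so its correlation with TPM approximates
#' `meth_target_r`; other promoters get expression-independent betas.
#' Read counts are binomial at a shifted-Poisson coverage with floor 5, so
#' every CpG survives the coverage-across-all-samples filter.
#' Deterministic under the config seed.
#'
#' @param cfg a [sim_config()].
#' @param layout output of [simulate_layout()].
#' @param sim_expr output of [simulate_expression()].
#' @return a methylation tibble (`chrom`, `pos`, `sample_id`, `meth_reads`,
#'   `total_reads`).
#' @export
simulate_methylation <- function(cfg, layout, sim_expr) {
  set.seed(cfg$seed + 2L)
  truth <- layout$truth
  mk_ids <- truth$herv_id[truth$role == "marker"]
  loci_mk <- layout$loci[layout$loci$feature_id %in% mk_ids, , drop = FALSE]
  prom <- promoter_regions(loci_mk, flank_bp = 1000)
  tpm <- sim_expr$expr$tpm
  samples <- colnames(tpm)
  n_s <- length(samples)
  rho <- abs(cfg$meth_target_r)

  purrr::map_dfr(seq_len(nrow(prom)), function(i) {
    hid <- prom$herv_id[i]
    anti <- truth$anticorrelated[truth$herv_id == hid]
    if (anti) {
      t <- tpm[hid, ]
      s <- (t - mean(t)) / stats::sd(t)
      beta_s <- 0.5 + 0.25 * (-rho * s +
                                sqrt(1 - rho^2) * stats::rnorm(n_s))
    } else {
      beta_s <- stats::runif(1, 0.3, 0.8) + stats::rnorm(n_s, 0, 0.08)
    }
    beta_s <- pmin(pmax(beta_s, 0.02), 0.98)
    pos <- floor(seq(prom$start[i] + 100, prom$end[i] - 100,
                     length.out = cfg$cpgs_per_promoter))
    purrr::map_dfr(seq_along(pos), function(j) {
      beta_cpg <- pmin(pmax(beta_s + stats::rnorm(n_s, 0, 0.03), 0.01), 0.99)
      cov <- 5 + stats::rpois(n_s, cfg$meth_coverage_mean - 5)
      tibble::tibble(chrom = prom$chrom[i], pos = pos[j],
                     sample_id = samples,
                     meth_reads = stats::rbinom(n_s, cov, beta_cpg),
                     total_reads = cov)
    })
  })
}

#' Simulate a complete synthetic cohort
#'
#' Runs [simulate_layout()], [simulate_expression()] and
#' [simulate_methylation()] with the per-stage seeds derived from
#' `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param methylation generate the methylation table too (default `TRUE`;
#'   skipping it saves time when only expression is needed).
#' @return list of class `herv_cohort`: `config`, `loci`, `truth`, `expr`,
#'   `labels`, `meth`.
#' @export
simulate_cohort <- function(cfg, methylation = TRUE) {
  layout <- simulate_layout(cfg)
  se <- simulate_expression(cfg, layout)
  meth <- if (methylation) simulate_methylation(cfg, layout, se) else NULL
  structure(list(config = cfg, loci = layout$loci, truth = layout$truth,
                 expr = se$expr, labels = se$labels, meth = meth),
            class = "herv_cohort")
}

#' @export
print.herv_cohort <- function(x, ...) {
  cat("<herv_cohort> seed ", x$config$seed, ": ",
      nrow(x$expr$tpm), " features x ", ncol(x$expr$tpm), " samples",
      if (!is.null(x$meth)) paste0(", ", nrow(x$meth), " CpG records"),
      "\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits the expression TSV, class sidecar, BED6 loci, labels TSV,
#' methylation TSV, ground-truth JSON, and a manifest JSON holding the
#' config, seed and an md5 checksum per file. Regenerating with the
#' manifest's seed reproduces the checksums.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param outdir output directory (created if missing).
#' @param force overwrite a non-empty directory (default `FALSE`).
#' @return tibble manifest (`file`, `md5`), invisibly; also written as
#'   `manifest.json`.
#' @export
write_dataset <- function(cohort, outdir, force = FALSE) {
  if (dir.exists(outdir) && length(dir(outdir)) > 0 && !force) {
    stop("output directory is not empty (use force = TRUE): ", outdir,
         call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = "expression.tsv", classes = "classes.tsv",
             loci = "loci.bed", labels = "labels.tsv",
             methylation = "methylation.tsv", truth = "truth.json")
  fp <- function(x) file.path(outdir, paths[[x]])
  write_expression_matrix(cohort$expr, fp("expression"), fp("classes"))
  write_loci_bed(cohort$loci, fp("loci"))
  write_sample_labels(cohort$labels, fp("labels"))
  written <- paths[c("expression", "classes", "loci", "labels")]
  if (!is.null(cohort$meth)) {
    write_methylation_table(cohort$meth, fp("methylation"))
    written <- c(written, paths["methylation"])
  }
  jsonlite::write_json(cohort$truth, fp("truth"), auto_unbox = FALSE,
                       digits = NA, na = "null")
  written <- c(written, paths["truth"])
  md5 <- tools::md5sum(file.path(outdir, written))
  manifest <- tibble::tibble(file = unname(written), md5 = unname(md5))
  jsonlite::write_json(
    list(seed = cohort$config$seed,
         config = unclass(cohort$config),
         files = manifest),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
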