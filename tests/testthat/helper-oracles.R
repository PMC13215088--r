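# Independent brute-force oracles used to cross-check the package's
# primitives, plus tiny fixture builders. Oracles deliberately use the
# dumbest correct formulation available.

# bases strictly between two 0-based half-open intervals, by enumerating
# integer positions (0 on overlap or touch)
oracle_gap <- function(s1, e1, s2, e2) {
  a <- s1:(e1 - 1)
  b <- s2:(e2 - 1)
  if (length(intersect(a, b)) > 0) return(0)
  between <- setdiff(seq(min(c(a, b)), max(c(a, b))), c(a, b))
  length(between)
}

# all-pairs neighbor scan over a loci tibble
oracle_neighbor_pairs <- function(loci, window_bp) {
  hervs <- loci[loci$feature_class == "hervRNA", ]
  genes <- loci[loci$feature_class != "hervRNA", ]
  out <- list()
  for (i in seq_len(nrow(hervs))) {
    for (j in seq_len(nrow(genes))) {
      if (hervs$chrom[i] != genes$chrom[j]) next
      g <- oracle_gap(hervs$start[i], hervs$end[i],
                      genes$start[j], genes$end[j])
      if (g <= window_bp) {
        out[[length(out) + 1]] <- tibble::tibble(
          herv_id = hervs$feature_id[i], gene_id = genes$feature_id[j],
          gap_bp = g)
      }
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(herv_id = character(), gene_id = character(),
                          gap_bp = numeric()))
  }
  dplyr::arrange(res, herv_id, gene_id)
}

# exact one-sided signed-rank p by enumerating every sign assignment
oracle_signed_rank_p <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  w_all <- vapply(0:(2^m - 1), function(mask) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(m - 1)), 1L) == 1L
    sum(r[signs])
  }, numeric(1))
  mean(w_all >= w_obs)
}

# connected components of the pairwise gap <= g relation, by iterated
# expansion (transitive closure)
oracle_cluster_partition <- function(loci, gap_bp) {
  n <- nrow(loci)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      same <- loci$chrom[i] == loci$chrom[j] &&
        loci$target_subgroup[i] == loci$target_subgroup[j]
      if (same && oracle_gap(loci$start[i], loci$end[i],
                             loci$start[j], loci$end[j]) <= gap_bp) {
        adj[i, j] <- TRUE
      }
    }
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (adj[i, j] && comp[j] != comp[i]) {
          new <- min(comp[i], comp[j])
          comp[comp == comp[i] | comp == comp[j]] <- new
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  split(loci$herv_id, comp)
}

# partition as a canonical set of member-sets for comparison
partition_sets <- function(ids, groups) {
  unname(sort(vapply(split(ids, groups), function(v)
    paste(sort(v), collapse = "|"), character(1))))
}

# small expression fixture: explicit matrix + classes
tiny_expr <- function(tpm = NULL) {
  if (is.null(tpm)) {
    tpm <- matrix(c(2, 0.5, 10, 12, 0.1, 0.2), nrow = 3, byrow = TRUE,
                  dimnames = list(c("h1", "h2", "g1"), c("sA", "sB")))
  }
  herv_expr(tpm, ifelse(startsWith(rownames(tpm), "h"), "hervRNA",
                        "coding_gene"))
}

# random loci layout on a couple of chromosomes
random_loci <- function(n, max_pos = 5e6, chroms = c("chr1", "chr2"),
                        herv_frac = 0.5) {
  start <- floor(runif(n, 0, max_pos))
  len <- floor(runif(n, 100, 5000))
  tibble::tibble(
    feature_id = sprintf("f%03d", seq_len(n)),
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + len, score = 0,
    strand = sample(c("+", "-"), n, replace = TRUE),
    feature_class = ifelse(runif(n) < herv_frac, "hervRNA", "coding_gene"))
}

# labelled 4-subgroup cohort with one perfectly specific marker per group
planted_marker_expr <- function(n_per = 5, on_tpm = 12, off_tpm = 0.2) {
  groups <- c("WNT", "SHH", "Group3", "Group4")
  labels <- tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(n_per * 4)),
    subgroup = rep(groups, each = n_per))
  tpm <- do.call(rbind, lapply(groups, function(g) {
    ifelse(labels$subgroup == g, on_tpm, off_tpm)
  }))
  rownames(tpm) <- paste0("mk_", groups)
  colnames(tpm) <- labels$sample_id
  list(expr = herv_expr(tpm, rep("hervRNA", 4)), labels = labels)
}
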