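#' Cluster-based Monte Carlo permutation test of group differences
#'
#' Tests whether two groups of participants differ anywhere on the face
#' template while controlling the family-wise error over all pixels. The
#' observed pixelwise t-map is thresholded at the cluster-forming critical
#' value (two-sided p = `config$cluster_forming_p`) and supra-threshold
#' clusters are formed per sign. The null distribution of the maximal cluster
#' statistic is approximated by Monte Carlo: on each iteration the
#' whole-participant group labels are randomly re-assigned (preserving group
#' sizes), the permuted t-map is thresholded identically, and the maximum
#' cluster statistic pooled over both signs is recorded. Each observed
#' cluster's p-value is `(b + 1) / (m + 1)` with `b` the number of
#' permutation maxima at least as large as the observed statistic — the
#' add-one correction keeps p-values strictly positive — and the cluster is
#' flagged significant when `p < config$cluster_alpha`.
#'
#' @param maps a named list of `density_map`s, or a participants x pixels
#'   matrix with a `map_dim` attribute; missing maps are dropped.
#' @param groups group label per map (factor or character, two levels),
#'   aligned with `maps`.
#' @param config an [analysis_config()]; `n_permutations`,
#'   `cluster_forming_p`, `cluster_alpha`, `connectivity` and
#'   `cluster_statistic` are honoured. `config$rng_seed`, when set, seeds the
#'   permutation stream.
#' @param exhaustive enumerate every group relabelling instead of Monte Carlo
#'   sampling (feasible only for small cohorts); p-values are then exact
#'   proportions over all relabellings.
#' @return a list: `clusters` (tibble with `id`, `sign`, `size`, `mass`,
#'   `stat`, `p`, `significant`), `labels` (cluster-id matrix), `t_map`,
#'   `t_crit`, `null_max` (permutation distribution of the maximal cluster
#'   statistic), `n_permutations`.
#' @export
permutation_test <- function(maps, groups, config = analysis_config(),
                             exhaustive = FALSE) {
  if (is.list(maps)) {
    keep <- !vapply(maps, function(m) isTRUE(attr(m, "missing")), logical(1))
    groups <- groups[keep]
    M <- maps_to_matrix(maps)
  } else {
    M <- maps
  }
  d <- attr(M, "map_dim")
  if (is.null(d)) stop_dyad("invalid-argument", "maps matrix needs a map_dim attribute")
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop_dyad("invalid-argument", "exactly two groups required")
  nA <- sum(groups == levels(groups)[1])
  nB <- sum(groups == levels(groups)[2])
  if (nA < 2 || nB < 2) {
    stop_dyad("insufficient-data", "need at least 2 participants per group")
  }
  n <- nA + nB
  df <- n - 2
  t_crit <- qt(1 - config$cluster_forming_p / 2, df)
  idxA_obs <- which(groups == levels(groups)[1])

  M2 <- M^2
  S <- colSums(M)
  Q <- colSums(M2)
  t_for <- function(idxA) {
    sel <- numeric(n)
    sel[idxA] <- 1
    SA <- drop(sel %*% M)
    QA <- drop(sel %*% M2)
    t_from_sums(SA, QA, nA, S - SA, Q - QA, nB)
  }
  t_obs <- t_for(idxA_obs)
  t_map <- matrix(t_obs, d[1], d[2])
  cl <- find_clusters(t_map, t_crit, config)

  use_mass <- config$cluster_statistic == "mass"
  max_stat <- function(tv) {
    .max_cluster_stat(matrix(tv, d[1], d[2]), t_crit, config$connectivity, use_mass)
  }
  if (exhaustive) {
    splits <- utils::combn(n, nA)
    null_max <- apply(splits, 2, function(idx) max_stat(t_for(idx)))
    m <- length(null_max)
    p_of <- function(s) sum(null_max >= s - 1e-9) / m
  } else {
    if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
    B <- config$n_permutations
    null_max <- numeric(B)
    # batches of relabellings share one BLAS multiply for the group sums
    chunk <- 128L
    b0 <- 0L
    while (b0 < B) {
      bs <- min(chunk, B - b0)
      SEL <- matrix(0, n, bs)
      for (j in seq_len(bs)) SEL[sample.int(n, nA), j] <- 1
      SA <- crossprod(SEL, M)
      QA <- crossprod(SEL, M2)
      for (j in seq_len(bs)) {
        tv <- t_from_sums(SA[j, ], QA[j, ], nA, S - SA[j, ], Q - QA[j, ], nB)
        null_max[b0 + j] <- max_stat(tv)
      }
      b0 <- b0 + bs
    }
    p_of <- function(s) (sum(null_max >= s - 1e-9) + 1) / (B + 1)
  }
  if (nrow(cl$clusters)) {
    cl$clusters$p <- vapply(cl$clusters$stat, p_of, numeric(1))
    cl$clusters$significant <- cl$clusters$p < config$cluster_alpha
  } else {
    cl$clusters$p <- numeric(0)
    cl$clusters$significant <- logical(0)
  }
  list(clusters = cl$clusters, labels = cl$labels, t_map = t_map,
       t_crit = t_crit, null_max = null_max,
       n_permutations = length(null_max))
}

#' Significance mask of a permutation-test result
#'
#' @param result a [permutation_test()] result.
#' @return an integer matrix: +1 over significant positive clusters, -1 over
#'   significant negative clusters, 0 elsewhere.
#' @export
significance_mask <- function(result) {
  mask <- matrix(0L, nrow(result$labels), ncol(result$labels))
  sig <- result$clusters[result$clusters$significant, , drop = FALSE]
  for (id in sig$id) {
    mask[result$labels == id] <- ifelse(id > 0, 1L, -1L)
  }
  mask
}
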