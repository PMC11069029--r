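# Second-level between-group statistics: Wilcoxon rank-sum maps over
# per-subject contrast maps, corrected by cluster-based permutation testing
# with the maximum cluster-mass statistic.

#' Wilcoxon rank-sum Z for two groups
#'
#' Mann-Whitney statistic with midrank ties and tie-corrected variance,
#' converted to a normal Z without continuity correction; positive Z means
#' `group_a` is stochastically larger.  `exact = TRUE` replaces the normal
#' two-sided p by full enumeration of all group labelings (feasible for
#' small samples), using the two-sided tail
#' `P(|U - nm/2| >= |u_obs - nm/2|)`.
#'
#' @param group_a,group_b numeric vectors (each length >= 2).
#' @param exact logical; enumerate all labelings for the p-value.
#' @return list with `z`, `p` (two-sided), `u` (Mann-Whitney U of group A).
#' @examples
#' ranksum_z(c(1, 2, 3), c(4, 5, 6))          # z = -1.964
#' ranksum_z(c(1, 2, 3), c(4, 5, 6), exact = TRUE)$p  # 2/20 = 0.1
#' @export
ranksum_z <- function(group_a, group_b, exact = FALSE) {
  n <- length(group_a); m <- length(group_b)
  if (n < 2 || m < 2) stop_param("each group needs at least 2 values")
  x <- c(group_a, group_b)
  res <- ranksum_z_sites(matrix(x, ncol = 1),
                         c(rep(TRUE, n), rep(FALSE, m)))
  r <- rank(x)
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  out <- list(z = res$z[1], p = res$p[1], u = u)
  if (exact) {
    N <- n + m
    if (choose(N, n) > 2e5)
      stop_param("exact enumeration infeasible for these group sizes")
    mu <- n * m / 2
    dev <- abs(u - mu)
    combs <- combn(N, n)
    devs <- apply(combs, 2, function(idx)
      abs(sum(r[idx]) - n * (n + 1) / 2 - mu))
    out$p <- mean(devs >= dev - 1e-12)
  }
  out
}

#' Threshold a site-statistic map into a signed binary map
#'
#' Sites with uncorrected `p < alpha` get the sign of their Z; edge-masked
#' (invalid) sites are always 0.  This is the cluster-threshold-detection
#' (CTD) step that seeds clusters.
#'
#' @param z,p numeric arrays of site Z values and two-sided p-values.
#' @param alpha CTD threshold (default 0.05).
#' @param valid logical array of usable sites (default: all).
#' @return integer array in \{-1, 0, 1\} with the shape of `z`.
#' @export
threshold_map <- function(z, p, alpha = 0.05, valid = NULL) {
  out <- sign(z)
  out[!(p < alpha)] <- 0L
  if (!is.null(valid)) out[!valid] <- 0L
  storage.mode(out) <- "integer"
  if (!is.null(dim(z))) dim(out) <- dim(z)
  out
}

#' Find signed clusters on the channel x frequency x time grid
#'
#' Connected components of same-signed suprathreshold sites.  Connectivity
#' is 4-neighbor in each channel's frequency x time chart plus (unless
#' `tf_only`) links between the same (f, t) cell on neighboring channels.
#' Cluster mass is the sum of member Z values; clusters are returned sorted
#' by decreasing |mass|.
#'
#' @param signed_map integer array `[channel, freq, time]` in \{-1, 0, 1\}.
#' @param zmap numeric array of the same shape.
#' @param neighbors channel adjacency: list (per channel, integer indices or
#'   labels) as from [channel_neighbors()].
#' @param channels channel labels corresponding to the array's first axis.
#' @param tf_only cluster within channels only.
#' @return list of clusters, each with `sign`, `mass`, `n_sites`, and
#'   `sites` (matrix of channel/freq/time indices).
#' @export
find_clusters <- function(signed_map, zmap, neighbors, channels = NULL,
                          tf_only = FALSE) {
  d <- dim(signed_map)
  stopifnot(length(d) == 3, all(dim(zmap) == d))
  nb <- neighbors_to_indices(neighbors, channels, d[1])
  res <- find_clusters_cpp(as.integer(signed_map), as.numeric(zmap),
                           d[1], d[2], d[3], nb, tf_only)
  build_cluster_list(res, d)
}

neighbors_to_indices <- function(neighbors, channels, nch) {
  if (is.null(neighbors)) return(rep(list(integer(0)), nch))
  if (is.null(channels)) channels <- names(neighbors)
  stopifnot(length(channels) == nch)
  lapply(channels, function(ch) {
    nbs <- neighbors[[ch]] %||% character(0)
    if (is.character(nbs)) {
      idx <- match(nbs, channels)
      as.integer(idx[!is.na(idx)])
    } else as.integer(nbs)
  })
}

build_cluster_list <- function(res, d) {
  k <- length(res$mass)
  if (!k) return(list())
  clusters <- lapply(seq_len(k), function(i) {
    sites <- which(res$label == i)
    s0 <- sites - 1L
    ch <- s0 %% d[1]
    f <- (s0 %/% d[1]) %% d[2]
    t <- s0 %/% (d[1] * d[2])
    list(sign = res$sign[i], mass = res$mass[i], n_sites = length(sites),
         sites = cbind(channel = ch + 1L, freq = f + 1L, time = t + 1L),
         site_index = sites)
  })
  clusters[order(-abs(vapply(clusters, `[[`, 0, "mass")))]
}

#' Cluster-based permutation test of a group difference
#'
#' Observed clusters are formed from the true group labels (rank-sum Z per
#' site, CTD threshold `alpha_ctd`, connected components, mass = summed Z).
#' Each of `n_perm` permutations shuffles the group labels, rebuilds the
#' map and clusters, and records the maximum |mass|; the cluster p-value is
#' the proportion of the permutation distribution at or above the observed
#' |mass| (set `strict = TRUE` for the strictly-greater proportion, or
#' `plus_one = TRUE` for the (b+1)/(n+1) estimator).
#'
#' @param contrasts numeric array `[subject, channel, freq, time]` of
#'   per-subject contrast maps.
#' @param labels group label per subject (2 levels; first level = group A).
#' @param n_perm number of label permutations (default 1000).
#' @param alpha_ctd site threshold (default 0.05).
#' @param neighbors channel adjacency list (labels), or `NULL` for no
#'   cross-channel links.
#' @param channels channel labels of the array's channel axis.
#' @param valid logical `[freq, time]` or `[channel, freq, time]` validity
#'   mask; invalid sites never enter clusters.
#' @param tf_only restrict clustering to each sensor's time-frequency chart.
#' @param strict,plus_one p-value conventions (see above).
#' @param seed integer seed for the permutation draws.
#' @return object of class `cluster_result`: `clusters` data.frame (`sign`,
#'   `mass`, `n_sites`, `p_cluster`), `members` (per-cluster site index
#'   matrices), `z`/`p_uncorrected` site maps, `perm_max` distribution, and
#'   the test's parameters.
#' @export
permutation_test <- function(contrasts, labels, n_perm = 1000,
                             alpha_ctd = 0.05, neighbors = NULL,
                             channels = NULL, valid = NULL, tf_only = FALSE,
                             strict = FALSE, plus_one = FALSE, seed = NULL) {
  d <- dim(contrasts)
  stopifnot(length(d) == 4)
  n_perm <- assert_count(n_perm, "n_perm")
  labels <- as.factor(labels)
  if (nlevels(labels) != 2 || min(table(labels)) < 2)
    stop_param("need two groups with >= 2 subjects each")
  in_a <- labels == levels(labels)[1]
  nsite <- prod(d[2:4])
  X <- matrix(contrasts, nrow = d[1])
  vmask <- rep(TRUE, nsite)
  if (!is.null(valid)) {
    if (length(dim(valid)) == 2) {
      # [freq, time] mask replicated across the channel axis
      vmask <- rep(as.vector(valid), each = d[2])
    } else vmask <- as.vector(valid)
  }
  vmask <- vmask & !apply(is.na(X), 2, any)
  X[is.na(X)] <- 0
  nb <- neighbors_to_indices(neighbors, channels, d[2])
  res <- with_seed(seed,
    perm_cluster_cpp(X, vmask, in_a, alpha_ctd, n_perm,
                     d[2], d[3], d[4], nb, tf_only))
  clusters <- build_cluster_list(res, d[2:4])
  pvals <- vapply(clusters, function(cl) {
    b <- if (strict) sum(res$perm_max > abs(cl$mass))
         else sum(res$perm_max >= abs(cl$mass))
    if (plus_one) (b + 1) / (n_perm + 1) else b / n_perm
  }, numeric(1))
  tab <- data.frame(
    cluster = seq_along(clusters),
    sign = vapply(clusters, `[[`, 0, "sign"),
    mass = vapply(clusters, `[[`, 0, "mass"),
    n_sites = vapply(clusters, `[[`, 0L, "n_sites"),
    p_cluster = pvals)
  structure(list(clusters = tab, members = lapply(clusters, `[[`, "sites"),
                 z = array(res$z, d[2:4]),
                 p_uncorrected = array(res$p, d[2:4]),
                 perm_max = res$perm_max, alpha_ctd = alpha_ctd,
                 n_perm = n_perm, channels = channels,
                 group_a = levels(labels)[1], tf_only = tf_only),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), %d permutations, CTD alpha %g\n",
              nrow(x$clusters), x$n_perm, x$alpha_ctd))
  if (nrow(x$clusters)) print(head(x$clusters, 10))
  invisible(x)
}

#' Serialize a cluster result to JSON
#'
#' Cluster site lists are written as (channel, freq, time) index triples.
#' @param result a `cluster_result`.
#' @param path output path.
#' @export
write_cluster_json <- function(result, path) {
  out <- list(
    alpha_ctd = result$alpha_ctd, n_perm = result$n_perm,
    group_a = result$group_a,
    clusters = lapply(seq_len(nrow(result$clusters)), function(i) {
      list(sign = result$clusters$sign[i], mass = result$clusters$mass[i],
           p_cluster = result$clusters$p_cluster[i],
           sites = unname(apply(result$members[[i]], 1, as.list)))
    }),
    perm_max = result$perm_max)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
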