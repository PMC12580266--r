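#' Z-score group-mean expression profiles
#'
#' Builds one profile per gene over the design's group means (one value per
#' group, the usual x-axis of cluster trend plots), then centers and scales
#' each gene to mean 0 / SD 1. Genes with zero SD across groups get an
#' all-zero profile and are flagged; clustering should exclude them.
#'
#' @param expr an [expression_matrix()] (normalized values recommended).
#' @param design a [cross_design()].
#' @param by "group_mean" (default) or "sample" (z-score over replicate-level
#'   values instead of group means).
#' @return list: `profiles` (genes x groups or genes x samples matrix),
#'   `flagged` (character vector of constant genes).
#' @export
standardize_profiles <- function(expr, design, by = c("group_mean",
                                                      "sample")) {
  by <- match.arg(by)
  m <- unclass(as.matrix(expr))
  if (by == "group_mean") {
    prof <- vapply(design$groups$group, function(g)
      rowMeans(m[, replicates_of(design, g), drop = FALSE]),
      numeric(nrow(m)))
  } else {
    prof <- m[, design$samples$sample, drop = FALSE]
  }
  mu <- rowMeans(prof)
  sd <- apply(prof, 1, stats::sd)
  flagged <- rownames(prof)[sd == 0]
  z <- (prof - mu) / ifelse(sd == 0, 1, sd)
  z[sd == 0, ] <- 0
  list(profiles = z, flagged = flagged)
}

# squared Euclidean distances, n x k
dist2 <- function(x, centers) {
  outer(rowSums(x^2), rep(1, nrow(centers))) -
    2 * x %*% t(centers) +
    outer(rep(1, nrow(x)), rowSums(centers^2))
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  idx <- sample.int(n, 1L)
  for (j in seq_len(k - 1L)) {
    d2 <- apply(dist2(x, x[idx, , drop = FALSE]), 1, min)
    d2[idx] <- 0
    if (sum(d2) == 0) {
      cand <- setdiff(seq_len(n), idx)
      idx <- c(idx, cand[sample.int(length(cand), 1L)])
    } else {
      idx <- c(idx, sample.int(n, 1L, prob = d2 / sum(d2)))
    }
  }
  x[idx, , drop = FALSE]
}

#' Fuzzy c-means clustering
#'
#' Standard fuzzy c-means with Euclidean distances and k-means++-style
#' seeded initialization: memberships
#' `u_ij = 1 / sum_k (d_ij / d_ik)^(2/(m-1))`, centers the u^m-weighted
#' means, alternated until the largest membership change drops below `tol`.
#' A point at exactly zero distance from a center takes membership 1 there
#' (split equally if several centers coincide with it). The objective
#' `sum u^m d^2` is recorded per iteration and is non-increasing.
#'
#' @param profiles numeric matrix (points x features).
#' @param c number of clusters.
#' @param m fuzzification parameter (> 1); 2 is the field's convention.
#' @param seed integer seed for the initialization.
#' @param tol convergence tolerance on memberships.
#' @param max_iter iteration cap.
#' @return list of class `fcm_model`: `centers` (c x features),
#'   `membership` (points x c, rows sum to 1), `m`, `objective`
#'   (per-iteration values), `iterations`.
#' @export
fuzzy_cmeans <- function(profiles, c = 5L, m = 2, seed = 1L,
                         tol = 1e-6, max_iter = 500L) {
  x <- as.matrix(profiles)
  if (c < 1L) stop("c must be >= 1")
  if (m <= 1) stop("fuzzification parameter m must exceed 1")
  if (nrow(unique(x)) < c)
    stop("fewer distinct profiles (", nrow(unique(x)),
         ") than clusters (", c, ")")
  set.seed(seed)
  centers <- kmeanspp_init(unique(x), c)
  memb_from <- function(centers) {
    d2 <- pmax(dist2(x, centers), 0)
    u <- matrix(0, nrow(x), c)
    zero <- d2 < 1e-300
    hz <- rowSums(zero) > 0
    if (any(hz)) u[hz, ] <- zero[hz, , drop = FALSE] /
        rowSums(zero[hz, , drop = FALSE])
    if (any(!hz)) {
      w <- d2[!hz, , drop = FALSE]^(-1 / (m - 1))
      u[!hz, ] <- w / rowSums(w)
    }
    list(u = u, d2 = d2)
  }
  st <- memb_from(centers)
  obj <- sum(st$u^m * st$d2)
  it <- 0L
  repeat {
    it <- it + 1L
    um <- st$u^m
    centers <- (t(um) %*% x) / colSums(um)
    new <- memb_from(centers)
    obj <- c(obj, sum(new$u^m * new$d2))
    delta <- max(abs(new$u - st$u))
    st <- new
    if (delta < tol || it >= max_iter) break
  }
  rownames(st$u) <- rownames(x)
  structure(list(centers = centers, membership = st$u, m = m,
                 objective = obj, iterations = it), class = "fcm_model")
}

#' Assign genes to clusters by membership threshold
#'
#' A gene is assigned to its argmax-membership cluster only when that
#' membership is at least `threshold` (the conventional 0.7); otherwise it
#' is left unassigned (NA).
#'
#' @param model an `fcm_model` from [fuzzy_cmeans()].
#' @param threshold minimum membership for assignment.
#' @return integer vector (cluster index or NA), named by gene.
#' @export
assign_members <- function(model, threshold = 0.7) {
  u <- model$membership
  best <- max.col(u, ties.method = "first")
  top <- u[cbind(seq_len(nrow(u)), best)]
  out <- ifelse(top >= threshold, best, NA_integer_)
  names(out) <- rownames(u)
  out
}

#' The cluster peaking in a given group
#'
#' Picks the cluster whose center attains its maximum at `group`'s profile
#' position — e.g. the cluster highest in the paternal-excess triploids.
#' If several qualify, the one with the largest center value there wins.
#'
#' @param model an `fcm_model` whose centers' columns are design groups.
#' @param group group (column) label.
#' @return integer cluster index, or NA if no center peaks at `group`.
#' @export
peak_cluster <- function(model, group) {
  ctr <- model$centers
  j <- match(group, colnames(ctr))
  if (is.na(j)) stop("group not a profile column: ", group)
  peaks <- max.col(ctr, ties.method = "first") == j
  if (!any(peaks)) return(NA_integer_)
  which(peaks)[which.max(ctr[peaks, j])]
}

#' K-means sub-clustering
#'
#' Lloyd's algorithm via [stats::kmeans()], best of `n_init` seeded restarts
#' by within-cluster sum of squares.
#'
#' @param profiles numeric matrix (points x features).
#' @param k number of sub-clusters.
#' @param seed integer seed.
#' @param n_init random restarts.
#' @return list: `labels` (integer vector named by point), `tot_withinss`,
#'   `centers`.
#' @export
kmeans_subcluster <- function(profiles, k = 10L, seed = 1L, n_init = 10L) {
  x <- as.matrix(profiles)
  if (nrow(unique(x)) < k)
    stop("fewer distinct points than sub-clusters")
  set.seed(seed)
  km <- suppressWarnings(
    stats::kmeans(x, centers = k, nstart = n_init,
                  algorithm = "Lloyd", iter.max = 200L))
  labels <- km$cluster
  names(labels) <- rownames(x)
  list(labels = labels, tot_withinss = km$tot.withinss,
       centers = km$centers)
}
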