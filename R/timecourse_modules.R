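#' Row Z-score standardization
#'
#' Subtracts the row mean and divides by the row sample SD. Constant rows
#' (SD 0 or undefined) are set to all-zero and flagged.
#'
#' @param m numeric matrix with at least 2 columns.
#' @return list with `matrix` (standardized) and `constant` (logical flag
#'   per row).
#' @export
zscore_rows <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) stop("need at least 2 columns")
  mu <- rowMeans(m)
  s <- apply(m, 1, stats::sd)
  constant <- !is.finite(s) | s == 0
  z <- (m - mu) / ifelse(constant, 1, s)
  z[constant, ] <- 0
  list(matrix = z, constant = constant)
}

# k-means++ center seeding (Arthur & Vassilvitskii)
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- sample.int(n, 1L, prob = prob)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

#' Cluster time-course profiles into modules by k-means
#'
#' Euclidean k-means with k-means++ seeding, `restarts` independent starts
#' keeping the solution with the lowest total within-cluster sum of
#' squares. Deterministic given `seed`.
#'
#' @param z numeric matrix (typically row Z-scores), features x time points.
#' @param k number of modules (>= 2, <= rows).
#' @param seed integer seed.
#' @param restarts independent k-means++ starts (default 10).
#' @return object of class `module_assignment`: list with `cluster` (named
#'   integer vector), `centroids` (k x time points), `inertia`, `k`.
#' @export
cluster_modules <- function(z, k, seed = 1L, restarts = 10L) {
  z <- as.matrix(z)
  if (k < 2L) stop("k must be >= 2")
  if (k > nrow(z)) stop("k (", k, ") exceeds number of rows (", nrow(z), ")")
  best <- NULL
  with_seed(derive_seed(seed, "kmeans"), {
    for (r in seq_len(restarts)) {
      cen <- kmeanspp_centers(z, k)
      km <- suppressWarnings(
        stats::kmeans(z, centers = cen, iter.max = 100L,
                      algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  out <- list(cluster = stats::setNames(best$cluster, rownames(z)),
              centroids = best$centers, inertia = best$tot.withinss,
              k = k)
  class(out) <- "module_assignment"
  out
}

#' Default time-point to differentiation-stage map
#'
#' First time point is pre-adipocyte (PA), last is mature adipocyte (MA),
#' everything in between is clonal expansion (CE).
#'
#' @param time_points character vector of time-point labels.
#' @return named character vector, time point -> stage.
#' @export
default_stage_map <- function(time_points) {
  stage <- rep("CE", length(time_points))
  stage[1] <- "PA"
  stage[length(stage)] <- "MA"
  stats::setNames(stage, time_points)
}

#' Assign a differentiation stage to a module centroid
#'
#' The stage whose time points have the highest mean centroid value wins;
#' exact ties are broken in the order PA > CE > MA with a warning.
#'
#' @param centroid numeric vector named by time point (or in the order of
#'   `names(stage_map)`).
#' @param stage_map named character vector, time point -> stage in
#'   PA/CE/MA (see [default_stage_map()]).
#' @return single character stage label.
#' @export
assign_stage <- function(centroid, stage_map) {
  tps <- names(stage_map)
  if (is.null(names(centroid))) names(centroid) <- tps
  if (!all(names(centroid) %in% tps)) {
    stop("unmapped time point(s): ",
         paste(setdiff(names(centroid), tps), collapse = ", "))
  }
  stages <- c("PA", "CE", "MA")
  means <- vapply(stages, function(s) {
    cols <- tps[stage_map == s]
    if (length(cols) == 0L) return(-Inf)
    mean(centroid[cols])
  }, numeric(1))
  top <- which(means == max(means))
  if (length(top) > 1L) {
    warning("stage tie (", paste(stages[top], collapse = ", "),
            "); broken in PA > CE > MA order")
  }
  stages[top[1L]]
}

#' Assign stages to every module of a clustering
#' @param assignment a `module_assignment` from [cluster_modules()].
#' @param stage_map named time point -> stage map.
#' @return the assignment with added `module_stage` (per module) and
#'   `stage` (per feature) elements.
#' @export
assign_stages <- function(assignment, stage_map) {
  ms <- apply(assignment$centroids, 1, assign_stage, stage_map = stage_map)
  assignment$module_stage <- ms
  assignment$stage <- stats::setNames(ms[assignment$cluster],
                                      names(assignment$cluster))
  assignment
}

#' Per-feature Pearson correlation between two time-course datasets
#'
#' Computes a standard Pearson r for each feature between its profiles in
#' the two matrices (matched rows and columns, at least 3 shared time
#' points) and a 10-bin histogram of r over \[-1, 1\] (equal-width,
#' right-closed, r = -1 in the lowest bin). Features with zero variance in
#' either profile have undefined r: they are excluded from the bins and
#' counted separately.
#'
#' @param a,b numeric matrices with identical rownames and >= 3 shared
#'   columns (time points).
#' @return list with `r` (named vector, NA where undefined), `bins`
#'   (named integer vector of 10 bin counts) and `n_undefined`.
#' @export
profile_correlation <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  feats <- intersect(rownames(a), rownames(b))
  cols <- intersect(colnames(a), colnames(b))
  if (length(cols) < 3L) stop("need at least 3 matched time points")
  a <- a[feats, cols, drop = FALSE]; b <- b[feats, cols, drop = FALSE]
  r <- vapply(seq_along(feats), function(i) {
    if (stats::sd(a[i, ]) == 0 || stats::sd(b[i, ]) == 0) NA_real_
    else stats::cor(a[i, ], b[i, ])
  }, numeric(1))
  names(r) <- feats
  brk <- seq(-1, 1, length.out = 11L)
  bins <- table(cut(r[!is.na(r)], breaks = brk, include.lowest = TRUE,
                    right = TRUE))
  list(r = r, bins = stats::setNames(as.integer(bins), names(bins)),
       n_undefined = sum(is.na(r)))
}

#' Upper-tail hypergeometric overrepresentation p-value
#'
#' P(X >= k) for X ~ Hypergeometric(N, n, m): the probability of drawing at
#' least `k` members of a size-`m` set when sampling `n` items without
#' replacement from a universe of `N`.
#'
#' @param k observed overlap.
#' @param n size of set A (the draw).
#' @param m size of set B (the marked items).
#' @param N universe size.
#' @return p-value.
#' @export
hypergeom_overrep <- function(k, n, m, N) {
  if (k < 0 || n < 0 || m < 0 || N < 0 || k > min(n, m) ||
      n > N || m > N) {
    stop("inconsistent counts: need 0 <= k <= min(n, m) <= N")
  }
  stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values (standard step-up with monotonicity).
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Negative-binomial likelihood-ratio test for a group effect
#'
#' A pragmatic stand-in for a full GLM-based count LRT: the NB
#' log-likelihood is maximized under the full model (one mean per group)
#' and the reduced model (grand mean), both with a shared
#' method-of-moments dispersion estimated from the within-group
#' variability; twice the log-likelihood difference is referred to a
#' chi-squared distribution with (groups - 1) degrees of freedom. It makes
#' no claim of numerical equality with shrinkage-based GLM implementations.
#'
#' @param y non-negative counts (numeric vector).
#' @param group factor (or coercible) with >= 2 levels, >= 2 replicates
#'   each.
#' @return list with `p_value`, `stat`, `df`, `dispersion`, `group_means`.
#' @export
nb_lrt <- function(y, group) {
  group <- as.factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (any(table(group) < 2L)) {
    stop("need at least 2 replicates per group (dispersion inestimable)")
  }
  if (all(y == 0)) {
    return(list(p_value = 1, stat = 0, df = nlevels(group) - 1L,
                dispersion = 0,
                group_means = tapply(y, group, mean)))
  }
  mu_g <- tapply(y, group, mean)
  mu0 <- mean(y)
  # pooled within-group variance -> method-of-moments dispersion
  resid2 <- (y - mu_g[group])^2
  s2 <- sum(resid2) / (length(y) - nlevels(group))
  disp <- max((s2 - mu0) / mu0^2, 1e-8)
  size <- 1 / disp
  ll <- function(mu) sum(stats::dnbinom(round(y), size = size,
                                        mu = pmax(mu, 1e-10), log = TRUE))
  stat <- 2 * (ll(mu_g[group]) - ll(rep(mu0, length(y))))
  stat <- max(stat, 0)
  df <- nlevels(group) - 1L
  list(p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       stat = stat, df = df, dispersion = disp, group_means = mu_g)
}

#' Venn partition counts of 2 or 3 identifier sets
#'
#' @param sets named list of 2 or 3 character vectors.
#' @return named integer vector of exclusive region counts (e.g.
#'   `A_only`, `B_only`, `A_B` for two sets; all 7 regions for three).
#' @export
overlap_report <- function(sets) {
  if (!length(sets) %in% c(2L, 3L)) stop("need 2 or 3 sets")
  if (is.null(names(sets))) names(sets) <- LETTERS[seq_along(sets)]
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- sapply(sets, function(s) universe %in% s)
  pattern <- apply(member, 1, function(row) {
    paste(names(sets)[row], collapse = "_")
  })
  combos <- unlist(lapply(seq_along(sets), function(sz) {
    utils::combn(names(sets), sz, paste, collapse = "_")
  }))
  counts <- stats::setNames(integer(length(combos)), combos)
  tab <- table(pattern)
  counts[names(tab)] <- as.integer(tab)
  names(counts) <- ifelse(grepl("_", names(counts)), names(counts),
                          paste0(names(counts), "_only"))
  counts
}
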