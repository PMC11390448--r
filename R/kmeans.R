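#' Seeded K-means partition of instance features
#'
#' K-means++ initialization with `nstart` independent restarts; each restart
#' is optimized with the Hartigan-Wong exchange algorithm (via
#' [stats::kmeans()]), which attains strictly stronger local optima than
#' plain Lloyd iteration, falling back to an internal Lloyd loop (convergence
#' tolerance `tol` on centroid movement) for degenerate inputs such as
#' duplicate seeds. The best restart by within-cluster sum of squares is
#' returned. Fully deterministic for a fixed `(features, k, seed)`; the
#' attained solution is stable under Lloyd reassignment (locally optimal
#' within-cluster SS).
#'
#' @param features numeric matrix, one row per instance (a vector is treated
#'   as one-dimensional features).
#' @param k number of clusters (default 2, the positive/negative split used
#'   for pseudo-labeling).
#' @param seed integer seed.
#' @param nstart number of k-means++ restarts (default 10).
#' @param tol convergence tolerance on total squared centroid movement.
#' @param max_iter Lloyd iteration cap per restart.
#' @return list with `cluster` (integer vector in `1..k`), `centers`
#'   (`k x d` matrix), `withinss` (total within-cluster sum of squares).
#' @export
kmeans_partition <- function(features, k = 2, seed = 1, nstart = 10,
                             tol = 1e-4, max_iter = 100) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (n < k) {
    stop(sprintf("need at least k = %d instances, got %d", k, n), call. = FALSE)
  }
  if (k < 1L) stop_config("k", "must be >= 1")

  seed_pp <- function() {
    # k-means++ seeding
    centers <- x[sample.int(n, 1L), , drop = FALSE]
    while (nrow(centers) < k) {
      d2 <- apply(row_dist2(x, centers), 1, min)
      d2 <- pmax(d2, 0)
      probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers <- rbind(centers, x[sample.int(n, 1L, prob = probs), , drop = FALSE])
    }
    centers
  }

  lloyd_once <- function(centers) {
    assign <- integer(n)
    for (it in seq_len(max_iter)) {
      D <- row_dist2(x, centers)
      assign <- max.col(-D, ties.method = "first")
      new_centers <- centers
      for (j in seq_len(k)) {
        members <- assign == j
        if (any(members)) {
          new_centers[j, ] <- colMeans(x[members, , drop = FALSE])
        } else {
          # empty cluster: reseed at the point farthest from its centre
          far <- which.max(apply(D, 1, min))
          new_centers[j, ] <- x[far, ]
        }
      }
      moved <- sum((new_centers - centers)^2)
      centers <- new_centers
      if (moved < tol) break
    }
    D <- row_dist2(x, centers)
    assign <- max.col(-D, ties.method = "first")
    wss <- sum(pmax(D[cbind(seq_len(n), assign)], 0))
    list(cluster = assign, centers = centers, withinss = wss)
  }

  one_restart <- function() {
    centers <- seed_pp()
    distinct <- nrow(unique(centers)) == k
    if (distinct) {
      fit <- tryCatch(
        stats::kmeans(x, centers = centers, iter.max = max_iter,
                      algorithm = "Hartigan-Wong"),
        error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(fit)) {
        return(list(cluster = as.integer(fit$cluster),
                    centers = unname(fit$centers),
                    withinss = fit$tot.withinss))
      }
    }
    lloyd_once(centers)
  }

  with_seed(seed, {
    best <- NULL
    for (s in seq_len(nstart)) {
      fit <- one_restart()
      if (is.null(best) || fit$withinss < best$withinss - 1e-12) best <- fit
    }
    best
  })
}
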