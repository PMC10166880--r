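# Gaussian mixture grouping of cells on two marker-gene axes.
# The k-means initializer (k-means++ seeding + Lloyd iterations) and the EM
# loop (full 2x2 covariances, diagonal regularization) are implemented here
# directly; they are the method, not plumbing.

#' k-means initialization for the mixture model
#'
#' k-means++ seeding followed by Lloyd iterations until the assignment
#' fixpoint (or 300 iterations). Deterministic given `seed`.
#'
#' @param points numeric n x 2 matrix.
#' @param K number of clusters, `K <= n`.
#' @param seed integer RNG seed.
#' @param max_iter Lloyd iteration cap.
#' @return list with `centers` (K x 2) and `assignments` (integer vector in
#'   `1:K`).
#' @export
kmeans_init <- function(points, K, seed = 0L, max_iter = 300L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < K) stop("need at least K points (n = ", n, ", K = ", K, ")",
                  call. = FALSE)
  set.seed(seed)
  # k-means++ seeding: first center uniform, then D^2-weighted
  centers <- matrix(0, K, ncol(points))
  centers[1, ] <- points[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(points, 2, centers[1, ])^2)
  for (k in seq_len(K)[-1]) {
    if (all(d2 == 0)) {
      centers[k, ] <- points[sample.int(n, 1L), ]
    } else {
      centers[k, ] <- points[sample.int(n, 1L, prob = d2), ]
    }
    d2 <- pmin(d2, rowSums(sweep(points, 2, centers[k, ])^2))
  }
  assign_pts <- function(centers) {
    d <- vapply(seq_len(K),
                function(k) rowSums(sweep(points, 2, centers[k, ])^2),
                numeric(n))
    max.col(-matrix(d, nrow = n), ties.method = "first")
  }
  assignments <- assign_pts(centers)
  for (iter in seq_len(max_iter)) {
    for (k in seq_len(K)) {
      members <- assignments == k
      if (any(members)) {
        centers[k, ] <- colMeans(points[members, , drop = FALSE])
      }
    }
    new_assign <- assign_pts(centers)
    if (identical(new_assign, assignments)) break
    assignments <- new_assign
  }
  list(centers = centers, assignments = assignments)
}

# log density of N(mu, Sigma) at each row of X, 2-D, via Cholesky
log_dmvnorm <- function(X, mu, sigma) {
  L <- chol(sigma)
  z <- forwardsolve(t(L), t(X) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(L))) - log(2 * pi)
}

#' Fit a 2-D Gaussian mixture by EM with k-means initialization
#'
#' Full-covariance expectation-maximization started from the hard k-means
#' partition (one-hot responsibilities). Covariances get a diagonal
#' regularization floor `reg`; iteration stops when the relative
#' log-likelihood change drops below `tol` or at `max_iter`. Components are
#' reordered by descending weight so results are reproducible.
#'
#' @param points numeric n x 2 matrix.
#' @param K number of components.
#' @param seed integer RNG seed (used by the k-means++ initializer).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap.
#' @param reg diagonal added to each covariance (eigenvalue floor).
#' @return a `MixtureModel`: list with `K`, `weights`, `means` (K x 2),
#'   `covariances` (list of 2 x 2), `responsibilities` (n x K),
#'   `loglik_trace`, `assignments` (integer, by max responsibility), and
#'   `converged`.
#' @export
fit_gmm_points <- function(points, K, seed = 0L, tol = 1e-6,
                           max_iter = 200L, reg = 1e-6) {
  X <- as.matrix(points)
  storage.mode(X) <- "double"
  n <- nrow(X)
  init <- kmeans_init(X, K, seed)
  resp <- matrix(0, n, K)
  resp[cbind(seq_len(n), init$assignments)] <- 1
  weights <- numeric(K)
  means <- matrix(0, K, 2)
  covs <- vector("list", K)
  loglik_trace <- numeric(0)
  converged <- FALSE

  m_step <- function(resp) {
    nk <- colSums(resp)
    nk <- pmax(nk, .Machine$double.eps)
    weights <<- nk / n
    for (k in seq_len(K)) {
      means[k, ] <<- colSums(X * resp[, k]) / nk[k]
      Xc <- sweep(X, 2, means[k, ])
      S <- crossprod(Xc * resp[, k], Xc) / nk[k]
      S <- S + diag(reg, 2)
      if (!all(is.finite(S)) || det(S) <= 0) {
        stop("singular covariance in component ", k,
             " despite regularization", call. = FALSE)
      }
      covs[[k]] <<- S
    }
  }

  m_step(resp)
  for (iter in seq_len(max_iter)) {
    # E-step with log-sum-exp
    logp <- vapply(seq_len(K), function(k) {
      log(weights[k]) + log_dmvnorm(X, means[k, ], covs[[k]])
    }, numeric(n))
    logp <- matrix(logp, nrow = n)
    mx <- apply(logp, 1, max)
    lse <- mx + log(rowSums(exp(logp - mx)))
    loglik <- sum(lse)
    resp <- exp(logp - lse)
    loglik_trace <- c(loglik_trace, loglik)
    if (iter > 1) {
      prev <- loglik_trace[iter - 1]
      if (abs(loglik - prev) <= tol * abs(prev)) {
        converged <- TRUE
        m_step(resp)
        break
      }
    }
    m_step(resp)
  }

  ord <- order(weights, decreasing = TRUE)
  resp <- resp[, ord, drop = FALSE]
  model <- structure(
    list(K = K, weights = weights[ord], means = means[ord, , drop = FALSE],
         covariances = covs[ord], responsibilities = resp,
         loglik_trace = loglik_trace,
         assignments = max.col(resp, ties.method = "first"),
         converged = converged),
    class = "MixtureModel")
  model
}

#' @export
print.MixtureModel <- function(x, ...) {
  cat("MixtureModel: K =", x$K, "| weights:",
      paste(sprintf("%.3f", x$weights), collapse = " "),
      "|", length(x$loglik_trace), "EM iterations",
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  invisible(x)
}

#' Fit a Gaussian mixture on two marker genes of a dataset
#'
#' Cells are placed on the plane spanned by the two genes' expression —
#' normalized mRNA-derived UMI counts by default (see [normalized_layer()]),
#' raw counts via `layer = "raw"` — and grouped by [fit_gmm_points()].
#'
#' @param ds a `CellDataset`.
#' @param gene_x,gene_y marker gene ids for the two axes.
#' @param K number of components.
#' @param layer `"normalized"` (default) or `"raw"`.
#' @param seed,tol,max_iter,reg passed to [fit_gmm_points()].
#' @return a `MixtureModel` carrying `gene_x`/`gene_y`/`layer` metadata.
#' @export
fit_gmm <- function(ds, gene_x, gene_y, K, layer = c("normalized", "raw"),
                    seed = 0L, tol = 1e-6, max_iter = 200L, reg = 1e-6) {
  layer <- match.arg(layer)
  X <- cbind(feature_values(ds, gene_x, layer),
             feature_values(ds, gene_y, layer))
  model <- fit_gmm_points(X, K, seed = seed, tol = tol,
                          max_iter = max_iter, reg = reg)
  model$gene_x <- gene_x
  model$gene_y <- gene_y
  model$layer <- layer
  model
}

#' Write mixture-model groups as a cell annotation
#'
#' Component indices (as strings, `"1" ... "K"`, ordered by descending
#' component weight) become an annotation column usable by the region
#' statistics exactly like a polygon selection.
#'
#' @param model a `MixtureModel` fitted on this dataset.
#' @param ds the `CellDataset` the model was fitted on.
#' @param key annotation column name to write.
#' @return the updated dataset.
#' @export
assign_groups <- function(model, ds, key) {
  stopifnot(inherits(model, "MixtureModel"))
  if (length(model$assignments) != n_cells(ds)) {
    stop("model was fitted on ", length(model$assignments),
         " cells but dataset has ", n_cells(ds), call. = FALSE)
  }
  set_annotation(ds, key, as.character(model$assignments))
}
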