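# 3D embedding of the feature matrix: principal components, Sammon
# mapping (via MASS::sammon, the classic step-halving descent), SMACOF
# majorization (Guttman transform, implemented here), and random
# placement. Embedders return raw coordinates; centring/box-scaling for
# display is a scene concern.

.new_embedding <- function(Y, method, params = list(), stress = NA_real_,
                           iterations = NA_integer_, seed = NULL,
                           extra = list()) {
  Y <- as.matrix(Y)
  if (ncol(Y) < 3) Y <- cbind(Y, matrix(0, nrow(Y), 3 - ncol(Y)))
  colnames(Y) <- c("x", "y", "z")
  if (any(!is.finite(Y))) stop("non-finite embedding coordinates")
  structure(c(list(Y = Y, method = method, params = params,
                   stress = stress, iterations_run = iterations,
                   seed = seed), extra),
            class = "embedding3d")
}

#' @export
print.embedding3d <- function(x, ...) {
  cat(sprintf("<embedding3d> %s: %d compounds%s\n", x$method, nrow(x$Y),
              if (is.na(x$stress)) "" else sprintf(", stress %.3g", x$stress)))
  invisible(x)
}

#' Euclidean distance matrix of a feature matrix
#'
#' @param M a `feature_matrix` or numeric matrix (n >= 2 rows)
#' @return symmetric n x n matrix with zero diagonal
#' @export
build_distance_matrix <- function(M) {
  X <- .as_matrix(M)
  stopifnot(nrow(X) >= 2)
  as.matrix(stats::dist(X))
}

#' PCA embedding into 3D
#'
#' Projects the mean-centred feature matrix onto its top-3 principal
#' components. With fewer than 3 positive-variance directions the
#' remaining coordinates are zero. Pairwise distances are preserved
#' exactly when the data's intrinsic dimension is at most 3.
#'
#' @param M a `feature_matrix` or numeric matrix
#' @return an `embedding3d`; `variance_explained` holds the per-component
#'   proportions
#' @export
pca_embed <- function(M) {
  X <- .as_matrix(M)
  stopifnot(nrow(X) >= 2)
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ncomp <- min(3L, ncol(p$x))
  Y <- p$x[, seq_len(ncomp), drop = FALSE]
  ev <- p$sdev^2
  ve <- if (sum(ev) > 0) ev / sum(ev) else ev
  ve3 <- rep(0, 3); ve3[seq_len(ncomp)] <- ve[seq_len(ncomp)]
  .new_embedding(Y, "pca", extra = list(variance_explained = ve3))
}

# deterministic seeded jitter for exact duplicate rows
.jitter_duplicates <- function(D, seed, eps = 1e-6) {
  n <- nrow(D)
  dup <- D == 0 & upper.tri(D)
  if (!any(dup)) return(D)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  D[dup] <- stats::runif(sum(dup), eps / 2, eps)
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  if (any(D == 0 & upper.tri(D))) stop("duplicate points remain after jitter")
  D
}

#' Sammon mapping into 3D
#'
#' Minimises the Sammon stress
#' `E = (1/sum d*) * sum (d*_ij - d_ij)^2 / d*_ij`
#' over embedding coordinates, starting from the PCA solution, by the
#' classic iterative descent with step halving. Exact duplicate points
#' are jittered by ~1e-6 (seeded) because the stress is undefined at
#' zero input distance.
#'
#' @param M a `feature_matrix` or numeric matrix (n >= 4 rows)
#' @param max_iter iteration cap (default 100)
#' @param tol relative stress-change tolerance (default 1e-9)
#' @param seed integer seed (used only for duplicate jitter)
#' @return an `embedding3d` (`iterations_run` is NA: the descent does not
#'   report its iteration count)
#' @export
sammon_embed <- function(M, max_iter = 100L, tol = 1e-9, seed = 1L) {
  X <- .as_matrix(M)
  n <- nrow(X)
  if (n < 4) stop("Sammon mapping needs at least 4 compounds")
  D <- .jitter_duplicates(build_distance_matrix(X), seed)
  init <- pca_embed(X)$Y
  # break exact ties in the initial configuration (duplicates collapse)
  if (anyDuplicated(init)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed + 1L)
    init <- init + matrix(stats::rnorm(length(init), 0, 1e-7), n, 3)
  }
  fit <- MASS::sammon(stats::as.dist(D), y = init, k = 3L,
                      niter = max_iter, tol = tol, trace = FALSE)
  init_stress <- .sammon_stress(D, init)
  .new_embedding(fit$points, "sammon",
                 params = list(max_iter = max_iter, tol = tol),
                 stress = fit$stress, seed = seed,
                 extra = list(initial_stress = init_stress))
}

.sammon_stress <- function(D, Y) {
  dY <- as.matrix(stats::dist(Y))
  up <- upper.tri(D)
  sum((D[up] - dY[up])^2 / D[up]) / sum(D[up])
}

#' SMACOF multidimensional scaling into 3D
#'
#' Minimises the raw stress `sigma(Y) = sum_(i<j) (D_ij - d_ij(Y))^2`
#' (unit weights) by iterated Guttman transforms from a classical-scaling
#' initialisation. Majorization guarantees a monotone non-increasing
#' stress sequence, which is asserted at every iteration.
#'
#' @param D distance matrix (or `feature_matrix`/numeric matrix, turned
#'   into Euclidean distances)
#' @param max_iter iteration cap (default 200)
#' @param tol relative stress-improvement stopping threshold (default 1e-6)
#' @param seed integer seed (used only when the initialisation is
#'   degenerate)
#' @return an `embedding3d` with the stress sequence in `stress_trace`
#' @export
smacof_embed <- function(D, max_iter = 200L, tol = 1e-6, seed = 1L) {
  if (inherits(D, "feature_matrix") || (is.matrix(D) && !isSymmetric(unname(D))))
    D <- build_distance_matrix(D)
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(n >= 2, all(abs(D - t(D)) < 1e-12), all(diag(D) == 0))
  if (all(D == 0))
    return(.new_embedding(matrix(0, n, 3), "smacof", stress = 0,
                          iterations = 0L, seed = seed,
                          extra = list(stress_trace = 0)))
  # classical scaling init; pad/collapse to 3 dims
  cs <- suppressWarnings(stats::cmdscale(D, k = min(3L, n - 1L)))
  Y <- cbind(cs, matrix(0, n, 3 - ncol(cs)))
  if (all(Y == 0)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    Y <- matrix(stats::rnorm(n * 3, 0, 1e-3), n, 3)
  }
  raw_stress <- function(Y) {
    dY <- as.matrix(stats::dist(Y))
    sum((D - dY)[upper.tri(D)]^2)
  }
  trace <- raw_stress(Y)
  iters <- 0L
  for (it in seq_len(max_iter)) {
    dY <- as.matrix(stats::dist(Y))
    ratio <- ifelse(dY > 0, D / dY, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    Ynew <- (B %*% Y) / n  # Guttman transform, unit weights
    s <- raw_stress(Ynew)
    prev <- trace[length(trace)]
    if (s > prev * (1 + 1e-10) + 1e-12)
      stop("internal error: SMACOF stress increased (majorization broken)")
    trace <- c(trace, s)
    Y <- Ynew
    iters <- it
    if (prev - s < tol * max(prev, .Machine$double.eps)) break
  }
  .new_embedding(Y, "smacof", params = list(max_iter = max_iter, tol = tol),
                 stress = trace[length(trace)], iterations = iters,
                 seed = seed, extra = list(stress_trace = trace))
}

#' Random 3D placement
#'
#' Uniform positions in the unit cube; the fallback when no features are
#' selected.
#'
#' @param n number of compounds
#' @param seed integer seed
#' @return an `embedding3d` with `method = "random"`
#' @export
random_embed <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  Y <- matrix(stats::runif(n * 3), n, 3)
  .new_embedding(Y, "random", seed = seed)
}
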