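# Pluggable 3D coordinate providers (wizard "create structures" step).
# Force-field geometry optimisation is deliberately delegated: any
# function(molecule_graph) -> molecule_graph-with-coords can be
# registered. The built-in "topological" provider produces deterministic
# toy geometries (classical scaling of graph distances at 1.5 A per
# bond), sufficient for alignment of topologically encoded test
# structures — not chemically realistic conformers.

.coordinate_providers <- new.env(parent = emptyenv())

#' Register a 3D coordinate provider
#' @param name provider name
#' @param fun function(molecule_graph) -> molecule_graph with `coords`
#' @return `name`, invisibly
#' @export
register_coordinate_provider <- function(name, fun) {
  stopifnot(is.function(fun))
  assign(name, fun, envir = .coordinate_providers)
  invisible(name)
}

# graph (topological) distance matrix by BFS
.graph_distances <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- adjacency(mol)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    queue <- s
    while (length(queue)) {
      a <- queue[[1]]; queue <- queue[-1]
      for (b in adj[[a]]$nbr) {
        if (is.infinite(D[s, b])) {
          D[s, b] <- D[s, a] + 1
          queue <- c(queue, b)
        }
      }
    }
  }
  D
}

.topological_coords <- function(mol) {
  n <- nrow(mol$atoms)
  if (n == 1L) {
    mol$coords <- matrix(0, 1, 3)
    return(mol)
  }
  D <- .graph_distances(mol)
  # disconnected components laid out side by side
  if (any(is.infinite(D))) {
    comp <- components(mol)
    offset <- 0
    coords <- matrix(0, n, 3)
    for (cl in unique(comp)) {
      idx <- which(comp == cl)
      sub <- D[idx, idx, drop = FALSE]
      cs <- .classical_3d(sub * 1.5)
      cs[, 1] <- cs[, 1] + offset
      coords[idx, ] <- cs
      offset <- offset + max(cs[, 1]) - min(cs[, 1]) + 3
    }
    mol$coords <- coords
    return(mol)
  }
  mol$coords <- .classical_3d(D * 1.5)
  mol
}

.classical_3d <- function(D) {
  n <- nrow(D)
  k <- min(3L, n - 1L)
  cs <- suppressWarnings(stats::cmdscale(D, k = k))
  Y <- cbind(cs, matrix(0, n, 3 - ncol(cs)))
  # deterministic tiny out-of-plane lift so flat layouts are not exactly
  # degenerate for superposition
  if (all(Y[, 3] == 0) && n > 3)
    Y[, 3] <- 1e-3 * sin(seq_len(n))
  Y
}

#' Generate 3D structures for a dataset
#'
#' Applies a registered coordinate provider to every molecule lacking 3D
#' coordinates; molecules that already carry 3D structure pass through
#' unchanged (2D-only inputs are accepted upstream and flow through with
#' `has3d = FALSE` if no provider is run).
#'
#' @param dataset a [ches_dataset()]
#' @param provider provider name (built-in: "topological")
#' @param force recompute even when coordinates exist
#' @return the dataset with coordinates filled and `has3d` updated
#' @export
generate_structures <- function(dataset, provider = "topological",
                                force = FALSE) {
  if (!exists(provider, envir = .coordinate_providers, inherits = FALSE))
    stop("unknown coordinate provider '", provider, "'")
  fun <- get(provider, envir = .coordinate_providers)
  dataset$molecules <- lapply(dataset$molecules, function(m) {
    if (!force && !is.null(m$coords) && any(abs(m$coords[, 3]) > 1e-8))
      return(m)
    fun(m)
  })
  dataset$has3d <- all(vapply(dataset$molecules,
                              function(m) !is.null(m$coords), logical(1)))
  dataset
}
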