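# Synthetic fixtures: scaffold-series molecule sets (emulating a series
# of structurally similar compounds such as polybrominated diphenyl
# ethers), Gaussian-mixture feature tables with known cluster structure,
# and planted endpoints correlated with the features. Everything is
# deterministic under its seed.

#' Specify a scaffold series
#'
#' @param scaffold scaffold SMILES
#' @param substituents character vector of substituent SMILES fragments
#'   (use "" for no substitution at a point)
#' @param attachment_points atom indices of the scaffold (parse order)
#'   where substituents may attach
#' @param n_per_scaffold number of molecules to generate
#' @param name series name (used as the ground-truth label)
#' @return an object of class `scaffold_series_spec`
#' @export
scaffold_series_spec <- function(scaffold, substituents, attachment_points,
                                 n_per_scaffold = 5L, name = NULL) {
  mol <- parse_smiles(scaffold)  # validates eagerly
  stopifnot(n_per_scaffold >= 1,
            all(attachment_points >= 1),
            all(attachment_points <= nrow(mol$atoms)))
  structure(list(scaffold = scaffold, substituents = substituents,
                 attachment_points = as.integer(attachment_points),
                 n_per_scaffold = as.integer(n_per_scaffold),
                 name = name %||% scaffold),
            class = "scaffold_series_spec")
}

#' Attach a substituent to a SMILES string
#'
#' String-level SMILES surgery: inserts `(substituent)` directly after
#' the given atom's token (including its ring-closure digits), so the
#' substituent becomes a branch at that atom.
#'
#' @param smiles scaffold SMILES
#' @param atom_index atom (in parse order) to substitute at
#' @param substituent substituent SMILES fragment (e.g. "Br", "OC")
#' @return the substituted SMILES string
#' @export
#' @examples
#' attach_substituent("c1ccccc1", 2, "Br")  # "c1c(Br)cccc1"
attach_substituent <- function(smiles, atom_index, substituent) {
  if (!nzchar(substituent)) return(smiles)
  mol <- parse_smiles(smiles)
  ends <- attr(mol, "atom_end")
  stopifnot(atom_index >= 1, atom_index <= length(ends))
  pos <- ends[atom_index]
  paste0(substr(smiles, 1, pos), "(", substituent, ")",
         substr(smiles, pos + 1L, nchar(smiles)))
}

#' Generate a scaffold-series dataset
#'
#' Enumerates scaffold + substituent combinations: every generated
#' molecule draws one substituent per attachment point (uniformly,
#' seeded) and records its generating scaffold in the ground-truth
#' nominal column `scaffold`.
#'
#' @param specs list of [scaffold_series_spec()] (a single spec is
#'   accepted)
#' @param seed integer seed
#' @param name dataset name
#' @return a [ches_dataset()] with a dataset-origin `scaffold` column
#' @export
generate_scaffold_series <- function(specs, seed = 1L,
                                     name = "scaffold-series") {
  if (inherits(specs, "scaffold_series_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  mols <- list(); labels <- character(0)
  for (si in seq_along(specs)) {
    sp <- specs[[si]]
    for (r in seq_len(sp$n_per_scaffold)) {
      smi <- sp$scaffold
      # draw per attachment point; attach right-to-left so earlier atom
      # offsets stay valid
      subs <- sample(sp$substituents, length(sp$attachment_points),
                     replace = TRUE)
      for (pi in order(sp$attachment_points, decreasing = TRUE))
        smi <- attach_substituent(smi, sp$attachment_points[pi], subs[pi])
      id <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]", "", sp$name), r)
      mols[[length(mols) + 1L]] <- parse_smiles(smi, id = id)
      labels <- c(labels, sp$name)
    }
  }
  ches_dataset(mols,
               list(feature_column("scaffold", labels, ftype = "nominal",
                                   origin = "dataset")),
               name = name)
}

#' The default demonstration scaffold series
#'
#' Three aromatic two-ring scaffolds (diphenyl ether, biphenyl,
#' benzophenone) brominated/chlorinated at ring positions — a synthetic
#' stand-in for a structurally homogeneous halogenated series.
#'
#' @param n_per_scaffold molecules per scaffold (default 10)
#' @param seed integer seed
#' @return a [ches_dataset()]
#' @export
default_scaffold_series <- function(n_per_scaffold = 10L, seed = 1L) {
  specs <- list(
    scaffold_series_spec("O(c1ccccc1)c1ccccc1",
                         c("Br", "Br", ""), c(3, 5, 9, 11),
                         n_per_scaffold, name = "diphenyl-ether"),
    scaffold_series_spec("c1ccc(cc1)c1ccccc1",
                         c("Br", "Cl", ""), c(2, 5, 9, 11),
                         n_per_scaffold, name = "biphenyl"),
    scaffold_series_spec("C(=O)(c1ccccc1)c1ccccc1",
                         c("Br", "C", ""), c(5, 7, 11, 13),
                         n_per_scaffold, name = "benzophenone"))
  generate_scaffold_series(specs, seed = seed, name = "halogenated-series")
}

#' Gaussian-mixture feature matrix with known clusters
#'
#' Cluster centres are placed with pairwise distance at least
#' `separation` (rejection sampling in a cube, seeded); points are drawn
#' from isotropic Gaussians with standard deviation `sigma`.
#'
#' @param n_clusters number of clusters
#' @param n_per_cluster points per cluster
#' @param dim feature dimensionality
#' @param sigma within-cluster standard deviation
#' @param separation minimum centre-to-centre distance
#' @param seed integer seed
#' @return list(M = `feature_matrix`, labels = integer vector,
#'   centers = matrix)
#' @export
generate_gaussian_features <- function(n_clusters = 3L, n_per_cluster = 20L,
                                       dim = 4L, sigma = 0.1,
                                       separation = 10, seed = 1L) {
  stopifnot(sigma > 0, separation > 0, n_clusters >= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  side <- separation * max(2, n_clusters)
  repeat {
    centers <- matrix(stats::runif(n_clusters * dim, 0, side),
                      n_clusters, dim)
    if (n_clusters == 1L) break
    if (min(stats::dist(centers)) >= separation) break
  }
  n <- n_clusters * n_per_cluster
  labels <- rep(seq_len(n_clusters), each = n_per_cluster)
  X <- centers[labels, , drop = FALSE] +
    matrix(stats::rnorm(n * dim, 0, sigma), n, dim)
  M <- structure(list(X = X, dim_names = paste0("f", seq_len(dim)),
                      scaling = list()),
                 class = "feature_matrix")
  list(M = M, labels = labels, centers = centers)
}

#' Plant an endpoint linearly related to the features
#'
#' `endpoint = X w + N(0, noise_sigma)`: a numeric column correlated
#' with the feature matrix but not used for embedding, for
#' neighbourhood-consistency checks (an endpoint left out of the mapping
#' should still vary smoothly over the embedded positions when it is
#' driven by the mapped features).
#'
#' @param M a `feature_matrix` or numeric matrix
#' @param weights numeric vector, one weight per feature dimension
#' @param noise_sigma Gaussian noise standard deviation
#' @param seed integer seed
#' @return a numeric [feature_column()] named "endpoint"
#' @export
generate_planted_endpoint <- function(M, weights, noise_sigma = 0,
                                      seed = 1L) {
  X <- .as_matrix(M)
  stopifnot(length(weights) == ncol(X))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  y <- as.numeric(X %*% weights)
  if (noise_sigma > 0) y <- y + stats::rnorm(nrow(X), 0, noise_sigma)
  feature_column("endpoint", y, ftype = "numeric", origin = "dataset")
}
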