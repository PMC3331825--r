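# Per-cluster common substructures and rigid-body superposition.
#
# The MCS search follows the candidate-list scheme: enumerate all maximal
# connected common subgraphs of the first molecule pair (backtracking
# with a node-expansion budget), then intersect the candidate list
# against each remaining cluster member by SMARTS matching. Atoms are
# compared on element + aromaticity, bonds on order/aromaticity;
# connected subgraphs only, because a disconnected "substructure" cannot
# orient molecules.

#' Construct a common-substructure record
#' @param smarts pattern string
#' @param natoms atom count
#' @param source "mcs" or "fragment"
#' @param matched_atoms list of per-compound atom-index vectors
#' @return object of class `common_substructure`
#' @export
common_substructure <- function(smarts, natoms, source = c("mcs", "fragment"),
                                matched_atoms = NULL) {
  structure(list(smarts = smarts, natoms = as.integer(natoms),
                 source = match.arg(source), matched_atoms = matched_atoms),
            class = "common_substructure")
}

#' @export
print.common_substructure <- function(x, ...) {
  cat(sprintf("<common_substructure> %s (%d atoms, %s)\n",
              x$smarts, x$natoms, x$source))
  invisible(x)
}

.atoms_compatible <- function(molA, a, molB, b) {
  molA$atoms$element[a] == molB$atoms$element[b] &&
    molA$atoms$aromatic[a] == molB$atoms$aromatic[b]
}

.bonds_compatible <- function(molA, ra, molB, rb) {
  if (molA$bonds$aromatic[ra] != molB$bonds$aromatic[rb]) return(FALSE)
  molA$bonds$aromatic[ra] || molA$bonds$order[ra] == molB$bonds$order[rb]
}

# all maximal connected common subgraphs of a molecule pair, returned as
# subgraphs of molA: list(atoms = A atom indices, bonds = A bond rows).
# `budget` caps backtracking node expansions.
.mcs_pair <- function(molA, molB, budget = 2e5) {
  adjA <- adjacency(molA); adjB <- adjacency(molB)
  nA <- nrow(molA$atoms); nB <- nrow(molB$atoms)
  results <- new.env(parent = emptyenv())
  visited <- new.env(parent = emptyenv())  # mapping states already expanded
  nodes <- 0L
  overflow <- FALSE

  record <- function(mapA, bondsA) {
    key <- paste(paste(sort(mapA), collapse = ","),
                 paste(sort(bondsA), collapse = ","), sep = "|")
    assign(key, list(atoms = sort(mapA), bonds = sort(bondsA)),
           envir = results)
  }

  recurse <- function(mapA, mapB, bondsA) {
    nodes <<- nodes + 1L
    if (nodes > budget) { overflow <<- TRUE; return() }
    state <- paste(paste(sort(paste0(mapA, ":", mapB)), collapse = ","),
                   paste(sort(bondsA), collapse = ","), sep = "|")
    if (exists(state, envir = visited, inherits = FALSE)) return()
    assign(state, TRUE, envir = visited)
    # every common subgraph is a candidate, not only maximal ones: a
    # smaller pair subgraph may be the largest one shared by the rest of
    # the cluster
    record(mapA, bondsA)
    extended <- FALSE
    # extensions: grow by one atom pair over a compatible bond, or close a
    # ring bond between already-mapped atoms
    for (pi in seq_along(mapA)) {
      a <- mapA[pi]; b <- mapB[pi]
      for (ka in seq_along(adjA[[a]]$nbr)) {
        a2 <- adjA[[a]]$nbr[ka]; ra <- adjA[[a]]$bond[ka]
        if (ra %in% bondsA) next
        pos <- match(a2, mapA)
        for (kb in seq_along(adjB[[b]]$nbr)) {
          b2 <- adjB[[b]]$nbr[kb]; rb <- adjB[[b]]$bond[kb]
          if (!.bonds_compatible(molA, ra, molB, rb)) next
          if (!is.na(pos)) {
            # ring closure: both endpoints mapped to each other
            if (mapB[pos] == b2) {
              extended <- TRUE
              recurse(mapA, mapB, c(bondsA, ra))
            }
          } else {
            if (b2 %in% mapB) next
            if (!.atoms_compatible(molA, a2, molB, b2)) next
            extended <- TRUE
            recurse(c(mapA, a2), c(mapB, b2), c(bondsA, ra))
          }
          if (overflow) return()
        }
        if (overflow) return()
      }
    }
    invisible(extended)
  }

  for (a in seq_len(nA)) {
    for (b in seq_len(nB)) {
      if (!.atoms_compatible(molA, a, molB, b)) next
      recurse(a, b, integer(0))
      if (overflow) break
    }
    if (overflow) break
  }
  if (overflow)
    warning("common-subgraph search budget exceeded; result may be ",
            "suboptimal")
  lapply(ls(results), function(k) get(k, envir = results))
}

#' Maximum common substructure of a cluster
#'
#' Computes all maximal connected common subgraphs of the first molecule
#' pair, then intersects the candidate list against every remaining
#' cluster member; the largest surviving candidate (atoms, then bonds)
#' becomes the cluster's common substructure. Returns `NULL` ("no
#' alignment is performed") when nothing of at least `min_atoms` atoms
#' survives.
#'
#' @param molecules cluster members (>= 2), all with 3D coordinates
#' @param min_atoms smallest usable substructure (default 3: fewer atoms
#'   cannot fix a rigid orientation)
#' @param budget node-expansion cap for the pairwise search
#' @return a [common_substructure()] or `NULL`
#' @export
cluster_mcs <- function(molecules, min_atoms = 3L, budget = 2e5) {
  stopifnot(length(molecules) >= 2)
  no3d <- vapply(molecules, function(m) is.null(m$coords), logical(1))
  if (any(no3d))
    stop("compound(s) without 3D coordinates: ",
         paste(vapply(molecules[no3d], function(m) m$id, character(1)),
               collapse = ", "),
         "; generate structures first (coordinate-provider step)")
  cands <- .mcs_pair(molecules[[1]], molecules[[2]], budget = budget)
  if (!length(cands)) return(NULL)
  ord <- order(-vapply(cands, function(c) length(c$atoms), integer(1)),
               -vapply(cands, function(c) length(c$bonds), integer(1)))
  cands <- cands[ord]
  smarts <- vapply(cands, function(c)
    subgraph_smarts(molecules[[1]], c$atoms, c$bonds), character(1))
  sizes <- vapply(cands, function(c) length(c$atoms), integer(1))
  # lazy intersection: walk candidates from the largest and return the
  # first that every remaining cluster member contains
  seen <- character(0)
  rest <- molecules[-(1:2)]
  for (ci in seq_along(cands)) {
    if (sizes[ci] < min_atoms) break
    if (smarts[ci] %in% seen) next
    seen <- c(seen, smarts[ci])
    ok <- all(vapply(rest, function(m)
      length(match_smarts(smarts[ci], m, max_matches = 1L)) > 0,
      logical(1)))
    if (ok) {
      matched <- lapply(molecules, function(m)
        match_smarts(smarts[ci], m, max_matches = 1L)[[1]])
      return(common_substructure(smarts[ci], sizes[ci], "mcs",
                                 matched_atoms = matched))
    }
  }
  NULL
}

#' Select the maximum structural fragment of a cluster
#'
#' Among fragment features whose incidence is 1 for every cluster member,
#' returns the largest (most atoms; ties broken by lexicographically
#' smallest SMARTS). Requires structural features to have been computed.
#'
#' @param cluster_members integer compound indices of the cluster
#' @param fragment_features list of [fragment_feature()] with incidence
#' @return a [common_substructure()] (source "fragment") or `NULL` if no
#'   fragment covers the whole cluster
#' @export
msf_select <- function(cluster_members, fragment_features) {
  if (is.null(fragment_features) || !length(fragment_features))
    stop("MSF aligner requires structural features")
  covers <- vapply(fragment_features, function(f) {
    if (is.null(f$incidence)) stop("fragment incidence not computed")
    all(f$incidence[cluster_members] == 1L)
  }, logical(1))
  if (!any(covers)) return(NULL)
  cand <- fragment_features[covers]
  natoms <- vapply(cand, `[[`, integer(1), "natoms")
  smarts <- vapply(cand, `[[`, character(1), "smarts")
  pick <- order(-natoms, smarts)[1]
  common_substructure(smarts[pick], natoms[pick], "fragment")
}

# --- rigid-body superposition -----------------------------------------

#' Construct a rigid transform
#' @param rotation 3x3 proper rotation (det +1)
#' @param translation length-3 vector
#' @param rmsd RMSD over matched atoms (Angstroms)
#' @return object of class `rigid_transform`
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            rmsd = 0) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation is not orthonormal")
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 rmsd = rmsd),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rmsd %.4g A\n", x$rmsd))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#' @param transform a [rigid_transform()]
#' @param coords n x 3 matrix
#' @return transformed n x 3 matrix
#' @export
apply_transform <- function(transform, coords) {
  coords <- as.matrix(coords)
  sweep(coords %*% t(transform$rotation), 2, -transform$translation)
}

# Kabsch: proper rotation R and translation t minimising
# || R p + t - q ||^2 over matched coordinate rows.
.kabsch <- function(P, Q) {
  pc <- colMeans(P); qc <- colMeans(Q)
  H <- crossprod(sweep(P, 2, pc), sweep(Q, 2, qc))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- qc - as.numeric(R %*% pc)
  moved <- sweep(P %*% t(R), 2, -t)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  rigid_transform(R, t, rmsd)
}

#' Align a molecule onto a reference over a common substructure
#'
#' Least-squares (Kabsch) superposition of the moving molecule's matched
#' substructure atoms onto the reference's; when either molecule has
#' several substructure embeddings, the embedding pair with the smallest
#' RMSD wins. Reflections are never used (det(rotation) = +1). The
#' returned transform applies to ALL atoms of the moving molecule; the
#' RMSD is over matched atoms. With fewer than 3 matched atoms the
#' rotation is underdetermined and a translation-only alignment is
#' returned with a warning.
#'
#' @param reference,moving [molecule_graph()]s with 3D coordinates
#' @param sub a [common_substructure()] matching both
#' @param max_embeddings cap on embeddings considered per molecule
#' @return a [rigid_transform()]
#' @export
align_to_reference <- function(reference, moving, sub, max_embeddings = 32L) {
  if (is.null(reference$coords) || is.null(moving$coords))
    stop("both molecules need 3D coordinates")
  pat <- parse_smarts(sub$smarts)
  em_ref <- match_smarts(pat, reference, max_matches = max_embeddings)
  em_mov <- match_smarts(pat, moving, max_matches = max_embeddings)
  if (!length(em_ref) || !length(em_mov))
    stop("substructure '", sub$smarts, "' does not match both molecules")
  if (length(em_ref[[1]]) < 3) {
    warning("fewer than 3 matched atoms; translation-only alignment")
    Q <- reference$coords[em_ref[[1]], , drop = FALSE]
    P <- moving$coords[em_mov[[1]], , drop = FALSE]
    t <- colMeans(Q) - colMeans(P)
    moved <- sweep(P, 2, -t)
    return(rigid_transform(diag(3), t, sqrt(mean(rowSums((moved - Q)^2)))))
  }
  best <- NULL
  for (er in em_ref) {
    Q <- reference$coords[er, , drop = FALSE]
    for (em in em_mov) {
      tr <- .kabsch(moving$coords[em, , drop = FALSE], Q)
      if (is.null(best) || tr$rmsd < best$rmsd) best <- tr
    }
  }
  best
}

#' Align all cluster members onto the first
#'
#' The first cluster member (dataset order) is the fixed reference and
#' gets the identity transform; every other member is aligned onto it
#' over the common substructure.
#'
#' @param molecules cluster members with 3D coordinates
#' @param sub a [common_substructure()] matching all members
#' @return list of [rigid_transform()], one per member
#' @export
align_cluster <- function(molecules, sub) {
  stopifnot(length(molecules) >= 1)
  out <- vector("list", length(molecules))
  out[[1]] <- rigid_transform()
  if (length(molecules) > 1) {
    for (m in 2:length(molecules))
      out[[m]] <- align_to_reference(molecules[[1]], molecules[[m]], sub)
  }
  out
}
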