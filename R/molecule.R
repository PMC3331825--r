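#' @keywords internal
"_PACKAGE"

# Standard atomic masses (IUPAC 2021, rounded) and default valences used for
# implicit-hydrogen completion of the organic subset.
.ELEMENT_MASS <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974, S = 32.06,
  Cl = 35.45, K = 39.098, Ca = 40.078, Fe = 55.845, Zn = 65.38,
  Se = 78.971, Br = 79.904, I = 126.904
)

.DEFAULT_VALENCE <- c(
  B = 3, C = 4, N = 3, O = 2, P = 3, S = 2, F = 1, Cl = 1, Br = 1, I = 1,
  H = 1
)

.HALOGENS <- c("F", "Cl", "Br", "I", "At")

#' Construct a molecule graph
#'
#' The unit every pipeline stage consumes: a labelled graph of atoms and
#' bonds with optional 3D coordinates and a free-form property map. Graphs
#' may be disconnected (salts); hydrogens may be explicit atoms or implicit
#' counts inferred from standard valences.
#'
#' @param atoms data.frame with columns `element` (symbol), `charge`
#'   (integer formal charge), `aromatic` (logical), and optionally `hcount`
#'   (implicit hydrogens; computed from standard valences when absent).
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices),
#'   `order` (1, 2 or 3) and `aromatic` (logical). Aromatic bonds keep a
#'   Kekule order when the input provides one.
#' @param coords optional numeric matrix, one (x, y, z) row per atom, in
#'   Angstroms (or flat 2D coordinates with z = 0).
#' @param id compound identifier string.
#' @param props named character vector/list of property tags.
#' @return An object of class `molecule_graph`.
#' @export
molecule_graph <- function(atoms, bonds = NULL, coords = NULL, id = "",
                           props = list()) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  stopifnot(nrow(atoms) >= 1, "element" %in% names(atoms))
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (is.null(atoms$aromatic)) atoms$aromatic <- FALSE
  n <- nrow(atoms)
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- data.frame(i = integer(0), j = integer(0),
                        order = integer(0), aromatic = logical(0))
  } else {
    bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
    if (is.null(bonds$aromatic)) bonds$aromatic <- FALSE
    if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n))
      stop("bond references an invalid atom index")
    if (any(bonds$i == bonds$j))
      stop("bond connects an atom to itself")
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) stop("duplicate bonds")
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n || ncol(coords) != 3L)
      stop("coords must be an n x 3 matrix with one row per atom")
    storage.mode(coords) <- "double"
  }
  mol <- structure(
    list(atoms = atoms, bonds = bonds, coords = coords,
         id = as.character(id), props = as.list(props)),
    class = "molecule_graph")
  if (is.null(mol$atoms$hcount) || anyNA(mol$atoms$hcount))
    mol$atoms$hcount <- implicit_hydrogens(mol)
  mol
}

#' @export
print.molecule_graph <- function(x, ...) {
  cat(sprintf("<molecule_graph> %s: %d atoms, %d bonds%s%s\n",
              if (nzchar(x$id)) x$id else "(unnamed)",
              nrow(x$atoms), nrow(x$bonds),
              if (!is.null(x$coords)) ", 3D" else "",
              if (length(x$props)) sprintf(", %d tags", length(x$props)) else ""))
  invisible(x)
}

#' Number of atoms in a molecule graph
#' @param mol a `molecule_graph`
#' @return integer atom count
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

# Implicit hydrogen counts from standard valences. Aromatic bonds count 1.5
# valence units (benzene carbon: 2 * 1.5 = 3 used, 1 H left). Atoms outside
# the organic subset, charged atoms and explicit hydrogens get 0.
implicit_hydrogens <- function(mol) {
  n <- nrow(mol$atoms)
  used <- numeric(n)
  b <- mol$bonds
  if (nrow(b)) {
    val <- ifelse(b$aromatic, 1.5, b$order)
    for (r in seq_len(nrow(b))) {
      used[b$i[r]] <- used[b$i[r]] + val[r]
      used[b$j[r]] <- used[b$j[r]] + val[r]
    }
  }
  h <- integer(n)
  for (a in seq_len(n)) {
    el <- mol$atoms$element[a]
    # bracket atoms carry an explicit H count; charged/exotic atoms get none
    if (isTRUE(mol$atoms$hfixed[a])) { h[a] <- mol$atoms$hcount[a]; next }
    if (el == "H" || mol$atoms$charge[a] != 0L) next
    dv <- .DEFAULT_VALENCE[el]
    if (is.na(dv)) next
    h[a] <- max(0L, as.integer(dv - ceiling(used[a])))
  }
  h
}

# Adjacency list: element [[a]] is a data.frame of (nbr, bond row index).
adjacency <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (a in seq_len(n)) adj[[a]] <- list(nbr = integer(0), bond = integer(0))
  b <- mol$bonds
  for (r in seq_len(nrow(b))) {
    i <- b$i[r]; j <- b$j[r]
    adj[[i]]$nbr <- c(adj[[i]]$nbr, j); adj[[i]]$bond <- c(adj[[i]]$bond, r)
    adj[[j]]$nbr <- c(adj[[j]]$nbr, i); adj[[j]]$bond <- c(adj[[j]]$bond, r)
  }
  adj
}

# Connected components by BFS; returns integer component label per atom.
components <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- adjacency(mol)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      a <- queue[[1]]; queue <- queue[-1]
      nb <- adj[[a]]$nbr
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

# A bond is a ring bond iff its endpoints stay connected after removing it.
ring_bonds <- function(mol) {
  b <- mol$bonds
  nb <- nrow(b)
  if (nb == 0L) return(logical(0))
  adj <- adjacency(mol)
  vapply(seq_len(nb), function(r) {
    src <- b$i[r]; dst <- b$j[r]
    seen <- logical(nrow(mol$atoms))
    seen[src] <- TRUE
    queue <- src
    while (length(queue)) {
      a <- queue[[1]]; queue <- queue[-1]
      sel <- adj[[a]]$bond != r
      nbr <- adj[[a]]$nbr[sel]
      new <- nbr[!seen[nbr]]
      if (dst %in% new) return(TRUE)
      seen[new] <- TRUE
      queue <- c(queue, new)
    }
    FALSE
  }, logical(1))
}

#' Molecular weight of a molecule graph
#'
#' Sum of standard atomic masses over all atoms, counting implicit
#' hydrogens inferred from standard valences; additive over disconnected
#' components.
#' @param mol a `molecule_graph`
#' @return numeric mass in g/mol
#' @export
molecular_weight <- function(mol) {
  m <- .ELEMENT_MASS[mol$atoms$element]
  if (anyNA(m))
    stop("no atomic mass tabulated for element(s): ",
         paste(unique(mol$atoms$element[is.na(m)]), collapse = ", "))
  sum(m) + sum(mol$atoms$hcount) * .ELEMENT_MASS[["H"]]
}
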