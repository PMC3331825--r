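# Independent oracles and small fixture builders shared by the tests.
# Oracles deliberately avoid the package's own code paths.

# --- random test molecules (trees plus occasional extra ring edge) -----

random_test_molecule <- function(n_atoms, seed, elements = c("C", "N", "O", "S"),
                                 ring_prob = 0.3) {
  set.seed(seed)
  el <- sample(elements, n_atoms, replace = TRUE)
  atoms <- data.frame(element = el, charge = 0L, aromatic = FALSE,
                      stringsAsFactors = FALSE)
  bonds <- NULL
  if (n_atoms > 1) {
    parent <- vapply(2:n_atoms, function(a) sample(a - 1L, 1L), integer(1))
    order <- sample(c(1L, 2L), n_atoms - 1L, replace = TRUE,
                    prob = c(0.8, 0.2))
    bonds <- data.frame(i = parent, j = 2:n_atoms, order = order,
                        aromatic = FALSE)
    if (n_atoms >= 4 && stats::runif(1) < ring_prob) {
      # one extra edge closing a ring
      pair <- sample(n_atoms, 2)
      key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
      if (!paste(min(pair), max(pair)) %in% key)
        bonds <- rbind(bonds, data.frame(i = pair[1], j = pair[2],
                                         order = 1L, aromatic = FALSE))
    }
  }
  molecule_graph(atoms, bonds, id = paste0("rnd", seed))
}

# --- exhaustive simple-path fragment oracle (igraph) -------------------

# Every distinct labelled simple path of 1..max_atoms atoms, canonical
# form = lexicographic min of the two directions. Path discovery is
# igraph's, label construction is re-derived here.
oracle_linear_fragments <- function(mol, max_atoms = 7L) {
  n <- nrow(mol$atoms)
  asym <- function(a) {
    e <- mol$atoms$element[a]
    if (mol$atoms$aromatic[a]) {
      le <- tolower(e)
      if (nchar(le) == 1L && le %in% c("b","c","n","o","p","s")) le
      else paste0("[", le, "]")
    } else if (e %in% c("B","C","N","O","P","S","F","Cl","Br","I")) e
    else paste0("[", e, "]")
  }
  bkey <- function(i, j) paste(min(i, j), max(i, j))
  bmap <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(mol$bonds))) {
    sym <- if (mol$bonds$aromatic[r]) ":" else
      c("-", "=", "#")[mol$bonds$order[r]]
    assign(bkey(mol$bonds$i[r], mol$bonds$j[r]), sym, envir = bmap)
  }
  label <- function(path) {
    f <- asym(path[1]); b <- asym(path[length(path)])
    fwd <- asym(path[1]); rv <- asym(path[length(path)])
    if (length(path) > 1) {
      for (k in 2:length(path)) {
        fwd <- paste0(fwd, get(bkey(path[k - 1], path[k]), envir = bmap),
                      asym(path[k]))
        rk <- length(path) - k + 1L
        rv <- paste0(rv, get(bkey(path[rk + 1L], path[rk]), envir = bmap),
                     asym(path[rk]))
      }
    }
    if (fwd <= rv) fwd else rv
  }
  out <- character(0)
  out <- c(out, vapply(seq_len(n), function(a) label(a), character(1)))
  if (n > 1 && nrow(mol$bonds) > 0) {
    g <- igraph::graph_from_data_frame(mol$bonds[, c("i", "j")],
                                       directed = FALSE,
                                       vertices = data.frame(name = seq_len(n)))
    for (from in seq_len(n)) {
      paths <- igraph::all_simple_paths(g, from = as.character(from),
                                        cutoff = max_atoms - 1L)
      for (p in paths) {
        idx <- as.integer(names(p))
        if (length(idx) >= 2) out <- c(out, label(idx))
      }
    }
  }
  sort(unique(out))
}

# --- textbook Calinski-Harabasz --------------------------------------

oracle_calinski_harabasz <- function(X, labels) {
  n <- nrow(X); k <- length(unique(labels))
  grand <- colMeans(X)
  B <- 0; W <- 0
  for (cl in unique(labels)) {
    rows <- X[labels == cl, , drop = FALSE]
    ctr <- colMeans(rows)
    B <- B + nrow(rows) * sum((ctr - grand)^2)
    for (r in seq_len(nrow(rows))) W <- W + sum((rows[r, ] - ctr)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

# --- adjusted Rand index (contingency-table formula) ------------------

oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# --- exhaustive common-subtree oracle (acyclic molecules only) --------

# Largest connected common subgraph size over a set of acyclic
# molecules: enumerate connected atom subsets of the first molecule (a
# subtree has exactly the induced bonds) and check a label-preserving
# embedding into every other molecule by brute-force injective search.
oracle_mcs_size <- function(molecules) {
  molA <- molecules[[1]]
  nA <- nrow(molA$atoms)
  induced_bonds <- function(mol, atoms)
    which(mol$bonds$i %in% atoms & mol$bonds$j %in% atoms)
  is_connected_subset <- function(mol, atoms) {
    if (length(atoms) == 1) return(TRUE)
    br <- induced_bonds(mol, atoms)
    seen <- atoms[1]
    repeat {
      grew <- FALSE
      for (r in br) {
        bi <- mol$bonds$i[r]; bj <- mol$bonds$j[r]
        if (bi %in% seen && !(bj %in% seen)) { seen <- c(seen, bj); grew <- TRUE }
        if (bj %in% seen && !(bi %in% seen)) { seen <- c(seen, bi); grew <- TRUE }
      }
      if (!grew) break
    }
    length(seen) == length(atoms)
  }
  alab <- function(mol, a)
    paste(mol$atoms$element[a], mol$atoms$aromatic[a])
  blab <- function(mol, r)
    if (mol$bonds$aromatic[r]) "ar" else as.character(mol$bonds$order[r])
  bond_between <- function(mol, x, y) {
    hit <- which((mol$bonds$i == x & mol$bonds$j == y) |
                 (mol$bonds$i == y & mol$bonds$j == x))
    if (length(hit)) hit[1] else NA_integer_
  }
  embeds <- function(atoms, bonds, molB) {
    nB <- nrow(molB$atoms)
    try_map <- function(map) {
      if (length(map) == length(atoms)) return(TRUE)
      a <- atoms[length(map) + 1L]
      for (b in setdiff(seq_len(nB), map)) {
        if (alab(molA, a) != alab(molB, b)) next
        ok <- TRUE
        for (pi in seq_along(map)) {
          ra <- bond_between(molA, atoms[pi], a)
          if (is.na(ra) || !(ra %in% bonds)) next
          rb <- bond_between(molB, map[pi], b)
          if (is.na(rb) || blab(molA, ra) != blab(molB, rb)) { ok <- FALSE; break }
        }
        if (ok && try_map(c(map, b))) return(TRUE)
      }
      FALSE
    }
    try_map(integer(0))
  }
  best <- 0L
  for (size in seq_len(nA)) {
    for (subset in utils::combn(nA, size, simplify = FALSE)) {
      if (!is_connected_subset(molA, subset)) next
      bonds <- induced_bonds(molA, subset)
      if (all(vapply(molecules[-1], function(mB) embeds(subset, bonds, mB),
                     logical(1))))
        best <- max(best, size)
    }
  }
  best
}

# --- optimal superposition RMSD via Horn's quaternion method ----------

# Closed-form best proper-rotation RMSD of P onto Q (fixed row
# correspondence); independent of the SVD-based Kabsch route.
oracle_superposition_rmsd <- function(P, Q) {
  n <- nrow(P)
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  S <- crossprod(Pc, Qc)  # S[a, b] = sum p_a q_b
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[3, 1] + S[1, 3]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lambda <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  sq <- sum(Pc^2) + sum(Qc^2) - 2 * lambda
  sqrt(max(0, sq) / n)
}

# --- coordinate fixtures ----------------------------------------------

with_toy_coords <- function(mols) {
  ds <- generate_structures(ches_dataset(mols))
  ds$molecules
}

rotation_z <- function(theta)
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta),  cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
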