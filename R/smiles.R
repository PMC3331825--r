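# SMILES / SMARTS reading, writing and substructure matching.
#
# One shared reader covers both languages: SMILES atoms are concrete
# (element + aromatic flag), SMARTS atoms are predicates. The supported
# SMARTS subset is the one structural-alert files and mined linear
# fragments actually use: element symbols (aliphatic uppercase, aromatic
# lowercase), atomic-number primitives [#n], wildcards * / a / A, bond
# primitives - = # : ~ and the implicit single-or-aromatic default,
# branches, and ring closures. Charges and H-counts in brackets are parsed
# and ignored for matching (fragment-granularity semantics); recursive
# SMARTS and logical operators are rejected with an informative error.

.AROMATIC_ELEMENTS <- c("b", "c", "n", "o", "p", "s", "se", "as")
.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

.SYM2NUM <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12,
              Al = 13, Si = 14, P = 15, S = 16, Cl = 17, K = 19, Ca = 20,
              Fe = 26, Zn = 30, Se = 34, Br = 35, I = 53)

# --- shared reader -----------------------------------------------------

# Parses a SMILES or SMARTS string into atom specs + bond list.
# Returns list(atoms = list of spec lists, bonds = data.frame(i, j, type),
#              atom_end = integer character offsets) where type is one of
# "single","double","triple","aromatic","any","default".
.read_molstring <- function(s, smarts = FALSE) {
  chars <- strsplit(s, "")[[1]]
  np <- length(chars)
  atoms <- list()
  bonds <- list()
  atom_end <- integer(0)
  prev <- 0L            # atom the next bond attaches to (0 = none)
  pending <- NULL       # explicit bond symbol awaiting its atom
  branch <- integer(0)  # stack of prev atoms
  rings <- list()       # open ring closures: number -> list(atom, type)
  pos <- 1L

  bond_type_of <- function(sym) switch(sym,
    "-" = "single", "=" = "double", "#" = "triple", ":" = "aromatic",
    "~" = "any", "/" = "single", "\\" = "single",
    stop("unsupported bond symbol '", sym, "'"))

  add_atom <- function(spec, end_pos) {
    atoms[[length(atoms) + 1L]] <<- spec
    atom_end[length(atoms)] <<- end_pos
    a <- length(atoms)
    if (prev > 0L) {
      type <- if (!is.null(pending)) pending else "default"
      bonds[[length(bonds) + 1L]] <<- list(i = prev, j = a, type = type)
    }
    pending <<- NULL
    prev <<- a
  }

  close_ring <- function(num, end_pos) {
    key <- as.character(num)
    if (is.null(rings[[key]])) {
      rings[[key]] <<- list(atom = prev, type = pending)
      pending <<- NULL
    } else {
      open <- rings[[key]]
      rings[[key]] <<- NULL
      type <- if (!is.null(pending)) pending
              else if (!is.null(open$type)) open$type else "default"
      if (open$atom == prev) stop("ring closure bonds atom to itself")
      bonds[[length(bonds) + 1L]] <<- list(i = open$atom, j = prev, type = type)
      pending <<- NULL
    }
    atom_end[prev] <<- end_pos
  }

  while (pos <= np) {
    ch <- chars[pos]
    if (ch %in% c(" ", "\t")) break
    if (ch == "(") {
      branch <- c(branch, prev); pos <- pos + 1L
    } else if (ch == ")") {
      if (!length(branch)) stop("unbalanced ')' in '", s, "'")
      prev <- branch[length(branch)]; branch <- branch[-length(branch)]
      pos <- pos + 1L
    } else if (ch %in% c("-", "=", "#", ":", "~", "/", "\\")) {
      if (ch == "~" && !smarts) stop("'~' bond is SMARTS-only")
      pending <- bond_type_of(ch); pos <- pos + 1L
    } else if (ch == ".") {
      prev <- 0L; pending <- NULL; pos <- pos + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(as.integer(ch), pos); pos <- pos + 1L
    } else if (ch == "%") {
      if (pos + 2L > np) stop("truncated '%' ring closure")
      close_ring(as.integer(paste0(chars[pos + 1L], chars[pos + 2L])),
                 pos + 2L)
      pos <- pos + 3L
    } else if (ch == "[") {
      close_pos <- pos
      while (close_pos <= np && chars[close_pos] != "]") close_pos <- close_pos + 1L
      if (close_pos > np) stop("unterminated bracket atom in '", s, "'")
      body <- substr(s, pos + 1L, close_pos - 1L)
      add_atom(.parse_bracket(body, smarts, s), close_pos)
      pos <- close_pos + 1L
    } else {
      # bare atom: try two-letter organic symbols first
      two <- if (pos < np) paste0(ch, chars[pos + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(list(kind = "element", element = two, aromatic = FALSE),
                 pos + 1L)
        pos <- pos + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        add_atom(list(kind = "element", element = ch, aromatic = FALSE), pos)
        pos <- pos + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        add_atom(list(kind = "element", element = toupper(ch), aromatic = TRUE),
                 pos)
        pos <- pos + 1L
      } else if (smarts && ch == "*") {
        add_atom(list(kind = "any"), pos); pos <- pos + 1L
      } else if (smarts && ch == "a") {
        add_atom(list(kind = "arom"), pos); pos <- pos + 1L
      } else if (smarts && ch == "A") {
        add_atom(list(kind = "aliph"), pos); pos <- pos + 1L
      } else {
        stop("unsupported character '", ch, "' in '", s, "'")
      }
    }
  }
  if (length(branch)) stop("unbalanced '(' in '", s, "'")
  open_rings <- names(rings)[!vapply(rings, is.null, logical(1))]
  if (length(open_rings))
    stop("unclosed ring bond(s) ", paste(open_rings, collapse = ", "),
         " in '", s, "'")
  if (!length(atoms)) stop("no atoms in '", s, "'")
  bonds <- if (length(bonds)) {
    data.frame(i = vapply(bonds, `[[`, integer(1), "i"),
               j = vapply(bonds, `[[`, integer(1), "j"),
               type = vapply(bonds, `[[`, character(1), "type"),
               stringsAsFactors = FALSE)
  } else data.frame(i = integer(0), j = integer(0), type = character(0))
  list(atoms = atoms, bonds = bonds, atom_end = atom_end)
}

# Bracket-atom body, e.g. "#35", "nH", "O-", "13CH4" (isotope ignored).
.parse_bracket <- function(body, smarts, context) {
  rest <- body
  eat <- function(pattern) {
    m <- regmatches(rest, regexpr(pattern, rest))
    if (length(m) && nchar(m)) { rest <<- substr(rest, nchar(m) + 1L, nchar(rest)); m }
    else NULL
  }
  if (grepl("[$,;!]", body))
    stop("unsupported SMARTS construct in [", body, "] (pattern '",
         context, "')")
  eat("^[0-9]+")  # isotope, ignored
  spec <- NULL
  if (!is.null(num <- eat("^#[0-9]+"))) {
    spec <- list(kind = "atomnum", num = as.integer(sub("#", "", num)))
  } else if (!is.null(eat("^\\*"))) {
    spec <- list(kind = "any")
  } else if (!is.null(sym <- eat("^se|^as"))) {
    spec <- list(kind = "element",
                 element = paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, 2)),
                 aromatic = TRUE)
  } else if (!is.null(sym <- eat("^[A-Z][a-z]?"))) {
    # try two-letter symbol; fall back to one letter if unknown
    if (!sym %in% names(.SYM2NUM) && nchar(sym) == 2L) {
      rest <- paste0(substr(sym, 2, 2), rest)
      sym <- substr(sym, 1, 1)
    }
    spec <- list(kind = "element", element = sym, aromatic = FALSE)
  } else if (!is.null(sym <- eat("^[bcnops]"))) {
    spec <- list(kind = "element", element = toupper(sym), aromatic = TRUE)
  } else {
    stop("cannot parse bracket atom [", body, "] in '", context, "'")
  }
  eat("^@{1,2}")  # chirality, ignored
  hc <- 0L; hfixed <- FALSE
  if (!is.null(h <- eat("^H[0-9]*"))) {
    hc <- if (nchar(h) > 1L) as.integer(substr(h, 2, nchar(h))) else 1L
    hfixed <- TRUE
  }
  charge <- 0L
  if (!is.null(cg <- eat("^\\+[0-9]*|^-[0-9]*|^\\++|^-+"))) {
    sign <- if (substr(cg, 1, 1) == "+") 1L else -1L
    digits <- gsub("[+-]", "", cg)
    charge <- if (nchar(digits)) sign * as.integer(digits)
              else sign * nchar(cg)
  }
  if (nchar(rest))
    stop("unsupported token '", rest, "' in bracket atom [", body,
         "] of '", context, "'")
  spec$charge <- charge
  spec$hcount <- hc
  spec$hfixed <- hfixed
  spec
}

# --- SMILES ------------------------------------------------------------

#' Parse a SMILES string into a molecule graph
#'
#' Supports the organic subset, bracket atoms with charge/H-count/isotope,
#' branches, ring closures (including `%nn`), aromatic lowercase notation
#' and disconnected components (`.`). Aromatic flags are taken from the
#' notation and frozen; implicit hydrogens are completed from standard
#' valences.
#'
#' @param smiles a single SMILES string
#' @param id compound identifier to attach
#' @return a [molecule_graph()]
#' @export
#' @examples
#' parse_smiles("Oc1ccc(Br)cc1", id = "p-bromophenol")
parse_smiles <- function(smiles, id = "") {
  parsed <- .read_molstring(smiles, smarts = FALSE)
  specs <- parsed$atoms
  bad <- vapply(specs, function(a) a$kind != "element", logical(1))
  if (any(bad)) stop("wildcard atoms are not valid in SMILES: '", smiles, "'")
  atoms <- data.frame(
    element = vapply(specs, `[[`, character(1), "element"),
    charge = vapply(specs, function(a) as.integer(a$charge %||% 0L), integer(1)),
    aromatic = vapply(specs, `[[`, logical(1), "aromatic"),
    stringsAsFactors = FALSE)
  atoms$hcount <- vapply(specs, function(a)
    if (isTRUE(a$hfixed)) as.integer(a$hcount) else NA_integer_, integer(1))
  atoms$hfixed <- vapply(specs, function(a) isTRUE(a$hfixed), logical(1))
  b <- parsed$bonds
  if (nrow(b)) {
    arom_atom <- atoms$aromatic
    resolve <- function(type, i, j) {
      if (type == "default")
        if (arom_atom[i] && arom_atom[j]) "aromatic" else "single"
      else type
    }
    type <- mapply(resolve, b$type, b$i, b$j)
    order <- ifelse(type == "single", 1L,
             ifelse(type == "double", 2L,
             ifelse(type == "triple", 3L, 1L)))
    bonds <- data.frame(i = b$i, j = b$j, order = as.integer(order),
                        aromatic = type == "aromatic")
  } else bonds <- NULL
  mol <- molecule_graph(atoms, bonds, id = id)
  attr(mol, "atom_end") <- parsed$atom_end
  mol
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- SMARTS ------------------------------------------------------------

#' Parse a SMARTS pattern
#'
#' @param pattern SMARTS string (see the supported subset in the package
#'   vignette). The pattern must be connected.
#' @return an object of class `smarts_pattern` with `atoms` (predicate
#'   specs), `bonds` and `natoms`.
#' @export
parse_smarts <- function(pattern) {
  parsed <- tryCatch(.read_molstring(pattern, smarts = TRUE),
                     error = function(e)
                       stop("invalid SMARTS '", pattern, "': ",
                            conditionMessage(e), call. = FALSE))
  pat <- structure(
    list(atoms = parsed$atoms, bonds = parsed$bonds,
         natoms = length(parsed$atoms), string = pattern),
    class = "smarts_pattern")
  if (pat$natoms > 1L) {
    # connectivity check (matching walks the pattern from a seed atom)
    adj <- .pattern_adjacency(pat)
    seen <- logical(pat$natoms); seen[1] <- TRUE; queue <- 1L
    while (length(queue)) {
      a <- queue[[1]]; queue <- queue[-1]
      nb <- adj[[a]]$nbr[!seen[adj[[a]]$nbr]]
      seen[nb] <- TRUE; queue <- c(queue, nb)
    }
    if (!all(seen))
      stop("disconnected SMARTS patterns are not supported: '", pattern, "'")
  }
  pat
}

#' @export
print.smarts_pattern <- function(x, ...) {
  cat(sprintf("<smarts_pattern> %s (%d atoms, %d bonds)\n",
              x$string, x$natoms, nrow(x$bonds)))
  invisible(x)
}

.pattern_adjacency <- function(pat) {
  adj <- lapply(seq_len(pat$natoms), function(a)
    list(nbr = integer(0), bond = integer(0)))
  for (r in seq_len(nrow(pat$bonds))) {
    i <- pat$bonds$i[r]; j <- pat$bonds$j[r]
    adj[[i]]$nbr <- c(adj[[i]]$nbr, j); adj[[i]]$bond <- c(adj[[i]]$bond, r)
    adj[[j]]$nbr <- c(adj[[j]]$nbr, i); adj[[j]]$bond <- c(adj[[j]]$bond, r)
  }
  adj
}

.atom_matches <- function(spec, mol, a) {
  el <- mol$atoms$element[a]
  arom <- mol$atoms$aromatic[a]
  switch(spec$kind,
    any = TRUE,
    arom = arom,
    aliph = !arom,
    atomnum = identical(unname(.SYM2NUM[el]), as.numeric(spec$num)),
    element = el == spec$element &&
      (is.na(spec$aromatic) || arom == spec$aromatic),
    stop("unknown atom spec kind: ", spec$kind))
}

.bond_matches <- function(type, mol, bond_row) {
  arom <- mol$bonds$aromatic[bond_row]
  ord <- mol$bonds$order[bond_row]
  switch(type,
    any = TRUE,
    default = arom || (!arom && ord == 1L),  # SMARTS single-or-aromatic
    aromatic = arom,
    single = !arom && ord == 1L,
    double = !arom && ord == 2L,
    triple = !arom && ord == 3L,
    stop("unknown bond type: ", type))
}

#' Match a SMARTS pattern against a molecule
#'
#' Backtracking subgraph matching. Every distinct embedding is returned as
#' an integer vector of molecule atom indices in pattern-atom order; an
#' empty list means no match. Boolean containment is `length(result) > 0`.
#'
#' @param pattern SMARTS string or a parsed `smarts_pattern`
#' @param molecule a [molecule_graph()]
#' @param max_matches stop after this many embeddings (safety cap)
#' @return list of integer vectors (possibly empty)
#' @export
#' @examples
#' mol <- parse_smiles("Oc1cccc(Br)c1")
#' length(match_smarts("Br-c:c:c-O", mol)) > 0
match_smarts <- function(pattern, molecule, max_matches = 10000L) {
  pat <- if (inherits(pattern, "smarts_pattern")) pattern
         else parse_smarts(pattern)
  stopifnot(inherits(molecule, "molecule_graph"))
  np <- pat$natoms
  nm <- nrow(molecule$atoms)
  if (np > nm) return(list())
  padj <- .pattern_adjacency(pat)
  madj <- adjacency(molecule)

  # visit pattern atoms in a connected order: each atom after the first is
  # adjacent to an already-visited atom
  order <- 1L
  visited <- logical(np); visited[1] <- TRUE
  anchor <- integer(np)  # pattern bond used to reach each visited atom
  while (length(order) < np) {
    found <- FALSE
    for (a in order) {
      for (k in seq_along(padj[[a]]$nbr)) {
        b <- padj[[a]]$nbr[k]
        if (!visited[b]) {
          order <- c(order, b); visited[b] <- TRUE
          anchor[b] <- padj[[a]]$bond[k]
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    if (!found) break
  }

  matches <- list()
  map <- integer(np)  # pattern atom -> molecule atom (0 = unmapped)

  consistent <- function(pa, ma) {
    if (!.atom_matches(pat$atoms[[pa]], molecule, ma)) return(FALSE)
    # all pattern bonds from pa to already-mapped atoms must exist + match
    for (k in seq_along(padj[[pa]]$nbr)) {
      pb <- padj[[pa]]$nbr[k]
      if (map[pb] == 0L) next
      mb <- map[pb]
      hit <- which(madj[[ma]]$nbr == mb)
      if (!length(hit)) return(FALSE)
      if (!.bond_matches(pat$bonds$type[padj[[pa]]$bond[k]], molecule,
                         madj[[ma]]$bond[hit[1]]))
        return(FALSE)
    }
    TRUE
  }

  recurse <- function(depth) {
    if (length(matches) >= max_matches) return()
    if (depth > np) {
      matches[[length(matches) + 1L]] <<- map
      return()
    }
    pa <- order[depth]
    cands <- if (depth == 1L) seq_len(nm) else {
      # restrict to neighbours of the mapped anchor atom
      arow <- pat$bonds[anchor[pa], ]
      prev_pat <- if (map[arow$i] != 0L) arow$i else arow$j
      madj[[map[prev_pat]]]$nbr
    }
    for (ma in cands) {
      if (ma %in% map[map != 0L]) next
      if (!consistent(pa, ma)) next
      map[pa] <<- ma
      recurse(depth + 1L)
      map[pa] <<- 0L
    }
  }
  recurse(1L)
  matches
}

# --- aromaticity perception -------------------------------------------

# Kekulized inputs (SD-files) carry no aromatic flags. A deliberately
# simple model is applied once at parse time and frozen: rings of size 5
# or 6 over C/N/O/S whose ring bonds alternate single/double (or are
# already flagged aromatic, e.g. V2000 order 4) are marked aromatic.
perceive_aromaticity <- function(mol) {
  if (any(mol$atoms$aromatic)) return(mol)  # trust input flags
  nb <- nrow(mol$bonds)
  if (nb == 0L) return(mol)
  adj <- adjacency(mol)
  n <- nrow(mol$atoms)
  candidate <- mol$atoms$element %in% c("C", "N", "O", "S")
  arom_atoms <- logical(n)
  arom_bonds <- logical(nb)
  # enumerate simple cycles of length <= 6 by DFS from each atom
  for (start in seq_len(n)) {
    if (!candidate[start]) next
    path <- start
    bonds_used <- integer(0)
    dfs <- function(a) {
      for (k in seq_along(adj[[a]]$nbr)) {
        b <- adj[[a]]$nbr[k]; br <- adj[[a]]$bond[k]
        if (b == start && length(path) >= 5L) {
          ring_b <- c(bonds_used, br)
          orders <- mol$bonds$order[ring_b]
          alt <- all(abs(diff(c(orders, orders[1]))) == 1L) &&
                 all(orders %in% c(1L, 2L))
          if (alt || all(mol$bonds$aromatic[ring_b])) {
            arom_atoms[path] <<- TRUE
            arom_bonds[ring_b] <<- TRUE
          }
        } else if (!(b %in% path) && candidate[b] && b > start &&
                   length(path) < 6L) {
          path <<- c(path, b); bonds_used <<- c(bonds_used, br)
          dfs(b)
          path <<- path[-length(path)]
          bonds_used <<- bonds_used[-length(bonds_used)]
        }
      }
    }
    dfs(start)
  }
  mol$atoms$aromatic <- mol$atoms$aromatic | arom_atoms
  mol$bonds$aromatic <- mol$bonds$aromatic | arom_bonds
  # recompute implicit H with the new aromatic bond orders
  mol$atoms$hcount <- NULL
  mol$atoms$hcount <- implicit_hydrogens(mol)
  mol
}

# --- writing -----------------------------------------------------------

.atom_symbol_out <- function(element, aromatic) {
  if (aromatic) {
    low <- tolower(element)
    if (low %in% .AROMATIC_ELEMENTS && nchar(low) == 1L) low
    else paste0("[", low, "]")
  } else if (element %in% .ORGANIC_SUBSET) element
  else paste0("[", element, "]")
}

.bond_symbol_out <- function(order, aromatic, explicit_single = TRUE) {
  if (aromatic) ":"
  else if (order == 1L) { if (explicit_single) "-" else "" }
  else if (order == 2L) "="
  else if (order == 3L) "#"
  else stop("cannot write bond of order ", order)
}

#' Write a molecule graph as a SMILES-compatible string
#'
#' Aromatic atoms are written lowercase with `:` ring bonds, aliphatic
#' single bonds explicitly as `-`, so the output doubles as a SMARTS
#' pattern; disconnected components are joined with `.`.
#'
#' @param mol a [molecule_graph()]
#' @return SMILES string
#' @export
write_smiles <- function(mol) {
  comp <- components(mol)
  parts <- vapply(unique(comp), function(cl) {
    atoms <- which(comp == cl)
    bonds <- which(mol$bonds$i %in% atoms & mol$bonds$j %in% atoms)
    subgraph_smarts(mol, atoms, bonds)
  }, character(1))
  paste(parts, collapse = ".")
}

# SMARTS for a connected subgraph of a molecule (DFS, ring-closure digits).
# Aliphatic single bonds are written explicitly as '-' so mined fragments
# are unambiguous under any standard engine.
subgraph_smarts <- function(mol, atom_idx, bond_rows) {
  sub_atoms <- sort(unique(atom_idx))
  bond_set <- mol$bonds[bond_rows, , drop = FALSE]
  local <- match(seq_len(nrow(mol$atoms)), sub_atoms)  # mol idx -> local idx
  nsub <- length(sub_atoms)
  adj <- lapply(seq_len(nsub), function(a) list(nbr = integer(0), bond = integer(0)))
  for (r in seq_len(nrow(bond_set))) {
    i <- local[bond_set$i[r]]; j <- local[bond_set$j[r]]
    adj[[i]]$nbr <- c(adj[[i]]$nbr, j); adj[[i]]$bond <- c(adj[[i]]$bond, r)
    adj[[j]]$nbr <- c(adj[[j]]$nbr, i); adj[[j]]$bond <- c(adj[[j]]$bond, r)
  }
  # pass 1: DFS spanning tree; non-tree edges become ring closures
  visited <- logical(nsub)
  tree_child <- vector("list", nsub)   # child atoms in DFS order
  tree_bond <- vector("list", nsub)    # bond row reaching each child
  back_edges <- list()                 # list of (a, b, bond row)
  seen_bond <- logical(nrow(bond_set))
  dfs <- function(a) {
    visited[a] <<- TRUE
    for (k in seq_along(adj[[a]]$nbr)) {
      b <- adj[[a]]$nbr[k]; br <- adj[[a]]$bond[k]
      if (seen_bond[br]) next
      seen_bond[br] <<- TRUE
      if (visited[b]) {
        back_edges[[length(back_edges) + 1L]] <<- list(a = a, b = b, bond = br)
      } else {
        tree_child[[a]] <<- c(tree_child[[a]], b)
        tree_bond[[a]] <<- c(tree_bond[[a]], br)
        dfs(b)
      }
    }
  }
  dfs(1L)
  if (!all(visited)) stop("subgraph is not connected")

  # assign ring-closure digits at both endpoints
  ring_at <- vector("list", nsub)  # per atom: list of (digit, bond row)
  for (d in seq_along(back_edges)) {
    e <- back_edges[[d]]
    ring_at[[e$a]] <- c(ring_at[[e$a]], list(list(digit = d, bond = e$bond)))
    ring_at[[e$b]] <- c(ring_at[[e$b]], list(list(digit = d, bond = e$bond)))
  }

  # pass 2: emit
  emit <- function(a, via_bond) {
    mi <- sub_atoms[a]
    out <- if (is.null(via_bond)) "" else
      .bond_symbol_out(bond_set$order[via_bond], bond_set$aromatic[via_bond])
    out <- paste0(out, .atom_symbol_out(mol$atoms$element[mi],
                                        mol$atoms$aromatic[mi]))
    for (rc in ring_at[[a]])
      out <- paste0(out, .bond_symbol_out(bond_set$order[rc$bond],
                                          bond_set$aromatic[rc$bond]),
                    rc$digit)
    kids <- tree_child[[a]]
    kb <- tree_bond[[a]]
    if (length(kids)) {
      parts <- vapply(seq_along(kids),
                      function(k) emit(kids[k], kb[k]), character(1))
      if (length(parts) > 1L)
        out <- paste0(out,
                      paste0("(", parts[-length(parts)], ")", collapse = ""),
                      parts[length(parts)])
      else out <- paste0(out, parts)
    }
    out
  }
  emit(1L, NULL)
}
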