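# Linear structural fragment mining (FP2-style simple-path enumeration)
# and SMARTS-based binary structural features.

#' Create a fragment feature
#'
#' A SMARTS-encoded substructure with its per-compound binary incidence.
#'
#' @param smarts pattern string
#' @param natoms atom count of the fragment
#' @param incidence integer 0/1 vector over compounds (or `NULL` for a
#'   template loaded from a SMARTS file, before matching)
#' @param name optional display name
#' @return an object of class `fragment_feature`; `frequency` is the
#'   number of 1s in the incidence
#' @export
fragment_feature <- function(smarts, natoms = NULL, incidence = NULL,
                             name = NULL) {
  if (is.null(natoms)) natoms <- parse_smarts(smarts)$natoms
  stopifnot(natoms >= 1)
  if (!is.null(incidence)) {
    incidence <- as.integer(incidence)
    stopifnot(all(incidence %in% c(0L, 1L)))
  }
  structure(list(smarts = smarts, natoms = as.integer(natoms),
                 incidence = incidence,
                 frequency = if (is.null(incidence)) NA_integer_
                             else sum(incidence),
                 name = name %||% smarts),
            class = "fragment_feature")
}

#' @export
print.fragment_feature <- function(x, ...) {
  cat(sprintf("<fragment_feature> %s (%d atoms, frequency %s)\n",
              x$smarts, x$natoms,
              if (is.na(x$frequency)) "unmatched" else x$frequency))
  invisible(x)
}

# canonical encoding of one simple path: lexicographically smaller of the
# two directional atom/bond strings
.canonical_path_string <- function(mol, atom_path, bond_path) {
  asym <- vapply(atom_path, function(a)
    .atom_symbol_out(mol$atoms$element[a], mol$atoms$aromatic[a]),
    character(1))
  bsym <- vapply(bond_path, function(r)
    .bond_symbol_out(mol$bonds$order[r], mol$bonds$aromatic[r]),
    character(1))
  interleave <- function(a, b) {
    out <- character(length(a) + length(b))
    out[seq_along(a) * 2L - 1L] <- a
    if (length(b)) out[seq_along(b) * 2L] <- b
    paste(out, collapse = "")
  }
  fwd <- interleave(asym, bsym)
  rev_ <- interleave(rev(asym), rev(bsym))
  if (fwd <= rev_) fwd else rev_
}

#' Enumerate all linear fragments of a molecule set
#'
#' Mines every distinct simple path (no repeated atoms) of 1 to
#' `max_atoms` atoms over the molecular graphs, with atoms labelled by
#' element and aromaticity and bonds by order/aromaticity — the FP2-style
#' linear fragment enumeration. Each path is counted once via the
#' lexicographically smaller of its two directional encodings; incidence
#' is compound-level (a fragment is either present in a compound or not).
#'
#' @param molecules list of [molecule_graph()] objects
#' @param max_atoms largest fragment size in atoms (default 7)
#' @return list of [fragment_feature()] objects, one per distinct
#'   fragment, with incidence over `molecules`
#' @export
#' @examples
#' frags <- enumerate_linear_fragments(list(parse_smiles("CCO")))
#' vapply(frags, `[[`, character(1), "smarts")  # C, O, C-C, C-O, C-C-O
enumerate_linear_fragments <- function(molecules, max_atoms = 7L) {
  stopifnot(max_atoms >= 1)
  if (!length(molecules)) stop("empty molecule list")
  nmol <- length(molecules)
  seen <- new.env(parent = emptyenv())  # smarts -> integer molecule set
  for (m in seq_len(nmol)) {
    mol <- molecules[[m]]
    adj <- adjacency(mol)
    n <- nrow(mol$atoms)
    local <- new.env(parent = emptyenv())
    extend <- function(atom_path, bond_path) {
      key <- .canonical_path_string(mol, atom_path, bond_path)
      assign(key, TRUE, envir = local)
      if (length(atom_path) >= max_atoms) return()
      tip <- atom_path[length(atom_path)]
      for (k in seq_along(adj[[tip]]$nbr)) {
        nxt <- adj[[tip]]$nbr[k]
        if (nxt %in% atom_path) next
        extend(c(atom_path, nxt), c(bond_path, adj[[tip]]$bond[k]))
      }
    }
    for (a in seq_len(n)) extend(a, integer(0))
    for (key in ls(local)) {
      hit <- if (exists(key, envir = seen, inherits = FALSE))
        get(key, envir = seen) else integer(0)
      assign(key, c(hit, m), envir = seen)
    }
  }
  keys <- ls(seen)
  frags <- lapply(keys, function(key) {
    inc <- integer(nmol)
    inc[get(key, envir = seen)] <- 1L
    natoms <- length(gregexpr("\\[[^]]+\\]|Cl|Br|[BCNOPSFIbcnops]",
                              key)[[1]])
    fragment_feature(key, natoms = natoms, incidence = inc)
  })
  frags
}

#' Filter mined fragments into the final feature set
#'
#' Keeps fragments matched by at least `min_frequency` compounds and,
#' with `skip_omnipresent`, drops uninformative fragments occurring in
#' every compound. Output order is deterministic: descending atom count,
#' then ascending SMARTS.
#'
#' @param fragments list of [fragment_feature()] with incidence filled
#' @param min_frequency minimum number of matched compounds (default 2)
#' @param skip_omnipresent drop fragments present in all compounds
#'   (default TRUE)
#' @param n_compounds total number of compounds
#' @return filtered, ordered list of fragment features (may be empty)
#' @export
build_fragment_features <- function(fragments, min_frequency = 2L,
                                    skip_omnipresent = TRUE, n_compounds) {
  stopifnot(min_frequency >= 1)
  freq <- vapply(fragments, `[[`, integer(1), "frequency")
  if (anyNA(freq)) stop("fragment incidence not computed")
  keep <- freq >= min_frequency
  if (skip_omnipresent) keep <- keep & freq < n_compounds
  out <- fragments[keep]
  if (!length(out)) return(out)
  natoms <- vapply(out, `[[`, integer(1), "natoms")
  smarts <- vapply(out, `[[`, character(1), "smarts")
  out[order(-natoms, smarts)]
}

#' Load SMARTS patterns from a file
#'
#' One pattern per line, optionally followed by a whitespace-separated
#' name; lines starting with `#` are comments (inline `#` cannot be a
#' comment marker because it denotes a triple bond or atomic number in
#' SMARTS). Patterns are validated eagerly.
#'
#' @param path SMARTS file
#' @return list of [fragment_feature()] templates (incidence unfilled)
#' @export
load_smarts_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (k in seq_along(lines)) {
    line <- trimws(lines[k])
    if (!nzchar(line) || startsWith(line, "#")) next
    parts <- strsplit(line, "[ \t]+")[[1]]
    pat <- tryCatch(parse_smarts(parts[1]), error = function(e) e)
    if (inherits(pat, "error"))
      stop("invalid SMARTS on line ", k, " of ", path, ": ",
           conditionMessage(pat))
    out[[length(out) + 1L]] <-
      fragment_feature(parts[1], natoms = pat$natoms,
                       name = if (length(parts) > 1L)
                         paste(parts[-1], collapse = " ") else NULL)
  }
  out
}

#' Compute incidence of fragment templates over a molecule set
#'
#' @param fragments list of [fragment_feature()] (e.g. from
#'   [load_smarts_file()])
#' @param molecules list of [molecule_graph()]
#' @return the fragments with incidence and frequency filled
#' @export
fragment_incidence <- function(fragments, molecules) {
  lapply(fragments, function(f) {
    pat <- parse_smarts(f$smarts)
    inc <- vapply(molecules, function(mol)
      as.integer(length(match_smarts(pat, mol, max_matches = 1L)) > 0L),
      integer(1))
    fragment_feature(f$smarts, natoms = f$natoms, incidence = inc,
                     name = f$name)
  })
}

#' Convert fragment features to binary nominal feature columns
#'
#' @param fragments fragment features with incidence filled
#' @return list of [feature_column()] (fragment origin, values "0"/"1")
#' @export
fragment_feature_columns <- function(fragments) {
  lapply(fragments, function(f) {
    if (is.null(f$incidence)) stop("fragment incidence not computed")
    feature_column(f$name, as.character(f$incidence), ftype = "nominal",
                   origin = "fragment", smarts = f$smarts)
  })
}

#' Write fragments as a SMARTS file
#' @param fragments fragment features
#' @param path output file
#' @return `path`, invisibly
#' @export
write_smarts_file <- function(fragments, path) {
  writeLines(vapply(fragments, function(f)
    if (identical(f$name, f$smarts)) f$smarts
    else paste(f$smarts, f$name), character(1)), path)
  invisible(path)
}

#' Binary incidence matrix of fragment features
#' @param fragments fragment features with incidence filled
#' @param ids optional compound ids used as row names
#' @return integer matrix, compounds x fragments
#' @export
incidence_matrix <- function(fragments, ids = NULL) {
  M <- vapply(fragments, `[[`, integer(length(fragments[[1]]$incidence)),
              "incidence")
  M <- matrix(M, ncol = length(fragments))
  colnames(M) <- vapply(fragments, `[[`, character(1), "smarts")
  if (!is.null(ids)) rownames(M) <- ids
  M
}
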