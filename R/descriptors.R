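# Built-in numeric descriptors plus a pluggable provider registry for
# sophisticated descriptors (LogP etc.) that are deliberately not
# approximated in-house.

.descriptor_registry <- new.env(parent = emptyenv())

.BUILTIN_DESCRIPTORS <- c("molecular_weight", "heavy_atom_count",
                          "ring_count", "rotatable_bond_count",
                          "halogen_count")

.builtin_descriptor <- function(name, mol) {
  switch(name,
    molecular_weight = molecular_weight(mol),
    heavy_atom_count = sum(mol$atoms$element != "H"),
    # smallest-set-of-smallest-rings cardinality = cycle rank
    ring_count = nrow(mol$bonds) - nrow(mol$atoms) +
      length(unique(components(mol))),
    rotatable_bond_count = {
      b <- mol$bonds
      if (!nrow(b)) 0 else {
        ring <- ring_bonds(mol)
        heavy_deg <- integer(nrow(mol$atoms))
        for (r in seq_len(nrow(b))) {
          if (mol$atoms$element[b$j[r]] != "H")
            heavy_deg[b$i[r]] <- heavy_deg[b$i[r]] + 1L
          if (mol$atoms$element[b$i[r]] != "H")
            heavy_deg[b$j[r]] <- heavy_deg[b$j[r]] + 1L
        }
        sum(b$order == 1L & !b$aromatic & !ring &
              heavy_deg[b$i] >= 2L & heavy_deg[b$j] >= 2L)
      }
    },
    halogen_count = sum(mol$atoms$element %in% .HALOGENS),
    stop("unknown builtin descriptor: ", name))
}

#' Register a delegate descriptor provider
#'
#' Sophisticated descriptors (LogP, van der Waals volume, ...) are
#' delegate-only: supply a function of one [molecule_graph()] returning a
#' single numeric value. A failure on one molecule yields a missing value
#' plus a warning, not an abort.
#'
#' @param name descriptor name used in [compute_descriptors()] specs
#' @param fun function(molecule) -> numeric(1)
#' @return `name`, invisibly
#' @export
register_descriptor_provider <- function(name, fun) {
  stopifnot(is.function(fun))
  assign(name, fun, envir = .descriptor_registry)
  invisible(name)
}

#' Names of the built-in descriptors
#' @return character vector
#' @export
builtin_descriptors <- function() .BUILTIN_DESCRIPTORS

#' Compute numeric descriptors for a molecule set
#'
#' Built-ins: `molecular_weight` (standard atomic masses, implicit H from
#' standard valences), `heavy_atom_count`, `ring_count` (SSSR
#' cardinality), `rotatable_bond_count` (single, non-ring, non-aromatic
#' bonds whose both atoms have at least two heavy neighbours) and
#' `halogen_count`. Any other name must be a registered delegate
#' provider.
#'
#' @param molecules list of [molecule_graph()]
#' @param specs character vector of descriptor names
#' @return list of numeric [feature_column()]s, origin "descriptor"
#' @export
#' @examples
#' compute_descriptors(list(parse_smiles("CCCC")),
#'                     c("molecular_weight", "rotatable_bond_count"))
compute_descriptors <- function(molecules, specs) {
  stopifnot(length(specs) >= 1)
  lapply(specs, function(name) {
    vals <- if (name %in% .BUILTIN_DESCRIPTORS) {
      vapply(molecules, function(m) .builtin_descriptor(name, m), numeric(1))
    } else if (exists(name, envir = .descriptor_registry, inherits = FALSE)) {
      fun <- get(name, envir = .descriptor_registry)
      vapply(molecules, function(m) {
        v <- tryCatch(as.numeric(fun(m)), error = function(e) {
          warning("descriptor '", name, "' failed for compound '", m$id,
                  "': ", conditionMessage(e))
          NA_real_
        })
        if (length(v) != 1L) NA_real_ else v
      }, numeric(1))
    } else {
      stop("unknown descriptor '", name, "'; builtins are: ",
           paste(.BUILTIN_DESCRIPTORS, collapse = ", "),
           "; or register a delegate provider")
    }
    feature_column(name, vals, ftype = "numeric", origin = "descriptor")
  })
}
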