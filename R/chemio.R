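# Dataset input/output: SD-files (via ChemmineR), SMILES lists, CSV
# feature tables, and annotated SD-file export.

#' Create a feature column
#'
#' @param name column name
#' @param values one value per compound; character or numeric; `NA`, `""`
#'   and `"NA"` are missing markers (never coerced to 0)
#' @param ftype "numeric" or "nominal"; guessed with
#'   [guess_feature_type()] when `NULL` (ambiguous 0/1 columns default to
#'   nominal)
#' @param origin "dataset", "descriptor" or "fragment"
#' @param smarts SMARTS string for fragment-origin columns
#' @return an object of class `feature_column`
#' @export
feature_column <- function(name, values, ftype = NULL,
                           origin = c("dataset", "descriptor", "fragment"),
                           smarts = NULL) {
  origin <- match.arg(origin)
  if (is.numeric(values) && (is.null(ftype) || ftype == "numeric")) {
    # numeric input kept at full precision (no string round-trip)
    return(structure(list(name = name, ftype = "numeric",
                          values = as.numeric(values), origin = origin,
                          smarts = smarts, type_guess = NULL),
                     class = "feature_column"))
  }
  raw <- as.character(values)
  raw[!is.na(raw) & (raw == "" | raw == "NA")] <- NA
  guessed <- NULL
  if (is.null(ftype)) {
    guessed <- guess_feature_type(raw)
    ftype <- if (guessed == "numeric") "numeric" else "nominal"
  }
  ftype <- match.arg(ftype, c("numeric", "nominal"))
  vals <- if (ftype == "numeric") {
    num <- suppressWarnings(as.numeric(raw))
    if (any(is.na(num) & !is.na(raw)))
      stop("column '", name, "': non-numeric value in a numeric column")
    num
  } else raw
  if (origin == "fragment") {
    ok <- is.na(vals) | vals %in% c("0", "1")
    if (ftype != "nominal" || !all(ok))
      stop("fragment-origin columns must be binary nominal (0/1)")
  }
  structure(list(name = name, ftype = ftype, values = vals,
                 origin = origin, smarts = smarts,
                 type_guess = guessed),
            class = "feature_column")
}

#' Guess whether raw feature values are numeric or nominal
#'
#' Numeric iff every non-missing value parses as a real number and the
#' distinct values are not all in \{0, 1\}; nominal if any value fails to
#' parse; ambiguous (defaulted to nominal, user-overridable) when all
#' values parse but the distinct set is within \{0, 1\}.
#'
#' @param values character vector of raw values; `NA`, `""` and `"NA"` are
#'   missing
#' @return "numeric", "nominal" or "ambiguous"
#' @export
#' @examples
#' guess_feature_type(c("1.2", "3.4", "-0.5"))   # numeric
#' guess_feature_type(c("active", "inactive"))   # nominal
#' guess_feature_type(c("0", "1", "0"))          # ambiguous
guess_feature_type <- function(values) {
  raw <- as.character(values)
  raw[!is.na(raw) & (raw == "" | raw == "NA")] <- NA
  present <- raw[!is.na(raw)]
  if (!length(present)) stop("cannot guess the type of an all-missing column")
  num <- suppressWarnings(as.numeric(present))
  if (anyNA(num)) return("nominal")
  if (all(unique(num) %in% c(0, 1))) return("ambiguous")
  "numeric"
}

#' Assemble a dataset of molecules and feature columns
#'
#' @param molecules list of [molecule_graph()] objects
#' @param features list of [feature_column()] objects (each with one value
#'   per molecule)
#' @param name dataset name
#' @return an object of class `ches_dataset`; `has3d` is TRUE iff every
#'   molecule carries non-flat 3D coordinates
#' @export
ches_dataset <- function(molecules, features = list(), name = "dataset") {
  stopifnot(length(molecules) >= 1)
  n <- length(molecules)
  for (f in features)
    if (length(f$values) != n)
      stop("feature column '", f$name, "' has ", length(f$values),
           " values for ", n, " molecules")
  ids <- vapply(molecules, function(m) m$id, character(1))
  blank <- !nzchar(ids)
  ids[blank] <- as.character(which(blank))
  if (anyDuplicated(ids)) {
    warning("duplicate compound ids; suffixing duplicates")
    ids <- make.unique(ids, sep = "_")
    for (k in seq_len(n)) molecules[[k]]$id <- ids[k]
  } else {
    for (k in seq_len(n)) molecules[[k]]$id <- ids[k]
  }
  names(features) <- vapply(features, `[[`, character(1), "name")
  has3d <- all(vapply(molecules, function(m)
    !is.null(m$coords) && any(abs(m$coords[, 3]) > 1e-8), logical(1)))
  structure(list(molecules = molecules, features = features,
                 name = name, has3d = has3d),
            class = "ches_dataset")
}

#' @export
print.ches_dataset <- function(x, ...) {
  cat(sprintf("<ches_dataset> '%s': %d compounds, %d features, 3D: %s\n",
              x$name, length(x$molecules), length(x$features),
              if (x$has3d) "yes" else "no"))
  invisible(x)
}

#' Compound identifiers of a dataset
#' @param dataset a `ches_dataset`
#' @return character vector of ids
#' @export
compound_ids <- function(dataset)
  vapply(dataset$molecules, function(m) m$id, character(1))

# --- reading -----------------------------------------------------------

#' Read a molecular dataset from SDF, SMILES or CSV
#'
#' SD property tags become dataset-origin feature columns (missing where a
#' record lacks the tag). SMILES files may carry whitespace-separated ids.
#' A sibling CSV feature table can be joined on compound id or row order.
#' Unparseable records are collected and reported as a warning; the read
#' fails only if no molecule parses.
#'
#' @param path input file
#' @param format "sdf", "smiles" or "csv"; inferred from the extension
#'   when `NULL`
#' @param csv optional path of a CSV feature table to join
#' @param id_column id column of the CSV (default: a column named "id",
#'   case-insensitively, else the first column); set to `NA` to join on
#'   row order
#' @param name dataset name (default: file base name)
#' @return a [ches_dataset()]
#' @export
read_dataset <- function(path, format = NULL, csv = NULL, id_column = NULL,
                         name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sdf = , sd = , mol = "sdf",
                     smi = , smiles = , ism = "smiles",
                     csv = "csv",
                     stop("cannot infer format from extension '.", ext,
                          "'; pass `format`"))
  }
  format <- match.arg(format, c("sdf", "smiles", "csv"))
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  ds <- switch(format,
               sdf = .read_sdf_dataset(path, name),
               smiles = .read_smiles_dataset(path, name),
               csv = .read_csv_dataset(path, id_column, name))
  if (!is.null(csv)) ds <- join_feature_csv(ds, csv, id_column)
  ds
}

.read_sdf_dataset <- function(path, name) {
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  valid <- ChemmineR::validSDF(sdfset)
  errors <- which(!valid)
  sdfset <- sdfset[valid]
  if (length(sdfset) == 0L) stop("no molecule parsed from ", path)
  if (length(errors))
    warning("skipped unparseable SDF record(s): ",
            paste(errors, collapse = ", "))
  mols <- vector("list", length(sdfset))
  tags <- list()
  for (k in seq_along(sdfset)) {
    sdf <- sdfset[[k]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    element <- sub("_.*$", "", rownames(ab))
    atoms <- data.frame(element = element, charge = 0L, aromatic = FALSE,
                        stringsAsFactors = FALSE)
    bonds <- if (nrow(bb)) {
      ord <- as.integer(bb[, 3])
      data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                 order = ifelse(ord == 4L, 1L, ord),
                 aromatic = ord == 4L)
    } else NULL
    coords <- unname(ab[, 1:3, drop = FALSE])
    title <- ChemmineR::header(sdf)[["Molecule_Name"]]
    dat <- ChemmineR::datablock(sdf)
    id <- if (!is.null(title) && nzchar(trimws(title))) trimws(title)
          else if ("_Name" %in% names(dat) && nzchar(dat[["_Name"]]))
            dat[["_Name"]]
          else as.character(k)
    mol <- molecule_graph(atoms, bonds, coords = coords, id = id,
                          props = as.list(dat))
    mols[[k]] <- perceive_aromaticity(mol)
    tags[[k]] <- dat
  }
  all_tags <- unique(unlist(lapply(tags, names)))
  all_tags <- setdiff(all_tags, "_Name")
  features <- lapply(all_tags, function(tg) {
    vals <- vapply(tags, function(d)
      if (tg %in% names(d)) as.character(d[[tg]]) else NA_character_,
      character(1))
    feature_column(tg, vals, origin = "dataset")
  })
  ches_dataset(mols, features, name = name)
}

.read_smiles_dataset <- function(path, name) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no molecule parsed from ", path)
  mols <- list()
  failures <- character(0)
  for (k in seq_along(lines)) {
    parts <- strsplit(lines[k], "[ \t]+")[[1]]
    smi <- parts[1]
    id <- if (length(parts) > 1L) parts[2] else as.character(k)
    mol <- tryCatch(parse_smiles(smi, id = id), error = function(e) e)
    if (inherits(mol, "error"))
      failures <- c(failures, sprintf("line %d (%s): %s", k, smi,
                                      conditionMessage(mol)))
    else mols[[length(mols) + 1L]] <- mol
  }
  if (!length(mols))
    stop("no molecule parsed from ", path, ":\n",
         paste(failures, collapse = "\n"))
  if (length(failures))
    warning("skipped unparseable SMILES record(s):\n",
            paste(failures, collapse = "\n"))
  ches_dataset(mols, name = name)
}

.read_csv_dataset <- function(path, id_column, name) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  if (!nrow(tab)) stop("no molecule parsed from ", path)
  smi_col <- which(tolower(names(tab)) == "smiles")[1]
  if (is.na(smi_col))
    stop("CSV datasets require a 'smiles' column; ",
         "use `csv =` to join features onto an SDF/SMILES file instead")
  idc <- .resolve_id_column(tab, id_column, exclude = smi_col)
  mols <- list(); failures <- character(0)
  for (k in seq_len(nrow(tab))) {
    id <- if (is.na(idc)) as.character(k) else tab[[idc]][k]
    mol <- tryCatch(parse_smiles(tab[[smi_col]][k], id = id),
                    error = function(e) e)
    if (inherits(mol, "error"))
      failures <- c(failures, sprintf("row %d: %s", k, conditionMessage(mol)))
    else mols[[length(mols) + 1L]] <- mol
  }
  if (!length(mols))
    stop("no molecule parsed from ", path, ":\n",
         paste(failures, collapse = "\n"))
  if (length(failures)) {
    warning("skipped unparseable SMILES record(s):\n",
            paste(failures, collapse = "\n"))
    ok_rows <- setdiff(seq_len(nrow(tab)),
                       as.integer(sub("^row ([0-9]+).*", "\\1", failures)))
    tab <- tab[ok_rows, , drop = FALSE]
  }
  drop <- c(smi_col, if (!is.na(idc)) idc)
  features <- lapply(setdiff(seq_along(tab), drop), function(ci)
    feature_column(names(tab)[ci], tab[[ci]], origin = "dataset"))
  ches_dataset(mols, features, name = name)
}

.resolve_id_column <- function(tab, id_column, exclude = integer(0)) {
  if (is.null(id_column)) {
    hit <- which(tolower(names(tab)) == "id")[1]
    if (!is.na(hit)) return(hit)
    cand <- setdiff(seq_along(tab), exclude)[1]
    return(if (is.na(cand)) NA_integer_ else cand)
  }
  if (is.na(id_column)) return(NA_integer_)
  if (is.character(id_column)) {
    hit <- which(names(tab) == id_column)[1]
    if (is.na(hit)) stop("id column '", id_column, "' not found in CSV")
    return(hit)
  }
  as.integer(id_column)
}

#' Join a CSV feature table onto a dataset
#'
#' @param dataset a [ches_dataset()]
#' @param path CSV file with a header row
#' @param id_column id column (see [read_dataset()]); `NA` joins on row
#'   order
#' @return the dataset with the CSV columns appended as dataset-origin
#'   features
#' @export
join_feature_csv <- function(dataset, path, id_column = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  n <- length(dataset$molecules)
  idc <- .resolve_id_column(tab, id_column)
  if (is.na(idc)) {
    if (nrow(tab) != n)
      stop("CSV has ", nrow(tab), " rows for ", n,
           " compounds (row-order join)")
    ord <- seq_len(n)
    drop <- integer(0)
  } else {
    ids <- compound_ids(dataset)
    ord <- match(ids, tab[[idc]])
    if (anyNA(ord))
      stop("CSV join: no row for compound id(s) ",
           paste(ids[is.na(ord)], collapse = ", "))
    drop <- idc
  }
  for (ci in setdiff(seq_along(tab), drop)) {
    cname <- names(tab)[ci]
    if (cname %in% names(dataset$features)) {
      warning("CSV column '", cname, "' already present; skipped")
      next
    }
    dataset$features[[cname]] <-
      feature_column(cname, tab[[ci]][ord], origin = "dataset")
  }
  dataset
}

# --- writing -----------------------------------------------------------

.format_sdf_record <- function(mol, coords, tags) {
  n <- nrow(mol$atoms)
  b <- mol$bonds
  lines <- c(mol$id, "  chesmapr", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(b)))
  for (a in seq_len(n))
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              coords[a, 1], coords[a, 2], coords[a, 3],
                              mol$atoms$element[a]))
  if (nrow(b)) {
    # kekulized order is kept for aromatic bonds when known; order 1 with
    # the aromatic flag is written as 4 so round-trips re-perceive it
    ord <- ifelse(b$aromatic & b$order == 1L, 4L, b$order)
    for (r in seq_len(nrow(b)))
      lines <- c(lines, sprintf("%3d%3d%3d  0", b$i[r], b$j[r], ord[r]))
  }
  lines <- c(lines, "M  END")
  for (tg in names(tags)) {
    val <- tags[[tg]]
    if (is.na(val)) next
    lines <- c(lines, sprintf(">  <%s>", tg), as.character(val), "")
  }
  c(lines, "$$$$")
}

#' Export a dataset and scene as an annotated SD-file
#'
#' Writes a V2000 SD-file with one record per kept compound. Atom
#' coordinates are the compound's (aligned) structure translated to its
#' embedding-space position (or the original coordinates with
#' `embed_coords = FALSE`). Each record carries SD tags for the cluster
#' label, the embedding x/y/z, and every selected feature; missing feature
#' values omit the tag.
#'
#' @param dataset a [ches_dataset()]
#' @param scene a [build_scene()] result (or `NULL` for a plain dump)
#' @param path output file
#' @param keep integer indices of compounds to export (default: the
#'   scene's kept compounds, else all)
#' @param features names of feature columns to write (default all)
#' @param embed_coords place structures at embedding positions (default
#'   TRUE when a scene is given)
#' @return `path`, invisibly
#' @export
export_sdf <- function(dataset, scene = NULL, path, keep = NULL,
                       features = NULL, embed_coords = !is.null(scene)) {
  n <- length(dataset$molecules)
  if (is.null(keep)) keep <- if (!is.null(scene)) scene$kept else seq_len(n)
  keep <- sort(unique(as.integer(keep)))
  if (!length(keep)) stop("nothing to export")
  if (any(keep < 1L | keep > n)) stop("keep indices out of range")
  if (!is.null(scene) && !all(keep %in% scene$kept))
    stop("scene does not cover all kept compounds")
  if (is.null(features)) features <- names(dataset$features)
  out <- character(0)
  for (idx in keep) {
    mol <- dataset$molecules[[idx]]
    base <- if (!is.null(mol$coords)) mol$coords
            else matrix(0, nrow(mol$atoms), 3)
    if (!is.null(scene) && embed_coords) {
      srow <- match(idx, scene$kept)
      tr <- scene$transforms[[idx]]
      if (!is.null(tr)) base <- apply_transform(tr, base)
      ctr <- colMeans(base)
      base <- sweep(base, 2, ctr) +
        matrix(scene$positions[srow, ] * scene$space_scale,
               nrow(base), 3, byrow = TRUE)
    }
    tags <- list()
    if (!is.null(scene)) {
      srow <- match(idx, scene$kept)
      tags[["cluster"]] <- scene$cluster_of[srow]
      tags[["embedding_x"]] <- scene$positions[srow, 1]
      tags[["embedding_y"]] <- scene$positions[srow, 2]
      tags[["embedding_z"]] <- scene$positions[srow, 3]
    }
    for (fname in features) {
      f <- dataset$features[[fname]]
      if (is.null(f)) stop("unknown feature column: ", fname)
      tags[[fname]] <- f$values[idx]
    }
    out <- c(out, .format_sdf_record(mol, base, tags))
  }
  writeLines(out, path)
  invisible(path)
}
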