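# Viewable scene data: positions, superimposition, highlight colors,
# representatives, histograms, view-level filtering and JSON export.

.QUALITATIVE_PALETTE <- c(
  "#E41A1C", "#377EB8", "#4DAF4A", "#984EA3", "#FF7F00", "#FFFF33",
  "#A65628", "#F781BF", "#999999", "#66C2A5", "#FC8D62", "#8DA0CB")

#' Build a scene from pipeline outputs
#'
#' Embedding coordinates are centred at the origin and uniformly scaled
#' so the bounding-box diagonal is 1; `space_scale` multiplies positions
#' at export (the viewer-side "+/-" space sizing).
#'
#' @param embedding an `embedding3d`
#' @param clustering a `cluster_result`
#' @param transforms optional list of per-compound [rigid_transform()]
#'   (NULL entries allowed)
#' @param ids compound identifiers
#' @param space_scale positive multiplier applied at export
#' @return an object of class `ches_scene`
#' @export
build_scene <- function(embedding, clustering, transforms = NULL,
                        ids = NULL, space_scale = 1) {
  stopifnot(space_scale > 0)
  Y <- embedding$Y
  n <- nrow(Y)
  stopifnot(length(clustering$labels) == n)
  Y <- sweep(Y, 2, colMeans(Y))
  diag_len <- sqrt(sum((apply(Y, 2, max) - apply(Y, 2, min))^2))
  if (diag_len > 0) Y <- Y / diag_len
  if (is.null(ids)) ids <- as.character(seq_len(n))
  structure(list(positions = Y, cluster_of = clustering$labels,
                 transforms = transforms, colors = list(),
                 space_scale = space_scale, superimposed = FALSE,
                 original_positions = NULL, ids = ids,
                 kept = seq_len(n),
                 embedding_method = embedding$method,
                 cluster_algorithm = clustering$algorithm),
            class = "ches_scene")
}

#' @export
print.ches_scene <- function(x, ...) {
  cat(sprintf(
    "<ches_scene> %d compounds, %d clusters (%s), embedding %s%s\n",
    length(x$kept), length(unique(x$cluster_of)), x$cluster_algorithm,
    x$embedding_method, if (x$superimposed) ", superimposed" else ""))
  invisible(x)
}

#' Superimpose cluster members at their cluster centre
#'
#' Moves every compound to the centroid of its cluster's positions; a
#' second call toggles back to the original positions exactly.
#'
#' @param scene a `ches_scene`
#' @return the modified scene
#' @export
superimpose <- function(scene) {
  if (scene$superimposed) {
    scene$positions <- scene$original_positions
    scene$original_positions <- NULL
    scene$superimposed <- FALSE
    return(scene)
  }
  scene$original_positions <- scene$positions
  for (cl in unique(scene$cluster_of)) {
    idx <- which(scene$cluster_of == cl)
    ctr <- colMeans(scene$positions[idx, , drop = FALSE])
    scene$positions[idx, ] <- matrix(ctr, length(idx), 3, byrow = TRUE)
  }
  scene$superimposed <- TRUE
  scene
}

#' Map a numeric value onto the blue-white-red gradient
#'
#' Linear two-segment gradient over the value range: the minimum maps to
#' blue (0,0,255), the midpoint to white (255,255,255), the maximum to
#' red (255,0,0). Constant columns map everything to white; missing
#' values get a neutral gray.
#'
#' @param values the feature's non-missing value range is taken from here
#' @param v value(s) to colour (default: all of `values`)
#' @param missing_color RGB triple for missing values
#' @return integer matrix with columns r, g, b (one row per `v`)
#' @export
value_to_color <- function(values, v = values,
                           missing_color = c(128L, 128L, 128L)) {
  rng <- range(values, na.rm = TRUE)
  if (!is.finite(rng[1])) stop("need at least one non-missing value")
  out <- matrix(rep(as.integer(missing_color), each = length(v)),
                length(v), 3, dimnames = list(NULL, c("r", "g", "b")))
  ok <- !is.na(v)
  if (rng[1] == rng[2]) {
    out[ok, ] <- 255L
    return(out)
  }
  mid <- mean(rng)
  for (i in which(ok)) {
    x <- v[i]
    if (x <= mid) {
      f <- (x - rng[1]) / (mid - rng[1])       # blue -> white
      out[i, ] <- as.integer(round(c(255 * f, 255 * f, 255)))
    } else {
      f <- (x - mid) / (rng[2] - mid)          # white -> red
      out[i, ] <- as.integer(round(c(255, 255 * (1 - f), 255 * (1 - f))))
    }
  }
  out
}

#' Distinct colors for nominal feature values
#'
#' Deterministic assignment from a fixed qualitative palette, ordered by
#' first occurrence; with more distinct values than palette entries the
#' palette cycles (with a warning).
#'
#' @param values character/factor vector of nominal values
#' @return named character vector value -> hex color
#' @export
nominal_colors <- function(values) {
  vals <- as.character(values)
  vals <- vals[!is.na(vals)]
  stopifnot(length(vals) >= 1)
  uniq <- unique(vals)
  if (length(uniq) > length(.QUALITATIVE_PALETTE))
    warning("more distinct values (", length(uniq),
            ") than palette colors; cycling")
  idx <- ((seq_along(uniq) - 1L) %% length(.QUALITATIVE_PALETTE)) + 1L
  stats::setNames(.QUALITATIVE_PALETTE[idx], uniq)
}

#' Select a cluster's representative compound
#'
#' The member whose feature value is the maximum, lower median or
#' minimum among members (painted solid in the superimposed view); the
#' remaining members are sorted accordingly — descending for "maximum",
#' ascending for "minimum" and "median". With an even member count the
#' lower median is taken. All-missing values fall back to the first
#' member in dataset order with a warning.
#'
#' @param cluster_members integer compound indices
#' @param values numeric feature values (full dataset vector)
#' @param mode "maximum", "median" or "minimum"
#' @return the representative's compound index, with the full member
#'   ordering in attribute "ordering"
#' @export
select_representative <- function(cluster_members,
                                  values,
                                  mode = c("maximum", "median", "minimum")) {
  mode <- match.arg(mode)
  stopifnot(length(cluster_members) >= 1)
  v <- values[cluster_members]
  if (all(is.na(v))) {
    warning("all feature values missing; using first member")
    rep_idx <- cluster_members[1]
    ord <- cluster_members
  } else {
    ord_idx <- order(v, na.last = TRUE,
                     decreasing = (mode == "maximum"))
    ord <- cluster_members[ord_idx]
    rep_idx <- switch(mode,
      maximum = ord[1],
      minimum = ord[1],
      median = ord[ceiling(sum(!is.na(v)) / 2)])  # lower median
  }
  attr(rep_idx, "ordering") <- ord
  rep_idx
}

#' Histogram of a numeric feature
#'
#' Equal-width bins over the value range; bins are left-closed with the
#' rightmost bin closed on both sides, and counts sum to the number of
#' non-missing values. Constant columns yield a single degenerate bin.
#'
#' @param values numeric values (missing allowed)
#' @param n_bins number of bins
#' @return data.frame(lower, upper, count)
#' @export
feature_histogram <- function(values, n_bins = 10L) {
  v <- values[!is.na(values)]
  stopifnot(length(v) >= 1, n_bins >= 1)
  rng <- range(v)
  if (rng[1] == rng[2])
    return(data.frame(lower = rng[1], upper = rng[2], count = length(v)))
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  idx <- findInterval(v, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  data.frame(lower = edges[-length(edges)], upper = edges[-1],
             count = counts)
}

#' Remove compounds from a scene (view-level filter)
#'
#' The underlying dataset is untouched; export honours the filter.
#'
#' @param scene a `ches_scene`
#' @param indices compound indices (positions in the original dataset) to
#'   remove
#' @return the filtered scene
#' @export
scene_remove <- function(scene, indices) {
  indices <- unique(as.integer(indices))
  if (!all(indices %in% scene$kept)) stop("indices not in the scene")
  keep_rows <- which(!(scene$kept %in% indices))
  if (!length(keep_rows)) stop("cannot remove every compound")
  scene$positions <- scene$positions[keep_rows, , drop = FALSE]
  if (!is.null(scene$original_positions))
    scene$original_positions <-
      scene$original_positions[keep_rows, , drop = FALSE]
  scene$cluster_of <- scene$cluster_of[keep_rows]
  scene$ids <- scene$ids[keep_rows]
  scene$kept <- scene$kept[keep_rows]
  scene
}

#' Attach a highlight colouring to a scene
#'
#' @param scene a `ches_scene`
#' @param name highlight name
#' @param feature a [feature_column()]; numeric features use the
#'   blue-white-red gradient, nominal ones the qualitative palette. With
#'   `feature = NULL` an "element-color" marker is stored (CPK colouring
#'   is a renderer concern).
#' @return the scene with `colors[[name]]` filled (hex strings, one per
#'   kept compound)
#' @export
scene_highlight <- function(scene, name, feature = NULL) {
  if (is.null(feature)) {
    scene$colors[[name]] <- list(mode = "element-color")
    return(scene)
  }
  vals <- feature$values[scene$kept]
  hex <- if (feature$ftype == "numeric") {
    rgb <- value_to_color(vals)
    grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
  } else {
    pal <- nominal_colors(vals)
    unname(ifelse(is.na(vals), "#808080", pal[vals]))
  }
  scene$colors[[name]] <- list(mode = "feature", feature = feature$name,
                               hex = hex)
  scene
}

#' Serialize a scene to JSON
#'
#' The JSON round-trips losslessly: serialize, parse, serialize is
#' byte-identical.
#'
#' @param scene a `ches_scene`
#' @param path optional output file
#' @return JSON string (invisibly when `path` is given)
#' @export
scene_to_json <- function(scene, path = NULL) {
  compounds <- lapply(seq_along(scene$kept), function(i) {
    cmp <- list(id = scene$ids[i],
                index = scene$kept[i],
                x = round(scene$positions[i, 1], 9),
                y = round(scene$positions[i, 2], 9),
                z = round(scene$positions[i, 3], 9),
                cluster = scene$cluster_of[i])
    for (h in names(scene$colors)) {
      if (identical(scene$colors[[h]]$mode, "feature"))
        cmp[[paste0("color_", h)]] <- scene$colors[[h]]$hex[i]
    }
    cmp
  })
  obj <- list(
    compounds = compounds,
    clusters = as.list(sort(unique(scene$cluster_of))),
    highlights = lapply(scene$colors, function(cc)
      list(mode = cc$mode, feature = cc$feature)),
    space_scale = scene$space_scale,
    superimposed = scene$superimposed,
    embedding_method = scene$embedding_method,
    cluster_algorithm = scene$cluster_algorithm)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Parse a scene JSON string back into its list form
#' @param json JSON string or file path
#' @return named list mirroring the serialized structure
#' @export
scene_from_json <- function(json) {
  jsonlite::fromJSON(json, simplifyVector = FALSE)
}
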