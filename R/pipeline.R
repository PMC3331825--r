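# Six-step workflow orchestration from a single configuration: load ->
# structures -> features -> cluster -> embed -> align -> scene/export.

#' Default run configuration
#'
#' Mirrors the six wizard steps. Every entry can be overridden by the
#' corresponding element of `config` in [run_pipeline()] /
#' [validate_config()], or by a YAML file with the same structure.
#'
#' @return nested list of defaults
#' @export
default_config <- function() {
  list(
    dataset = list(path = NULL, format = NULL, csv = NULL, name = NULL),
    structures = list(provider = "topological"),
    features = list(
      dataset_columns = character(0),   # names of dataset columns to use
      descriptors = character(0),       # builtin/delegate descriptor names
      fragments = list(enabled = TRUE, max_atoms = 7L, min_frequency = 2L,
                       skip_omnipresent = TRUE),
      smarts_file = NULL),
    clustering = list(algorithm = "cascade-kmeans", k = NULL,
                      k_min = 2L, k_max = NULL, linkage = "complete",
                      restarts = 10L),
    embedding = list(method = "pca", max_iter = 200L, tol = 1e-6),
    alignment = list(method = "mcs", min_atoms = 3L, budget = 2e5),
    scene = list(space_scale = 1),
    seed = 1L)
}

.merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Load a run configuration from a YAML file
#' @param path YAML file
#' @return full configuration (defaults merged)
#' @export
read_config <- function(path) {
  .merge_config(default_config(), yaml::read_yaml(path))
}

#' Validate a run configuration
#'
#' Checks value ranges, mutually required options and file existence.
#' Returns structured errors rather than throwing on user mistakes.
#'
#' @param config configuration list (merged over [default_config()])
#' @param need_dataset require a dataset path (FALSE when a dataset
#'   object is passed to [run_pipeline()] directly)
#' @return character vector of error messages; empty means ok
#' @export
validate_config <- function(config, need_dataset = TRUE) {
  cfg <- .merge_config(default_config(), config)
  errs <- character(0)
  if (need_dataset) {
    if (is.null(cfg$dataset$path))
      errs <- c(errs, "dataset: no input path given")
    else if (!file.exists(cfg$dataset$path))
      errs <- c(errs, paste0("dataset: file not found: ", cfg$dataset$path))
  }
  if (!is.null(cfg$features$smarts_file) &&
      !file.exists(cfg$features$smarts_file))
    errs <- c(errs, paste0("features: SMARTS file not found: ",
                           cfg$features$smarts_file))
  cl <- cfg$clustering
  valid_algos <- c("cascade-kmeans", "kmeans", "hierarchical",
                   "farthest-first", "none")
  if (!cl$algorithm %in% valid_algos)
    errs <- c(errs, paste0("clustering: unknown algorithm '", cl$algorithm,
                           "'; valid: ", paste(valid_algos, collapse = ", ")))
  if (cl$algorithm == "cascade-kmeans" && !is.null(cl$k_max) &&
      cl$k_min > cl$k_max)
    errs <- c(errs, "clustering: k_min > k_max")
  if (cl$algorithm %in% c("kmeans", "hierarchical", "farthest-first") &&
      is.null(cl$k))
    errs <- c(errs, paste0("clustering: algorithm '", cl$algorithm,
                           "' needs k"))
  if (cl$algorithm == "hierarchical" &&
      !cl$linkage %in% c("single", "complete", "average", "ward"))
    errs <- c(errs, paste0("clustering: invalid linkage '", cl$linkage, "'"))
  valid_embed <- c("pca", "sammon", "smacof", "random")
  if (!cfg$embedding$method %in% valid_embed)
    errs <- c(errs, paste0("embedding: unknown method '",
                           cfg$embedding$method, "'; valid: ",
                           paste(valid_embed, collapse = ", ")))
  valid_align <- c("mcs", "msf", "none")
  if (!cfg$alignment$method %in% valid_align)
    errs <- c(errs, paste0("alignment: unknown method '",
                           cfg$alignment$method, "'"))
  if (cfg$alignment$method == "msf" &&
      !isTRUE(cfg$features$fragments$enabled) &&
      is.null(cfg$features$smarts_file))
    errs <- c(errs, paste0("alignment: the MSF aligner requires structural ",
                           "features (enable fragment mining or provide a ",
                           "SMARTS file)"))
  if (!is.null(cfg$scene$space_scale) && cfg$scene$space_scale <= 0)
    errs <- c(errs, "scene: space_scale must be > 0")
  errs
}

# md5 of an R object's serialization (stage-cache key)
.input_hash <- function(object) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(object, tf)
  unname(tools::md5sum(tf))
}

.cache_fetch <- function(cache_dir, key, compute) {
  if (is.null(cache_dir)) return(list(value = compute(), hit = FALSE))
  path <- file.path(cache_dir, paste0(key, ".rds"))
  if (file.exists(path)) return(list(value = readRDS(path), hit = TRUE))
  value <- compute()
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(value, path)
  list(value = value, hit = FALSE)
}

#' Map a dataset into chemical space
#'
#' Executes the mapping pipeline on an in-memory dataset: (optional)
#' structure generation, feature assembly (dataset columns, descriptors,
#' mined fragments, SMARTS files), clustering, 3D embedding, per-cluster
#' alignment and scene assembly.
#'
#' @param dataset a [ches_dataset()]
#' @param config configuration list (merged over [default_config()])
#' @param cache_dir optional directory for stage caching (structures and
#'   fragment mining are cached keyed on an input hash)
#' @param log function(message) used for stage logging
#' @return an object of class `ches_map`: the dataset (with structures),
#'   the selected feature columns, the `feature_matrix`, the
#'   `cluster_result`, the `embedding3d`, per-cluster substructures and
#'   transforms, and the assembled `ches_scene`
#' @export
ches_map <- function(dataset, config = list(), cache_dir = NULL,
                     log = function(msg) message(msg)) {
  cfg <- .merge_config(default_config(), config)
  errs <- validate_config(cfg, need_dataset = FALSE)
  if (length(errs))
    stop("invalid configuration:\n", paste("-", errs, collapse = "\n"))
  stopifnot(inherits(dataset, "ches_dataset"))
  n <- length(dataset$molecules)
  seed <- as.integer(cfg$seed)

  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log(sprintf("[%s] done", name))
    res
  }

  # structures
  dataset <- stage("structures", {
    if (!dataset$has3d && !identical(cfg$structures$provider, "none")) {
      key <- .input_hash(list("structures", cfg$structures,
                              lapply(dataset$molecules, function(m)
                                list(m$atoms, m$bonds))))
      got <- .cache_fetch(cache_dir, key, function()
        generate_structures(dataset, cfg$structures$provider))
      if (got$hit) log("[structures] cache hit")
      got$value
    } else dataset
  })

  # features
  feats <- stage("features", {
    out <- list()
    sel <- cfg$features$dataset_columns
    if (isTRUE(sel)) sel <- names(dataset$features)
    for (nm in sel) {
      if (is.null(dataset$features[[nm]]))
        stop("unknown dataset column '", nm, "'")
      out[[length(out) + 1L]] <- dataset$features[[nm]]
    }
    if (length(cfg$features$descriptors))
      out <- c(out, compute_descriptors(dataset$molecules,
                                        cfg$features$descriptors))
    frags <- list()
    if (isTRUE(cfg$features$fragments$enabled)) {
      fc <- cfg$features$fragments
      key <- .input_hash(list("fragments", fc,
                              lapply(dataset$molecules, function(m)
                                list(m$atoms, m$bonds))))
      got <- .cache_fetch(cache_dir, key, function() {
        mined <- enumerate_linear_fragments(dataset$molecules,
                                            max_atoms = fc$max_atoms)
        build_fragment_features(mined, min_frequency = fc$min_frequency,
                                skip_omnipresent = fc$skip_omnipresent,
                                n_compounds = n)
      })
      if (got$hit) log("[fragments] cache hit")
      frags <- got$value
    }
    if (!is.null(cfg$features$smarts_file)) {
      templates <- load_smarts_file(cfg$features$smarts_file)
      frags <- c(frags, fragment_incidence(templates, dataset$molecules))
    }
    out <- c(out, fragment_feature_columns(frags))
    list(columns = out, fragments = frags)
  })

  # feature matrix (may legitimately be absent: the no-feature path)
  M <- if (length(feats$columns))
    stage("feature-matrix", preprocess_features(feats$columns))
  else NULL
  if (is.null(M) && cfg$clustering$algorithm != "none")
    stop("stage 'cluster' failed: no features selected; ",
         "clustering requires features (use algorithm 'none')")
  if (is.null(M) && cfg$embedding$method != "random")
    stop("stage 'embed' failed: no features selected; ",
         "embedding requires features (use method 'random')")

  # cluster
  cl_res <- stage("cluster", {
    cl <- cfg$clustering
    switch(cl$algorithm,
      "none" = no_clustering(n),
      "kmeans" = kmeans_cluster(M, cl$k, restarts = cl$restarts,
                                seed = seed),
      "cascade-kmeans" = cascade_kmeans(M, k_min = cl$k_min,
                                        k_max = cl$k_max,
                                        restarts = cl$restarts,
                                        seed = seed),
      "hierarchical" = hierarchical_cluster(M, linkage = cl$linkage,
                                            k = cl$k),
      "farthest-first" = farthest_first(M, cl$k, seed = seed))
  })

  # embed
  emb <- stage("embed", {
    em <- cfg$embedding
    switch(em$method,
      "pca" = pca_embed(M),
      "sammon" = sammon_embed(M, max_iter = em$max_iter,
                              tol = min(em$tol, 1e-9), seed = seed),
      "smacof" = smacof_embed(build_distance_matrix(M),
                              max_iter = em$max_iter, tol = em$tol,
                              seed = seed),
      "random" = random_embed(n, seed = seed))
  })

  # align
  aligned <- stage("align", {
    transforms <- vector("list", n)
    subs <- list()
    if (cfg$alignment$method != "none") {
      for (cl_id in sort(unique(cl_res$labels))) {
        members <- which(cl_res$labels == cl_id)
        if (length(members) < 2) {
          if (length(members) == 1) transforms[[members]] <- rigid_transform()
          next
        }
        mols <- dataset$molecules[members]
        sub <- if (cfg$alignment$method == "mcs") {
          s <- tryCatch(
            cluster_mcs(mols, min_atoms = cfg$alignment$min_atoms,
                        budget = cfg$alignment$budget),
            error = function(e) {
              warning("cluster ", cl_id, ": ", conditionMessage(e))
              NULL
            })
          if (is.null(s) && length(feats$fragments)) {
            # degrade to the largest shared structural fragment
            s <- tryCatch(msf_select(members, feats$fragments),
                          error = function(e) NULL)
          }
          s
        } else {
          msf_select(members, feats$fragments)
        }
        if (is.null(sub)) next  # no alignment is performed
        subs[[as.character(cl_id)]] <- sub
        trs <- tryCatch(align_cluster(mols, sub), error = function(e) {
          warning("cluster ", cl_id, " alignment failed: ",
                  conditionMessage(e))
          NULL
        })
        if (!is.null(trs)) for (mi in seq_along(members))
          transforms[[members[mi]]] <- trs[[mi]]
      }
    }
    list(transforms = transforms, substructures = subs)
  })

  # scene
  scn <- stage("scene", {
    s <- build_scene(emb, cl_res, transforms = aligned$transforms,
                     ids = compound_ids(dataset),
                     space_scale = cfg$scene$space_scale)
    s <- scene_highlight(s, "cluster",
                         feature_column("cluster",
                                        as.character(cl_res$labels),
                                        ftype = "nominal"))
    s
  })

  structure(list(dataset = dataset, config = cfg,
                 features = feats$columns, fragments = feats$fragments,
                 feature_matrix = M, clustering = cl_res, embedding = emb,
                 substructures = aligned$substructures,
                 transforms = aligned$transforms, scene = scn),
            class = "ches_map")
}

#' @export
print.ches_map <- function(x, ...) {
  cat(sprintf("<ches_map> '%s': %d compounds\n", x$dataset$name,
              length(x$dataset$molecules)))
  cat(sprintf("  features : %d columns (%d fragment)\n",
              length(x$features),
              sum(vapply(x$features, function(f) f$origin == "fragment",
                         logical(1)))))
  cat(sprintf("  clusters : k = %d (%s)\n", x$clustering$k,
              x$clustering$algorithm))
  cat(sprintf("  embedding: %s%s\n", x$embedding$method,
              if (is.na(x$embedding$stress)) ""
              else sprintf(" (stress %.3g)", x$embedding$stress)))
  cat(sprintf("  aligned  : %d cluster(s) on common substructures\n",
              length(x$substructures)))
  invisible(x)
}

#' @export
summary.ches_map <- function(object, ...) {
  print(object)
  if (!is.null(object$clustering$quality_by_k)) {
    cat("Calinski-Harabasz by k:\n")
    print(round(object$clustering$quality_by_k, 2))
  }
  sizes <- table(object$clustering$labels)
  cat("cluster sizes:", paste(sizes, collapse = ", "), "\n")
  for (nm in names(object$substructures))
    cat(sprintf("cluster %s substructure: %s\n", nm,
                object$substructures[[nm]]$smarts))
  invisible(object)
}

#' @method plot ches_map
#' @export
plot.ches_map <- function(x, ...) {
  pos <- x$scene$positions
  cl <- x$scene$cluster_of
  pal <- .QUALITATIVE_PALETTE[((cl - 1L) %% length(.QUALITATIVE_PALETTE)) + 1L]
  graphics::plot(pos[, 1], pos[, 2], col = pal, pch = 19,
                 xlab = "embedding x", ylab = "embedding y",
                 main = sprintf("%s / %s", x$scene$cluster_algorithm,
                                x$scene$embedding_method), ...)
  invisible(x)
}

#' Run the full pipeline from a configuration
#'
#' Loads the dataset, executes the mapping, and writes the output
#' directory: `scene.json`, `out.sdf` (annotated SD-file),
#' `clusters.json` (labels + per-k quality scores), `embedding.csv`
#' (id, x, y, z) and `run.log`. Structure generation and fragment mining
#' are cached under `<out_dir>/cache` keyed on input hashes, so reruns
#' on the same dataset skip them.
#'
#' @param config configuration list or path to a YAML file
#' @param out_dir output directory (created if needed)
#' @param dataset optional in-memory [ches_dataset()] (overrides
#'   `config$dataset$path`)
#' @return the `ches_map` object, invisibly
#' @export
run_pipeline <- function(config, out_dir, dataset = NULL) {
  cfg <- if (is.character(config)) read_config(config)
         else .merge_config(default_config(), config)
  errs <- validate_config(cfg, need_dataset = is.null(dataset))
  if (length(errs))
    stop("invalid configuration:\n", paste("-", errs, collapse = "\n"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "at")
  on.exit(close(log_con))
  log <- function(msg) {
    writeLines(sprintf("%s %s", format(Sys.time(), "%H:%M:%S"), msg),
               log_con)
  }
  log(paste("seed:", cfg$seed))
  if (is.null(dataset))
    dataset <- read_dataset(cfg$dataset$path, format = cfg$dataset$format,
                            csv = cfg$dataset$csv, name = cfg$dataset$name)
  res <- ches_map(dataset, cfg, cache_dir = file.path(out_dir, "cache"),
                  log = log)
  scene_to_json(res$scene, file.path(out_dir, "scene.json"))
  export_sdf(res$dataset, res$scene, path = file.path(out_dir, "out.sdf"))
  jsonlite::write_json(
    list(algorithm = res$clustering$algorithm, k = res$clustering$k,
         labels = res$clustering$labels,
         quality_by_k = as.list(res$clustering$quality_by_k),
         seed = res$clustering$seed),
    file.path(out_dir, "clusters.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  utils::write.csv(
    data.frame(id = res$scene$ids, x = res$scene$positions[, 1],
               y = res$scene$positions[, 2], z = res$scene$positions[, 3]),
    file.path(out_dir, "embedding.csv"), row.names = FALSE)
  log("[export] done")
  invisible(res)
}
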