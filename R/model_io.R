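MODEL_SCHEMA_VERSION <- 1L

#' Bundle a fitted model with its provenance
#'
#' A model bundle carries everything needed to reproduce predictions: the
#' classifier itself, the preprocessing and Welch settings its features were
#' computed with, the class labels and free-form training metadata (seed,
#' participant, date, ...).
#'
#' @param model An `emg_tree` or `threshold_model`.
#' @param preprocessing Optional list describing the conditioning (e.g.
#'   band-pass corners, decimation factor).
#' @param welch Optional [welch_spec()].
#' @param metadata Named list of training metadata.
#' @return A `model_bundle`.
#' @export
model_bundle <- function(model, preprocessing = NULL, welch = NULL,
                         metadata = list()) {
  kind <- if (inherits(model, "emg_tree")) "tree"
    else if (inherits(model, "threshold_model")) "threshold"
    else stop("model must be an emg_tree or a threshold_model")
  classes <- if (kind == "tree") model$classes else model$class_order
  structure(list(kind = kind, model = model, preprocessing = preprocessing,
                 welch = welch, class_labels = classes, metadata = metadata),
            class = "model_bundle")
}

node_to_list <- function(node) {
  if (node$leaf)
    list(leaf = TRUE, mass = as.list(node$mass), label = node$label)
  else
    list(leaf = FALSE, feature = node$feature, threshold = node$threshold,
         left = node_to_list(node$left), right = node_to_list(node$right))
}

node_from_list <- function(l) {
  if (isTRUE(l$leaf)) {
    mass <- unlist(l$mass)
    list(leaf = TRUE, mass = mass, label = l$label)
  } else {
    list(leaf = FALSE, feature = as.integer(l$feature),
         threshold = as.numeric(l$threshold),
         left = node_from_list(l$left), right = node_from_list(l$right))
  }
}

mat_to_list <- function(m) {
  if (is.null(m)) return(NULL)
  out <- lapply(seq_len(nrow(m)), function(i) as.list(m[i, ]))
  names(out) <- rownames(m)
  out
}

mat_from_list <- function(l) {
  if (is.null(l)) return(NULL)
  m <- do.call(rbind, lapply(l, unlist))
  rownames(m) <- names(l)
  m
}

#' Save a model bundle as JSON
#'
#' The file carries an explicit `schema_version`; real numbers are written at
#' full precision (17 significant digits) so integer and text fields
#' round-trip identically and doubles round-trip bit-exactly.
#'
#' @param bundle A [model_bundle()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_model <- function(bundle, path) {
  stopifnot(inherits(bundle, "model_bundle"))
  m <- bundle$model
  params <- if (bundle$kind == "tree") {
    list(classes = m$classes, class_weights = as.list(m$class_weights),
         hyperparams = unclass(m$hyperparams),
         feature_names = m$feature_names, root = node_to_list(m$root))
  } else {
    list(mode = m$mode, class_order = m$class_order,
         lower = mat_to_list(m$lower), upper = mat_to_list(m$upper),
         quantile_method = m$quantile_method)
  }
  payload <- list(schema_version = MODEL_SCHEMA_VERSION, kind = bundle$kind,
                  class_labels = bundle$class_labels,
                  preprocessing = bundle$preprocessing,
                  welch = if (!is.null(bundle$welch)) unclass(bundle$welch),
                  metadata = bundle$metadata, parameters = params)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Load a model bundle from JSON
#'
#' @param path Path written by [save_model()].
#' @return A [model_bundle()].
#' @export
load_model <- function(path) {
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop("model parse error: ", conditionMessage(e)))
  if (is.null(payload$schema_version) ||
      payload$schema_version != MODEL_SCHEMA_VERSION)
    stop("model version error: unsupported or missing schema_version")
  p <- payload$parameters
  model <- if (payload$kind == "tree") {
    hp <- tree_hyperparams(p$hyperparams$max_depth,
                           p$hyperparams$min_samples_leaf,
                           p$hyperparams$min_samples_split)
    structure(list(root = node_from_list(p$root),
                   classes = unlist(p$classes),
                   class_weights = unlist(p$class_weights),
                   hyperparams = hp,
                   feature_names = unlist(p$feature_names)),
              class = "emg_tree")
  } else if (payload$kind == "threshold") {
    structure(list(mode = p$mode, class_order = unlist(p$class_order),
                   lower = mat_from_list(p$lower),
                   upper = mat_from_list(p$upper),
                   quantile_method = p$quantile_method),
              class = "threshold_model")
  } else stop("model version error: unknown kind ", payload$kind)
  welch <- if (!is.null(payload$welch)) {
    w <- payload$welch
    welch_spec(w$window_dur, w$segment_dur, w$overlap_frac,
               w$target_resolution, w$stride, unlist(w$band),
               w$feature_variant)
  }
  model_bundle(model,
               preprocessing = payload$preprocessing,
               welch = welch,
               metadata = payload$metadata)
}
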