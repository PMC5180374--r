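MODEL_SCHEMA_VERSION <- 1L

as_matrix <- function(x) {
  if (is.null(x)) return(NULL)
  if (!is.matrix(x)) x <- do.call(rbind, lapply(x, as.numeric))
  x
}

model_kind <- function(obj) {
  kinds <- c("transition_model", "cluster_model", "split_pca", "spine_pca")
  k <- intersect(class(obj), kinds)
  if (length(k) == 0) {
    stop("not a serializable spinetax model: ",
         paste(class(obj), collapse = "/"), call. = FALSE)
  }
  k[1]
}

encode_model <- function(obj) {
  kind <- model_kind(obj)
  body <- switch(kind,
    transition_model = list(
      T = obj$T, method = obj$method,
      initial_weights = obj$initial_weights,
      empty_rows = obj$empty_rows, E = obj$E, se = obj$se),
    cluster_model = list(
      kind = obj$kind, k = obj$k, m = obj$m, centroids = obj$centroids,
      training_x = obj$training$x, training_w = obj$training$w),
    spine_pca = list(
      loadings = obj$loadings, center = obj$center,
      explained = obj$explained, descriptors = obj$descriptors),
    split_pca = list(
      size = encode_model(obj$size)$model,
      contour = encode_model(obj$contour)$model,
      truncation = obj$truncation)
  )
  list(spinetax_model = kind, schema_version = MODEL_SCHEMA_VERSION,
       model = body)
}

decode_model <- function(payload) {
  if (is.null(payload$spinetax_model)) {
    stop("not a spinetax model file (missing kind tag)", call. = FALSE)
  }
  kind <- payload$spinetax_model
  b <- payload$model
  switch(kind,
    transition_model = new_transition_model(
      T = as_matrix(b$T), method = b$method,
      initial_weights = as.numeric(b$initial_weights),
      empty_rows = as.logical(b$empty_rows),
      E = if (is.null(b$E)) NULL else as.numeric(b$E),
      se = as_matrix(b$se)),
    cluster_model = new_cluster_model(
      kind = b$kind, k = as.integer(b$k),
      m = if (is.null(b$m)) NULL else as.numeric(b$m),
      centroids = as_matrix(b$centroids),
      training = if (is.null(b$training_x)) NULL else
        list(x = as_matrix(b$training_x), w = as_matrix(b$training_w))),
    spine_pca = {
      L <- as_matrix(b$loadings)
      ctr <- as.numeric(b$center)
      desc <- as.character(b$descriptors)
      colnames(L) <- desc
      names(ctr) <- desc
      structure(list(loadings = L, center = ctr,
                     explained = as.numeric(b$explained),
                     descriptors = desc), class = "spine_pca")
    },
    split_pca = structure(list(
      size = decode_model(list(spinetax_model = "spine_pca",
                               model = b$size)),
      contour = decode_model(list(spinetax_model = "spine_pca",
                                  model = b$contour)),
      truncation = as.numeric(b$truncation)), class = "split_pca"),
    stop("unknown model kind tag: ", kind, call. = FALSE)
  )
}

#' Serialize a model to JSON
#'
#' Writes transition models, cluster models and PCA fits to a
#' version-tagged JSON file. Numeric fields survive a write/read
#' round-trip exactly ([read_model()] of the written file reproduces the
#' stored numbers bit-identically).
#'
#' @param obj A `transition_model`, `cluster_model`, `spine_pca` or
#'   `split_pca` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @seealso [read_model()]
#' @export
write_model <- function(obj, path) {
  payload <- encode_model(obj)
  # 17 significant digits: doubles survive the round trip bit-exactly
  json <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                           null = "null", na = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read a serialized model from JSON
#'
#' @param path Path to a file produced by [write_model()].
#' @return The reconstructed model object; a malformed or truncated file
#'   raises a format error without returning a partial object.
#' @export
read_model <- function(path) {
  payload <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE),
    error = function(e) stop("malformed model file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  decode_model(payload)
}
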