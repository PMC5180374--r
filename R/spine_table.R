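#' Descriptor schema for spine morphometry
#'
#' The eleven per-spine morphometric descriptors used throughout the
#' package, in their fixed canonical column order, together with their
#' partition into size-related and contour-related subsets. All matrices
#' produced by the package use this column order.
#'
#' The descriptors are: `length` (curvilinear spine length, um), `hw`
#' (head width, um), `mwl` (max width location, um), `mw` (max width, um),
#' `nw` (neck width, um), `foot` (um), `circumference` (um), `area` (um^2),
#' `wlr` (width/length ratio), `lwr` (length/width ratio) and `lar`
#' (length/area ratio, 1/um).
#'
#' @return An object of class `descriptor_schema`: a list with elements
#'   `names` (all 11 descriptors, ordered), `size_set` and `contour_set`
#'   (disjoint subsets whose union is `names`).
#' @examples
#' sch <- descriptor_schema()
#' sch$size_set
#' @export
descriptor_schema <- function() {
  nm <- c("length", "hw", "mwl", "mw", "nw", "foot",
          "circumference", "area", "wlr", "lwr", "lar")
  structure(list(
    names = nm,
    size_set = c("length", "circumference", "area"),
    contour_set = c("hw", "foot", "mwl", "mw", "wlr", "lwr", "lar", "nw")
  ), class = "descriptor_schema")
}

#' @export
print.descriptor_schema <- function(x, ...) {
  cat("Descriptor schema (", length(x$names), " descriptors)\n", sep = "")
  cat("  order:  ", paste(x$names, collapse = ", "), "\n", sep = "")
  cat("  size:   ", paste(x$size_set, collapse = ", "), "\n", sep = "")
  cat("  contour:", paste(x$contour_set, collapse = ", "), "\n", sep = "")
  invisible(x)
}

wide_columns <- function(schema) {
  c(paste0(schema$names, "_t0"), paste0(schema$names, "_t1"))
}

#' Construct a spine table
#'
#' A spine table holds one row per spine with its population label and the
#' 11 morphometric descriptors at both time points t0 and t1 (paired
#' design: every spine carries both measurements). This is the universal
#' input of the package.
#'
#' @param df A data frame with columns `spine_id`, `population`, and
#'   `<descriptor>_t0` / `<descriptor>_t1` for each of the 11 descriptors
#'   of [descriptor_schema()].
#' @param schema Descriptor schema; defaults to [descriptor_schema()].
#' @return An object of class `spine_table` (a data frame with the columns
#'   in canonical order and the schema attached as an attribute).
#' @details Validation rejects non-finite values, non-positive length,
#'   width, area or circumference measurements, and duplicated spine ids
#'   within a population. Offending spine ids are reported in the error.
#' @export
spine_table <- function(df, schema = descriptor_schema()) {
  need <- c("spine_id", "population", wide_columns(schema))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("spine table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, need, drop = FALSE]
  df$spine_id <- as.character(df$spine_id)
  df$population <- as.character(df$population)
  num_cols <- wide_columns(schema)
  for (cl in num_cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      suppressWarnings(v2 <- as.numeric(as.character(v)))
      if (anyNA(v2) && !all(is.na(v) == is.na(v2))) {
        bad <- which(is.na(v2) & !is.na(as.character(v)))[1]
        stop("non-numeric value in column '", cl, "', row ", bad,
             call. = FALSE)
      }
      v <- v2
      df[[cl]] <- v
    }
  }
  X <- as.matrix(df[, num_cols, drop = FALSE])
  bad_finite <- !is.finite(X)
  if (any(bad_finite)) {
    ids <- unique(df$spine_id[rowSums(bad_finite) > 0])
    stop("missing or non-finite descriptor values for spine(s): ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  # strictly positive physical measurements (lengths/widths/areas)
  positive <- c("length", "hw", "mwl", "mw", "nw", "foot",
                "circumference", "area")
  pos_cols <- c(paste0(positive, "_t0"), paste0(positive, "_t1"))
  bad_pos <- X[, pos_cols, drop = FALSE] <= 0
  if (any(bad_pos)) {
    ids <- unique(df$spine_id[rowSums(bad_pos) > 0])
    stop("non-positive length/width/area descriptor for spine(s): ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(paste(df$population, df$spine_id, sep = "\r"))
  if (any(dup)) {
    stop("duplicated spine_id within a population: ",
         paste(unique(df$spine_id[dup]), collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, schema = schema, class = c("spine_table", "data.frame"))
}

#' @export
print.spine_table <- function(x, ...) {
  pops <- table(x$population)
  cat("Spine table: ", nrow(x), " spines, 11 descriptors at t0/t1\n",
      sep = "")
  cat("  populations: ",
      paste(sprintf("%s (%d)", names(pops), as.integer(pops)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Extract a descriptor matrix from a spine table
#'
#' @param table A [spine_table()].
#' @param time Either `"t0"` or `"t1"`.
#' @param descriptors Optional subset of descriptor names (canonical order
#'   is preserved); defaults to all 11.
#' @return Numeric matrix, one row per spine (rownames = spine ids),
#'   columns named by descriptor.
#' @export
descriptor_matrix <- function(table, time = c("t0", "t1"),
                              descriptors = NULL) {
  time <- match.arg(time)
  schema <- attr(table, "schema")
  if (is.null(descriptors)) descriptors <- schema$names
  descriptors <- schema$names[schema$names %in% descriptors]
  X <- as.matrix(table[, paste0(descriptors, "_", time), drop = FALSE])
  colnames(X) <- descriptors
  rownames(X) <- table$spine_id
  X
}

#' Combine spine tables
#'
#' Row-binds spine tables sharing a schema (e.g., two populations before a
#' pooled analysis).
#'
#' @param ... Spine tables.
#' @return A single `spine_table`.
#' @export
bind_spine_tables <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1 && is.list(tabs[[1]]) &&
      !inherits(tabs[[1]], "spine_table")) {
    tabs <- tabs[[1]]
  }
  df <- do.call(rbind, lapply(tabs, as.data.frame))
  spine_table(df, schema = attr(tabs[[1]], "schema"))
}

detect_delim <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (length(hdr) == 0) stop("empty file: ", path, call. = FALSE)
  if (grepl("\t", hdr)) "\t" else ","
}

#' Read a spine table from CSV/TSV
#'
#' Reads per-spine descriptor tables in either wide format (one row per
#' spine, `<descriptor>_t0` / `<descriptor>_t1` columns — the canonical
#' layout) or long format (two rows per spine keyed by a `time` column
#' with values `t0`/`t1`). The delimiter is auto-detected from the header
#' line (comma or tab) unless forced.
#'
#' @param path Path to a delimited text file with a header.
#' @param format `"auto"` (default), `"wide"` or `"long"`. Auto-detection
#'   keys on the presence of a `time` column.
#' @param sep Field delimiter; `NULL` (default) auto-detects.
#' @param aliases Optional named character vector mapping file column
#'   names to canonical names, e.g. `c(head_width = "hw")`.
#' @param schema Descriptor schema.
#' @return A validated [spine_table()].
#' @details In long format every spine must appear exactly once per time
#'   point; unpaired spines are reported by id. Missing descriptor columns
#'   are reported by name.
#' @export
read_spine_table <- function(path, format = c("auto", "wide", "long"),
                             sep = NULL, aliases = NULL,
                             schema = descriptor_schema()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(aliases)) {
    hit <- names(df) %in% names(aliases)
    names(df)[hit] <- unname(aliases[names(df)[hit]])
  }
  if (format == "auto") {
    format <- if ("time" %in% names(df)) "long" else "wide"
  }
  if (format == "long") {
    need <- c("spine_id", "population", "time", schema$names)
    missing_cols <- setdiff(need, names(df))
    if (length(missing_cols) > 0) {
      stop("long-format table is missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    df$time <- as.character(df$time)
    if (!all(df$time %in% c("t0", "t1"))) {
      stop("long-format 'time' column must contain only t0/t1",
           call. = FALSE)
    }
    key <- paste(df$population, df$spine_id, sep = "\r")
    counts <- table(key, df$time)
    paired <- rownames(counts)[counts[, "t0", drop = TRUE] == 1 &
                               counts[, "t1", drop = TRUE] == 1]
    unpaired <- setdiff(rownames(counts), paired)
    if (length(unpaired) > 0) {
      ids <- sub("^.*\r", "", unpaired)
      stop("spine(s) without both time points: ",
           paste(ids, collapse = ", "), call. = FALSE)
    }
    d0 <- df[df$time == "t0", , drop = FALSE]
    d1 <- df[df$time == "t1", , drop = FALSE]
    d1 <- d1[match(paste(d0$population, d0$spine_id, sep = "\r"),
                   paste(d1$population, d1$spine_id, sep = "\r")), ,
             drop = FALSE]
    wide <- data.frame(spine_id = d0$spine_id, population = d0$population,
                       stringsAsFactors = FALSE)
    for (nm in schema$names) {
      wide[[paste0(nm, "_t0")]] <- d0[[nm]]
      wide[[paste0(nm, "_t1")]] <- d1[[nm]]
    }
    df <- wide
  }
  spine_table(df, schema = schema)
}

# Shortest decimal representation that parses back to the same double.
format_roundtrip <- function(x) {
  vapply(x, function(v) {
    for (d in 1:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}

#' Write a spine table to CSV
#'
#' Numeric values are written with just enough digits to reparse to the
#' identical double, so write/read is the identity.
#'
#' @param table A [spine_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_spine_table <- function(table, path) {
  df <- as.data.frame(table)
  for (cl in names(df)) {
    if (is.numeric(df[[cl]])) df[[cl]] <- format_roundtrip(df[[cl]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
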