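# CSV/JSON readers and writers.  All user-facing tables use the units of
# their column names: nm for track coordinates, nM for concentrations,
# N/m for tensions, um for contour coordinates.

read_checked_csv <- function(path, required, what) {
  if (!file.exists(path))
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0)
    stop(sprintf("%s file is empty: %s", what, path), call. = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s file %s is missing column(s): %s", what, path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  extra <- setdiff(names(df), required)
  if (length(extra))
    warning(sprintf("ignoring extra column(s) in %s: %s", path,
                    paste(extra, collapse = ", ")))
  for (col in required) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' of %s (first at row %d)",
                   col, path, bad[1]), call. = FALSE)
    if (anyNA(v))
      stop(sprintf("missing value in column '%s' of %s (first at row %d)",
                   col, path, which(is.na(v))[1]), call. = FALSE)
    df[[col]] <- v
  }
  df[required]
}

#' Read a filament-track table
#'
#' Columns: `frame`, `filament_id`, `point_index`, `x_nm`, `y_nm`.
#' Row order within each track is restored from `point_index`.
#'
#' @param path CSV file path.
#' @return A data.frame of class `"filament_tracks"`.
#' @export
read_tracks <- function(path) {
  df <- read_checked_csv(path, c("frame", "filament_id", "point_index",
                                 "x_nm", "y_nm"), "tracks")
  class(df) <- c("filament_tracks", "data.frame")
  df
}

#' Read a binding curve (bulk concentration vs bound density)
#'
#' Columns: `bulk_nM`, `bound_per_um2`; concentrations must be positive
#' and strictly increasing, densities non-negative.
#'
#' @param path CSV file path.
#' @return A data.frame of class `"binding_curve"`.
#' @export
read_binding_curve <- function(path) {
  df <- read_checked_csv(path, c("bulk_nM", "bound_per_um2"), "binding curve")
  if (any(df$bulk_nM <= 0) || any(diff(df$bulk_nM) <= 0))
    stop("'bulk_nM' must be positive and strictly increasing", call. = FALSE)
  if (any(df$bound_per_um2 < 0))
    stop("'bound_per_um2' must be non-negative", call. = FALSE)
  class(df) <- c("binding_curve", "data.frame")
  df
}

#' Read a micropipette aspiration series
#'
#' Columns: `tension_N_per_m`, `rel_area`, and optionally `rel_volume`.
#' Tensions must be positive and sorted ascending.
#'
#' @param path CSV file path.
#' @return A data.frame of class `"aspiration_series"` with attribute
#'   `sigma0` set to the smallest tension.
#' @export
read_aspiration_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("tension_N_per_m", "rel_area")
  if (all(c(required, "rel_volume") %in% names(df)))
    required <- c(required, "rel_volume")
  df <- read_checked_csv(path, required, "aspiration")
  if (any(df$tension_N_per_m <= 0) || is.unsorted(df$tension_N_per_m))
    stop("'tension_N_per_m' must be positive and sorted ascending",
         call. = FALSE)
  attr(df, "sigma0") <- min(df$tension_N_per_m)
  class(df) <- c("aspiration_series", "data.frame")
  df
}

#' Read a closed vesicle contour
#'
#' Columns: `x_um`, `y_um`; one traversal of the closed contour, closure
#' implied (last point differs from the first).
#'
#' @param path CSV file path.
#' @return A data.frame of class `"vesicle_contour"`.
#' @export
read_contour <- function(path) {
  df <- read_checked_csv(path, c("x_um", "y_um"), "contour")
  class(df) <- c("vesicle_contour", "data.frame")
  df
}

#' Read model parameters from a JSON configuration
#'
#' Recognised keys (all optional, defaults from [septin_params()]):
#' `a1_nm`, `Lp1_um`, `dg1_flat_kT_per_nm`, `Kd_nM`, `ref_conc_M`.
#'
#' @param path JSON file path.
#' @return A [septin_params()] object.
#' @export
read_model_params <- function(path) {
  if (!file.exists(path))
    stop("params file not found: ", path, call. = FALSE)
  cfg <- jsonlite::fromJSON(path)
  defaults <- septin_params()
  septin_params(
    a1_nm = cfg$a1_nm %||% defaults$a1_nm,
    Lp1_nm = if (!is.null(cfg$Lp1_um)) cfg$Lp1_um * 1000 else defaults$Lp1_nm,
    dg1_flat = cfg$dg1_flat_kT_per_nm %||% defaults$dg1_flat,
    Kd_nM = cfg$Kd_nM %||% defaults$Kd_nM,
    ref_conc_M = cfg$ref_conc_M %||% defaults$ref_conc_M)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an analysis result as JSON with a run manifest
#'
#' Serialises a (possibly nested) list of results together with a manifest
#' recording the package version, timestamp, seed and input paths, so a run
#' can be reproduced.  Numeric values are written at 12 significant digits;
#' non-finite diagnostics become `null` with a warning.
#'
#' @param x A named list (or S3 list object) of results.
#' @param path Output JSON path.
#' @param subcommand Optional subcommand name recorded in the manifest.
#' @param seed Optional seed recorded in the manifest.
#' @param inputs Optional character vector of input paths.
#' @return Invisibly, the path.
#' @export
write_result <- function(x, path, subcommand = NULL, seed = NULL,
                         inputs = NULL) {
  clean <- clean_for_json(x)
  payload <- list(
    result = clean,
    manifest = list(
      package = "septcurve",
      version = as.character(utils::packageVersion("septcurve")),
      subcommand = subcommand,
      seed = seed,
      inputs = inputs,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

clean_for_json <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- x[!vapply(x, function(e) is.function(e) || inherits(e, c("lm", "nls")),
                   logical(1))]
    return(lapply(unclass(x), clean_for_json))
  }
  if (is.numeric(x)) {
    if (any(!is.finite(x))) {
      warning("non-finite value serialised as null")
      x[!is.finite(x)] <- NA
    }
    return(signif(x, 12))
  }
  x
}
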