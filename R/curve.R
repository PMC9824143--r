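#' Construct an (x, y) measurement curve
#'
#' The common container for one-dimensional instrument traces: scattering
#' intensity versus q (in inverse Angstrom), excess heat capacity versus
#' temperature (degrees Celsius), or absorbance versus wavenumber (cm^-1).
#'
#' @param x Numeric abscissa. Stored sorted; duplicate abscissa values are
#'   collapsed by averaging the ordinate (and any uncertainty).
#' @param y Numeric ordinate, same length as `x`.
#' @param y_err Optional per-point ordinate uncertainty; all values must be
#'   strictly positive.
#' @param meta Named list of free-form annotations (units, temperature,
#'   composition, generator parameters).
#' @return An object of class `xy_curve`: a list with elements `x`, `y`,
#'   `y_err` (or `NULL`) and `meta`.
#' @export
xy_curve <- function(x, y, y_err = NULL, meta = list()) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("x and y must have the same length", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("curve values must not be NA", call. = FALSE)
  if (!is.null(y_err)) {
    y_err <- as.numeric(y_err)
    if (length(y_err) != length(x)) {
      stop("y_err must match the length of x", call. = FALSE)
    }
    if (any(!is.finite(y_err)) || any(y_err <= 0)) {
      stop("y_err values must all be finite and > 0", call. = FALSE)
    }
  }
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  if (!is.null(y_err)) y_err <- y_err[ord]
  if (anyDuplicated(x)) {
    grp <- match(x, unique(x))
    y <- as.numeric(tapply(y, grp, mean))
    if (!is.null(y_err)) y_err <- as.numeric(tapply(y_err, grp, mean))
    x <- unique(x)
  }
  structure(list(x = x, y = y, y_err = y_err, meta = meta),
            class = "xy_curve")
}

#' @export
length.xy_curve <- function(x) length(x$x)

#' @export
print.xy_curve <- function(x, ...) {
  unit <- x$meta$x_unit %||% "?"
  cat(sprintf("<xy_curve> %d points, x in [%g, %g] (%s)\n",
              length(x$x), min(x$x), max(x$x), unit))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a two- or three-column delimited curve file
#'
#' Accepts whitespace-, comma- or tab-delimited numeric columns; lines whose
#' first non-blank character is `#` are comments. Two columns are read as
#' (x, y), a third as the per-point uncertainty. The curve is returned sorted
#' by x with duplicate abscissa values averaged.
#'
#' @param path Path to the text file.
#' @param x_unit Unit tag recorded in `meta$x_unit` (for example `"1/A"`,
#'   `"degC"` or `"1/cm"`).
#' @return An [xy_curve].
#' @export
read_xy_curve <- function(path, x_unit = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) < 2L) stop("curve too short: fewer than 2 data rows", call. = FALSE)
  rows <- strsplit(trimws(lines[keep]), "[,\t ]+")
  ncols <- lengths(rows)
  if (any(ncols < 2L)) {
    stop(sprintf("parse error at line %d: fewer than 2 columns", keep[which(ncols < 2L)[1L]]),
         call. = FALSE)
  }
  vals <- suppressWarnings(lapply(rows, function(r) as.numeric(r[1:min(3, length(r))])))
  bad <- which(vapply(vals, anyNA, logical(1)))
  if (length(bad)) {
    stop(sprintf("parse error at line %d: non-numeric value", keep[bad[1L]]), call. = FALSE)
  }
  x <- vapply(vals, `[`, numeric(1), 1L)
  y <- vapply(vals, `[`, numeric(1), 2L)
  y_err <- if (all(ncols >= 3L)) vapply(vals, `[`, numeric(1), 3L) else NULL
  xy_curve(x, y, y_err, meta = list(x_unit = x_unit, source = path))
}

#' Write a curve as delimited text
#'
#' Columns are x, y and (when present) y_err, tab separated, at 8 significant
#' digits so a write/read round trip reproduces the values to at least 6
#' significant digits.
#'
#' @param curve An [xy_curve].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xy_curve <- function(curve, path) {
  stopifnot(inherits(curve, "xy_curve"))
  cols <- list(curve$x, curve$y)
  header <- c("x", "y")
  if (!is.null(curve$y_err)) {
    cols <- c(cols, list(curve$y_err))
    header <- c(header, "y_err")
  }
  txt <- do.call(paste, c(lapply(cols, function(v) sprintf("%.8g", v)), sep = "\t"))
  unit <- curve$meta$x_unit %||% "unknown"
  writeLines(c(sprintf("# x_unit: %s", unit),
               paste0("# ", paste(header, collapse = "\t")), txt), path)
  invisible(path)
}

#' Restrict a curve to an abscissa window
#'
#' @param curve An [xy_curve].
#' @param window Length-2 numeric `c(lo, hi)`.
#' @return The restricted [xy_curve].
#' @export
crop_curve <- function(curve, window) {
  stopifnot(inherits(curve, "xy_curve"), length(window) == 2L)
  window <- sort(as.numeric(window))
  keep <- curve$x >= window[1] & curve$x <= window[2]
  if (!any(keep)) stop("window contains no data points", call. = FALSE)
  xy_curve(curve$x[keep], curve$y[keep],
           if (is.null(curve$y_err)) NULL else curve$y_err[keep],
           meta = curve$meta)
}

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards so library calls never perturb user code.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}
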