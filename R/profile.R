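# SAXS profile container and I/O.
#
# A profile is the standard 3-column solution-scattering record: momentum
# transfer q (in inverse Angstrom), intensity I(q) in arbitrary units, and a
# strictly positive per-point uncertainty s(q) on the same scale as I.

#' Construct a SAXS profile
#'
#' @param q numeric vector of momentum-transfer values, strictly increasing,
#'   in inverse Angstrom.
#' @param intensity intensities on the same grid (arbitrary units).
#' @param error per-point uncertainties, strictly positive, same units as
#'   `intensity`.
#' @param label free-text label carried through plots and summaries.
#' @return an object of class `saxs_profile`: a data frame with columns
#'   `q`, `intensity`, `error` and attribute `label`.
#' @examples
#' p <- saxs_profile(c(0.01, 0.02), c(100, 90), c(1, 1))
#' nrow(p)
#' @export
saxs_profile <- function(q, intensity, error, label = "") {
  q <- as.numeric(q); intensity <- as.numeric(intensity); error <- as.numeric(error)
  if (length(q) != length(intensity) || length(q) != length(error))
    stop("q, intensity and error must have equal length")
  if (length(q) < 2)
    stop("a SAXS profile needs at least 2 points")
  if (any(!is.finite(q)) || any(!is.finite(intensity)) || any(!is.finite(error)))
    stop("non-finite values in profile")
  if (any(diff(q) <= 0))
    stop("q must be strictly increasing")
  if (any(error <= 0))
    stop("all errors must be strictly positive")
  out <- data.frame(q = q, intensity = intensity, error = error)
  attr(out, "label") <- as.character(label)
  class(out) <- c("saxs_profile", "data.frame")
  out
}

#' Read a 3-column SAXS profile from text
#'
#' Parses ATSAS-style `.dat` files: whitespace-separated columns q, I(q),
#' s(q); lines starting with `#` (and blank lines) are skipped; columns past
#' the third are ignored.  Rows whose error is not strictly positive are
#' dropped (`drop_bad_errors = TRUE`, the default) or rejected.
#'
#' @param path file path.
#' @param drop_bad_errors drop rows with error <= 0 instead of erroring.
#' @param q_unit `"A"` (inverse Angstrom, default) or `"nm"` (inverse
#'   nanometre; q is divided by 10 on read).  No autodetection is attempted.
#' @param label optional label; defaults to the file name.
#' @return a [saxs_profile].
#' @export
read_saxs_profile <- function(path, drop_bad_errors = TRUE,
                              q_unit = c("A", "nm"), label = NULL) {
  q_unit <- match.arg(q_unit)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) stop("no data rows in ", path)
  rows <- matrix(NA_real_, length(lines), 3)
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) < 3)
      stop("malformed row at line ", lineno[i], " of ", path,
           ": fewer than 3 columns")
    v <- suppressWarnings(as.numeric(tok[1:3]))
    if (any(is.na(v)))
      stop("malformed row at line ", lineno[i], " of ", path,
           ": non-numeric field")
    rows[i, ] <- v
  }
  if (q_unit == "nm") rows[, 1] <- rows[, 1] / 10
  if (drop_bad_errors) {
    ok <- rows[, 3] > 0
    rows <- rows[ok, , drop = FALSE]
  } else if (any(rows[, 3] <= 0)) {
    stop("non-positive error at line ", lineno[which(rows[, 3] <= 0)[1]])
  }
  if (nrow(rows) < 2) stop("fewer than 2 usable rows in ", path)
  if (is.null(label)) label <- basename(path)
  saxs_profile(rows[, 1], rows[, 2], rows[, 3], label = label)
}

#' Write a SAXS profile as 3-column text
#'
#' @param profile a [saxs_profile].
#' @param path output path.
#' @param digits significant digits written (default 10, enough for an exact
#'   numeric round trip at double precision of typical intensities).
#' @return `path`, invisibly.
#' @export
write_saxs_profile <- function(profile, path, digits = 10) {
  stopifnot(inherits(profile, "saxs_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", attr(profile, "label")), con)
  writeLines(sprintf("%.*g %.*g %.*g", digits, profile$q,
                     digits, profile$intensity, digits, profile$error), con)
  invisible(path)
}

#' Resample a profile onto a new q grid by linear interpolation
#'
#' Intended for fixture construction only; model-versus-experiment
#' comparisons evaluate the forward model directly on the experimental grid
#' and never interpolate.
#'
#' @param profile a [saxs_profile].
#' @param q_grid strictly increasing grid inside `range(profile$q)`.
#' @return a [saxs_profile] on `q_grid`.
#' @export
resample_profile <- function(profile, q_grid) {
  stopifnot(inherits(profile, "saxs_profile"))
  if (min(q_grid) < min(profile$q) || max(q_grid) > max(profile$q))
    stop("q_grid requests extrapolation outside the profile's q range")
  I <- stats::approx(profile$q, profile$intensity, xout = q_grid)$y
  s <- stats::approx(profile$q, profile$error, xout = q_grid)$y
  saxs_profile(q_grid, I, s, label = attr(profile, "label"))
}

#' @export
print.saxs_profile <- function(x, ...) {
  cat(sprintf("SAXS profile '%s': %d points, q in [%.4g, %.4g] A^-1\n",
              attr(x, "label"), nrow(x), min(x$q), max(x$q)))
  invisible(x)
}

#' @export
plot.saxs_profile <- function(x, log = "y", ...) {
  graphics::plot(x$q, x$intensity, type = "l", log = log,
                 xlab = expression(q ~ (ring(A)^-1)), ylab = "I(q)",
                 main = attr(x, "label"), ...)
  invisible(x)
}
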