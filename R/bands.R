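#' Frequency band specification
#'
#' Defines a named frequency band by its lower and upper edges in Hz. The
#' conventional EEG bands used throughout the package are delta (0.5--4 Hz),
#' theta (4--8 Hz), alpha (8--12 Hz), beta (12--30 Hz) and gamma (30--40 Hz);
#' see [default_bands()].
#'
#' @param name Band label, e.g. `"delta"`.
#' @param lo Lower band edge in Hz; must satisfy `0 < lo < hi`.
#' @param hi Upper band edge in Hz.
#' @return An object of class `band_spec`.
#' @examples
#' band_spec("alpha", 8, 12)
#' @export
band_spec <- function(name, lo, hi) {
  stopifnot(is.character(name), length(name) == 1L)
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  if (!is.finite(lo) || !is.finite(hi) || lo <= 0 || hi <= lo)
    stop("band edges must satisfy 0 < lo < hi (got ", lo, ", ", hi, ")")
  structure(list(name = name, lo = lo, hi = hi), class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %s: %g-%g Hz\n", x$name, x$lo, x$hi))
  invisible(x)
}

#' Conventional EEG analysis bands
#'
#' @return A named list of [band_spec()] objects: delta 0.5--4, theta 4--8,
#'   alpha 8--12, beta 12--30 and gamma 30--40 Hz.
#' @export
default_bands <- function() {
  list(
    delta = band_spec("delta", 0.5, 4),
    theta = band_spec("theta", 4, 8),
    alpha = band_spec("alpha", 8, 12),
    beta  = band_spec("beta", 12, 30),
    gamma = band_spec("gamma", 30, 40)
  )
}

as_band_spec <- function(band) {
  if (inherits(band, "band_spec")) return(band)
  if (is.character(band) && length(band) == 1L) {
    b <- default_bands()[[band]]
    if (is.null(b)) stop("unknown band name: ", band)
    return(b)
  }
  stop("band must be a band_spec or the name of a default band")
}
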