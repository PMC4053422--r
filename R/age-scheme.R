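#' Age-group schemes
#'
#' An age scheme describes the ordered age bands of a mortality surface:
#' closed-open bands `[lower, lower + width)` of a common width, optionally
#' topped by an open-ended band such as `"85+"`. The default scheme is six
#' ten-year bands from age 35 with an open-ended `"85+"` top, the grid on
#' which coronary-heart-disease mortality is conventionally tabulated.
#'
#' @param labels Character vector of band labels, e.g. `c("35-44", "85+")`.
#'   Labels must be of the form `"<lower>-<upper>"` or `"<lower>+"` (open top,
#'   last band only).
#' @return An object of class `age_scheme`: a list with `labels`,
#'   `lower_bounds` (years), `width` (common closed-band width, years) and
#'   `open_top` (logical).
#' @examples
#' age_scheme(c("35-44", "45-54", "55-64", "65-74", "75-84", "85+"))
#' @export
age_scheme <- function(labels) {
  stopifnot(is.character(labels), length(labels) >= 1L)
  open <- grepl("\\+$", labels)
  if (any(open[-length(open)])) {
    stop("only the last age band may be open-ended", call. = FALSE)
  }
  lower <- suppressWarnings(as.integer(sub("[-+].*$", "", labels)))
  if (anyNA(lower)) {
    stop("unparseable age label(s): ",
         paste(labels[is.na(lower)], collapse = ", "), call. = FALSE)
  }
  if (any(diff(lower) <= 0)) {
    stop("age-band lower bounds must be strictly increasing", call. = FALSE)
  }
  closed <- !open
  upper <- rep(NA_integer_, length(labels))
  upper[closed] <- suppressWarnings(as.integer(sub("^[0-9]+-", "", labels[closed])))
  if (anyNA(upper[closed])) {
    stop("closed age bands need the form '<lower>-<upper>'", call. = FALSE)
  }
  widths <- unique(upper[closed] - lower[closed] + 1L)
  if (length(widths) > 1L) {
    stop("all closed age bands must share one width; got widths ",
         paste(widths, collapse = ", "), call. = FALSE)
  }
  width <- if (length(widths)) widths else diff(lower)[1]
  structure(
    list(labels = labels, lower_bounds = lower,
         width = as.integer(width), open_top = any(open)),
    class = "age_scheme"
  )
}

#' @rdname age_scheme
#' @export
default_age_scheme <- function() {
  age_scheme(c("35-44", "45-54", "55-64", "65-74", "75-84", "85+"))
}

#' @export
print.age_scheme <- function(x, ...) {
  cat("<age_scheme> ", length(x$labels), " bands, width ", x$width,
      if (x$open_top) ", open top" else "", ": ",
      paste(x$labels, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
format.age_scheme <- function(x, ...) paste(x$labels, collapse = " ")

n_ages <- function(scheme) length(scheme$labels)

# Build a scheme from labels in arbitrary order (sorted by lower bound).
infer_scheme <- function(labels) {
  lower <- suppressWarnings(as.integer(sub("[-+].*$", "", labels)))
  if (anyNA(lower)) {
    stop("unparseable age label(s): ",
         paste(labels[is.na(lower)], collapse = ", "), call. = FALSE)
  }
  age_scheme(labels[order(lower)])
}

same_scheme <- function(a, b) {
  identical(a$labels, b$labels) && identical(a$lower_bounds, b$lower_bounds)
}
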