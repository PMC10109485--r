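#' Closed real intervals
#'
#' An `interval` is the package's universal carrier of parameter and response
#' uncertainty: a closed set \[lower, upper\] with no distributional
#' assumption, equivalently written midpoint +/- radius.  Every uncertain
#' operating parameter (moxa burning temperature, stick diameter,
#' stick-to-skin distance, skin moisture content) and every uncertain
#' response (ST, HPM) is one of these.
#'
#' @param lower,upper Numeric scalars with `lower <= upper`.
#' @return An object of class `"interval"`: a named numeric vector with
#'   elements `lower` and `upper`.
#' @examples
#' interval(600, 650)            # moxa burning temperature range, deg C
#' interval_cr(625, 25)          # the same interval, midpoint/radius form
#' int_mid(interval(600, 650))   # 625
#' @seealso [rpdi()] for comparing two intervals, [box()] for a
#'   multidimensional product of intervals.
#' @export
interval <- function(lower, upper) {
  stopifnot(is.numeric(lower), is.numeric(upper),
            length(lower) == 1L, length(upper) == 1L,
            is.finite(lower), is.finite(upper))
  if (lower > upper)
    stop("reversed bounds: lower (", lower, ") exceeds upper (", upper,
         "); an interval needs lower <= upper", call. = FALSE)
  structure(c(lower = as.numeric(lower), upper = as.numeric(upper)),
            class = "interval")
}

#' @rdname interval
#' @param center Interval midpoint.
#' @param radius Interval half-width, `radius >= 0`.
#' @export
interval_cr <- function(center, radius) {
  stopifnot(is.numeric(center), is.numeric(radius),
            length(center) == 1L, length(radius) == 1L)
  if (radius < 0)
    stop("negative radius (", radius, "); an interval radius must be >= 0",
         call. = FALSE)
  interval(center - radius, center + radius)
}

#' @rdname interval
#' @param x An `interval`.
#' @export
int_lower <- function(x) unclass(x)[["lower"]]

#' @rdname interval
#' @export
int_upper <- function(x) unclass(x)[["upper"]]

#' @rdname interval
#' @export
int_mid <- function(x) (unclass(x)[["lower"]] + unclass(x)[["upper"]]) / 2

#' @rdname interval
#' @export
int_rad <- function(x) (unclass(x)[["upper"]] - unclass(x)[["lower"]]) / 2

#' @export
print.interval <- function(x, digits = 6, ...) {
  cat(format(x, digits = digits), "\n")
  invisible(x)
}

#' @export
format.interval <- function(x, digits = 6, ...) {
  sprintf("[%s, %s] (mid %s, rad %s)",
          format(int_lower(x), digits = digits),
          format(int_upper(x), digits = digits),
          format(int_mid(x), digits = digits),
          format(int_rad(x), digits = digits))
}

is_interval <- function(x) inherits(x, "interval")

#' Test membership in a closed interval
#'
#' Membership uses closed bounds with a small absolute tolerance so that
#' optimizer iterates sitting exactly on a bound are not rejected by
#' floating-point noise.
#'
#' @param x Numeric vector of candidate values.
#' @param int An [interval()].
#' @param tol Absolute tolerance in the units of the quantity.
#' @return Logical vector.
#' @export
int_contains <- function(x, int, tol = 1e-9) {
  x >= int_lower(int) - tol & x <= int_upper(int) + tol
}

#' Multidimensional boxes of intervals
#'
#' A `box` is an ordered, named list of [interval()]s, one per parameter
#' dimension.  It represents either the outer design domain of the uncertain
#' operating parameters or one candidate's uncertainty box (midpoints +/-
#' fixed radii) inside that domain.
#'
#' @param ... Named `interval` objects, or a single named list of them.
#' @return An object of class `"box"`.
#' @examples
#' design_domain()  # the standard 4-parameter operating domain
#' box(t1 = interval(600, 650), h = interval(25, 35))
#' @export
box <- function(...) {
  ints <- list(...)
  if (length(ints) == 1L && is.list(ints[[1]]) && !is_interval(ints[[1]]))
    ints <- ints[[1]]
  if (length(ints) < 1L) stop("a box needs at least one interval", call. = FALSE)
  ok <- vapply(ints, is_interval, logical(1))
  if (!all(ok)) stop("all box members must be 'interval' objects", call. = FALSE)
  if (is.null(names(ints)) || any(!nzchar(names(ints))))
    names(ints) <- paste0("x", seq_along(ints))
  structure(ints, class = "box")
}

#' @rdname box
#' @param x A `box`.
#' @export
box_lower <- function(x) vapply(x, int_lower, numeric(1))

#' @rdname box
#' @export
box_upper <- function(x) vapply(x, int_upper, numeric(1))

#' @rdname box
#' @export
box_mid <- function(x) vapply(x, int_mid, numeric(1))

#' @rdname box
#' @export
box_rad <- function(x) vapply(x, int_rad, numeric(1))

#' @export
print.box <- function(x, ...) {
  cat("box over", length(x), "parameter(s):\n")
  for (nm in names(x)) cat("  ", nm, ": ", format(x[[nm]]), "\n", sep = "")
  invisible(x)
}

#' Reliability-based possibility degree of interval (RPDI)
#'
#' `rpdi(A, B)` quantifies how reliably interval `A` lies below interval `B`:
#' \deqn{pr(A \le B) = \frac{B^R - A^L}{2A^\omega + 2B^\omega}}
#' where superscripts L/R denote lower/upper bounds and \eqn{\omega} the
#' radius.  Values at or above 1 mean `A <= B` holds with certainty; values
#' at or below 0 mean it certainly fails; intermediate values grade the
#' overlap.  The measure is complementary: `rpdi(A, B) + rpdi(B, A) = 1`
#' whenever at least one radius is positive.
#'
#' When `B` is a plain number `b` (a degenerate interval of zero radius) the
#' expression reduces to \eqn{(b - A^L) / (2A^\omega)}, which is how the
#' skin-surface-temperature interval is compared with the 45.5 deg C
#' allowable value.
#'
#' Degenerate conventions (both radii zero): the limit reading is used so
#' optimizer edge cases do not abort -- `+Inf` when `A` lies strictly below,
#' `-Inf` when strictly above, and `0.5` when the two points coincide.
#'
#' @param A An [interval()].
#' @param B An [interval()], or a numeric scalar treated as a degenerate
#'   interval.
#' @return A single numeric possibility degree (may be outside \[0, 1\] and,
#'   in degenerate cases, infinite).
#' @examples
#' rpdi(interval(2, 4), interval(6, 8))   # 1.5: certainly below
#' rpdi(interval(0, 1), interval(0, 1))   # 0.5: symmetric overlap
#' rpdi(interval(40.99, 45.50), 45.5)     # 1.0: upper bound at the allowable
#' @export
rpdi <- function(A, B) {
  stopifnot(is_interval(A))
  if (is.numeric(B) && length(B) == 1L && !is_interval(B))
    B <- interval(B, B)
  stopifnot(is_interval(B))
  denom <- 2 * int_rad(A) + 2 * int_rad(B)
  if (denom == 0) {
    a <- int_lower(A); b <- int_lower(B)
    if (a < b) return(Inf)
    if (a > b) return(-Inf)
    return(0.5)
  }
  (int_upper(B) - int_lower(A)) / denom
}

#' @rdname rpdi
#' @param b Numeric scalar: the degenerate comparison value.
#' @export
rpdi_degenerate <- function(A, b) rpdi(A, interval(b, b))
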