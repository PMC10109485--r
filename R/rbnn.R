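#' Fit a radial-basis-function network surrogate
#'
#' Fits a Gaussian radial-basis-function network mapping the operating
#' parameters to one or more responses (typically the two efficacy
#' indicators HPM and ST).  Inputs are affinely scaled to the unit cube;
#' the kernel centres are the scaled training points, the kernel is
#' \eqn{\phi(r) = \exp(-r^2 / (2\sigma^2))} with a shared width
#' \eqn{\sigma}, and the output weights solve the (optionally ridge
#' regularized) linear system \eqn{(\Phi + \gamma I)W = Y}.  With
#' `regularization = 0` the network interpolates its training data exactly.
#'
#' The default width is the median pairwise distance between scaled
#' training points -- a standard heuristic that keeps kernels overlapping
#' without flattening the interpolation matrix.
#'
#' @param design Data frame of training inputs (numeric columns; typically
#'   a [latin_hypercube()] table).
#' @param responses Data frame, matrix or numeric vector of training
#'   responses, one row per design row.
#' @param width Kernel width in scaled (unit-cube) distance, or `NULL` for
#'   the median-distance heuristic.
#' @param regularization Ridge penalty `gamma >= 0` on the interpolation
#'   system.
#' @return An object of class `"rbnn"` with elements `centers`, `width`,
#'   `weights`, `scaling`, `regularization`, `response_names`, `fitted`,
#'   `residuals`, `call`.
#' @examples
#' x <- expand.grid(a = seq(0, 1, 0.25), b = seq(0, 1, 0.25))
#' fit <- rbnn(x, x$a^2 + x$b^2)
#' predict(fit, data.frame(a = 0.3, b = 0.7))
#' @seealso [predict.rbnn()], [fit_metrics()], [rbnn_to_json()]
#' @export
rbnn <- function(design, responses, width = NULL, regularization = 0) {
  design <- as.data.frame(design)[
    , vapply(as.data.frame(design), is.numeric, logical(1)), drop = FALSE]
  X <- as.matrix(design)
  if (is.null(dim(responses))) {
    Y <- matrix(as.numeric(responses), ncol = 1,
                dimnames = list(NULL, "y"))
  } else {
    Y <- as.matrix(as.data.frame(responses)[
      , vapply(as.data.frame(responses), is.numeric, logical(1)),
      drop = FALSE])
  }
  stopifnot(nrow(X) == nrow(Y), regularization >= 0)
  if (nrow(X) < ncol(X) + 1)
    stop("need at least dim + 1 = ", ncol(X) + 1, " training points",
         call. = FALSE)
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  span <- pmax(hi - lo, .Machine$double.eps)
  U <- scale_unit(X, lo, span)
  D <- as.matrix(dist(U))
  if (regularization == 0 && any(D[upper.tri(D)] < 1e-12))
    stop("duplicate design points are not allowed with regularization = 0",
         call. = FALSE)
  if (is.null(width)) width <- median(D[upper.tri(D)])
  stopifnot(width > 0)
  Phi <- exp(-D^2 / (2 * width^2))
  offset <- colMeans(Y)                 # degree-0 tail: fit deviations only
  Yc <- sweep(Y, 2, offset)
  A <- Phi + diag(regularization, nrow(Phi))
  W <- tryCatch(solve(A, Yc), error = function(e) NULL)
  gamma <- regularization
  while (is.null(W)) {
    gamma <- max(gamma * 10, 1e-10)
    warning("singular RBF system; raising regularization to ", gamma,
            call. = FALSE)
    W <- tryCatch(solve(Phi + diag(gamma, nrow(Phi)), Yc),
                  error = function(e) NULL)
    if (gamma > 1) stop("RBF system remains singular", call. = FALSE)
  }
  fitted <- sweep(Phi %*% W, 2, offset, `+`)
  structure(list(
    centers = U, width = width, weights = W, offset = offset,
    scaling = list(lo = lo, span = span),
    regularization = gamma,
    response_names = colnames(Y),
    input_names = colnames(X),
    fitted = fitted, residuals = Y - fitted,
    call = match.call()
  ), class = "rbnn")
}

scale_unit <- function(X, lo, span) sweep(sweep(X, 2, lo, `-`), 2, span, `/`)

#' Predict from a fitted RBF network
#'
#' @param object An [rbnn()] fit.
#' @param newdata Data frame or matrix of input points (columns matching
#'   the training inputs), or a single numeric vector.
#' @param warn_extrapolation Warn when a point lies more than 10% of a
#'   parameter's range outside the training domain.
#' @param ... Unused.
#' @return Numeric matrix with one row per input point and one named
#'   column per response; use `[ , "ST"]` to take a single response.
#' @export
predict.rbnn <- function(object, newdata, warn_extrapolation = TRUE, ...) {
  X <- newdata_matrix(object, newdata)
  U <- scale_unit(X, object$scaling$lo, object$scaling$span)
  if (warn_extrapolation && any(U < -0.1 | U > 1.1))
    warning("prediction point(s) lie more than 10% of the range outside ",
            "the training domain; the RBF surrogate extrapolates poorly",
            call. = FALSE)
  cross_dist2 <- outer(rowSums(U^2), rowSums(object$centers^2), `+`) -
    2 * U %*% t(object$centers)
  Phi <- exp(-pmax(cross_dist2, 0) / (2 * object$width^2))
  sweep(Phi %*% object$weights, 2, object$offset, `+`)
}

newdata_matrix <- function(object, newdata) {
  if (is.numeric(newdata) && is.null(dim(newdata)))
    newdata <- matrix(newdata, nrow = 1,
                      dimnames = list(NULL, object$input_names))
  X <- as.matrix(as.data.frame(newdata)[, object$input_names, drop = FALSE])
  storage.mode(X) <- "double"
  X
}

#' Scalar response function (and gradient) from a fitted RBF network
#'
#' Wraps one response of an [rbnn()] fit as a plain
#' `function(x) -> scalar` plus its analytic gradient -- the form the
#' interval-propagation and optimization layers consume.  The gradient of
#' the Gaussian network is
#' \eqn{\nabla f(u) = \sum_i w_i \phi_i(u) (c_i - u)/\sigma^2} in scaled
#' coordinates, chained through the affine input scaling.
#'
#' @param object An [rbnn()] fit.
#' @param response Response name (default: the first response).
#' @return List with elements `f` and `gr`, both taking a bare numeric
#'   vector in raw parameter units.
#' @export
rbnn_fun <- function(object, response = object$response_names[1]) {
  stopifnot(inherits(object, "rbnn"), response %in% object$response_names)
  w <- object$weights[, response]
  off <- object$offset[[response]]
  cen <- object$centers
  lo <- object$scaling$lo; span <- object$scaling$span
  s2 <- object$width^2
  f <- function(x) {
    u <- (x - lo) / span
    d2 <- colSums((t(cen) - u)^2)
    off + sum(w * exp(-d2 / (2 * s2)))
  }
  gr <- function(x) {
    u <- (x - lo) / span
    diff <- t(cen) - u                      # dim x n_centers
    phi <- exp(-colSums(diff^2) / (2 * s2))
    as.numeric((diff %*% (w * phi)) / s2) / span
  }
  list(f = f, gr = gr)
}

#' @export
print.rbnn <- function(x, ...) {
  cat(sprintf(
    "Gaussian RBF network: %d centres, %d input(s) [%s], %d response(s) [%s]\n",
    nrow(x$centers), length(x$input_names),
    paste(x$input_names, collapse = ", "),
    ncol(x$weights), paste(x$response_names, collapse = ", ")))
  cat(sprintf("  width %.4f (scaled), regularization %g, max |training residual| %.3g\n",
              x$width, x$regularization, max(abs(x$residuals))))
  invisible(x)
}

#' @export
coef.rbnn <- function(object, ...) object$weights

#' @export
fitted.rbnn <- function(object, ...) object$fitted

#' @export
residuals.rbnn <- function(object, ...) object$residuals

#' @export
summary.rbnn <- function(object, ...) {
  mets <- lapply(object$response_names, function(nm)
    fit_metrics(object$fitted[, nm] + object$residuals[, nm],  # training y
                object$fitted[, nm]))
  names(mets) <- object$response_names
  structure(list(model = object, training_metrics = mets),
            class = "summary.rbnn")
}

#' @export
print.summary.rbnn <- function(x, ...) {
  print(x$model)
  for (nm in names(x$training_metrics)) {
    cat("  training ", nm, ": ", sep = "")
    print(x$training_metrics[[nm]])
  }
  invisible(x)
}

#' Serialize / restore an RBF network as JSON
#'
#' Writes every component needed for exact reload (scaling, centres, width,
#' weights, regularization) to a single JSON artifact, and restores it.
#' Round-tripping reproduces predictions to full double precision.
#'
#' @param object An [rbnn()] fit.
#' @param path File path for the JSON artifact.
#' @return `rbnn_to_json` returns `path` invisibly; `rbnn_from_json`
#'   returns the restored `"rbnn"` object.
#' @export
rbnn_to_json <- function(object, path) {
  stopifnot(inherits(object, "rbnn"))
  payload <- list(
    type = "moxiopt_rbnn", version = 1L,
    input_names = object$input_names,
    response_names = object$response_names,
    lo = as.numeric(object$scaling$lo),
    span = as.numeric(object$scaling$span),
    width = object$width,
    regularization = object$regularization,
    offset = as.numeric(object$offset),
    centers = unname(object$centers),
    weights = unname(object$weights)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname rbnn_to_json
#' @export
rbnn_from_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$type, "moxiopt_rbnn"))
    stop("not a serialized moxiopt RBF network: ", path, call. = FALSE)
  centers <- matrix(unlist(p$centers), ncol = length(p$input_names),
                    byrow = FALSE)
  if (is.matrix(p$centers)) centers <- p$centers
  weights <- if (is.matrix(p$weights)) p$weights else
    matrix(unlist(p$weights), ncol = length(p$response_names))
  colnames(centers) <- p$input_names
  colnames(weights) <- p$response_names
  U <- centers
  W <- weights
  offset <- setNames(p$offset, p$response_names)
  Phi <- exp(-as.matrix(dist(U))^2 / (2 * p$width^2))
  fitted <- sweep(Phi %*% W, 2, offset, `+`)
  structure(list(
    centers = U, width = p$width, weights = W, offset = offset,
    scaling = list(lo = setNames(p$lo, p$input_names),
                   span = setNames(p$span, p$input_names)),
    regularization = p$regularization,
    response_names = p$response_names,
    input_names = p$input_names,
    fitted = fitted, residuals = fitted * NA,
    call = quote(rbnn_from_json())
  ), class = "rbnn")
}
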