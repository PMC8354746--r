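#' Wendland C2 smoothing kernel specification
#'
#' The solver interpolates fields with the Wendland C2 kernel
#' \deqn{W(q, h) = \frac{\alpha}{h^2}\,(1 - q/2)^4 (1 + 2q), \quad 0 \le q < 2,}
#' with \eqn{q = |r|/h} and \eqn{\alpha = 7/(4\pi)} in two dimensions. The
#' \eqn{1/h^2} factor makes the kernel a proper density so that its integral
#' over the support disc \eqn{|r| \le 2h} equals 1. Support ends at
#' \eqn{q = 2}, i.e. at radius \code{2 * h}.
#'
#' The smoothing length is conventionally tied to the particle spacing;
#' \code{h = 1.3 * dx} is the package default (see [scenario_config()]).
#'
#' @param h smoothing length in metres; must be a positive finite scalar.
#' @return An object of class \code{"kernel_spec"}: a list with fields
#'   \code{h}, \code{support} (\code{= 2 * h}) and \code{alpha2d}
#'   (\code{= 7 / (4 * pi)}).
#' @examples
#' ks <- kernel_spec(0.065)
#' ks$support            # 0.13
#' wendland_value(c(0, 0), kernel_spec(1))  # 7 / (4 * pi)
#' @export
kernel_spec <- function(h) {
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stop("smoothing length `h` must be a positive finite scalar", call. = FALSE)
  structure(list(h = h, support = 2 * h, alpha2d = 7 / (4 * pi)),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("Wendland C2 kernel: h = %g m, support = %g m, alpha2d = 7/(4*pi)\n",
              x$h, x$support))
  invisible(x)
}

as_rvec <- function(r_vec) {
  if (is.matrix(r_vec)) {
    if (ncol(r_vec) != 2L) stop("displacement matrix must have 2 columns", call. = FALSE)
    r_vec
  } else {
    if (length(r_vec) != 2L) stop("displacement must be a length-2 vector", call. = FALSE)
    matrix(r_vec, ncol = 2L)
  }
}

#' Evaluate the Wendland C2 kernel
#'
#' @param r_vec a 2D displacement: either a length-2 numeric vector or an
#'   n-by-2 matrix of displacements (metres).
#' @param spec a [kernel_spec()].
#' @return Kernel density value(s) in 1/m^2; exactly 0 outside the support
#'   (\eqn{q \ge 2}).
#' @seealso [wendland_gradient()]
#' @export
wendland_value <- function(r_vec, spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  r_vec <- as_rvec(r_vec)
  if (!all(is.finite(r_vec)))
    stop("non-finite displacement passed to wendland_value()", call. = FALSE)
  q <- sqrt(r_vec[, 1]^2 + r_vec[, 2]^2) / spec$h
  w <- ifelse(q < 2, spec$alpha2d / spec$h^2 * (1 - q / 2)^4 * (1 + 2 * q), 0)
  as.numeric(w)
}

#' Analytic gradient of the Wendland C2 kernel
#'
#' The gradient with respect to the first particle's position,
#' \eqn{\nabla_i W_{ij}}, i.e. the radial derivative
#' \eqn{dW/dr = -5\alpha q (1 - q/2)^3 / h^3} times the unit displacement.
#' Zero at the origin (the kernel is smooth there) and outside the support.
#'
#' @inheritParams wendland_value
#' @return An n-by-2 matrix of gradient vectors (1/m^3); a 1-row matrix for a
#'   single displacement.
#' @export
wendland_gradient <- function(r_vec, spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  r_vec <- as_rvec(r_vec)
  if (!all(is.finite(r_vec)))
    stop("non-finite displacement passed to wendland_gradient()", call. = FALSE)
  r <- sqrt(r_vec[, 1]^2 + r_vec[, 2]^2)
  q <- r / spec$h
  dwdr <- ifelse(q < 2, -5 * spec$alpha2d * q / spec$h^3 * (1 - q / 2)^3, 0)
  scale <- ifelse(r > 0, dwdr / r, 0)
  cbind(gx = scale * r_vec[, 1], gy = scale * r_vec[, 2])
}
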