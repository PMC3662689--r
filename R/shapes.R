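#' Rectangular target
#'
#' Constructs an axis-aligned rectangular target. Coordinates are in mm with
#' the origin at the aim point (target centroid unless an offset is given),
#' x rightward and y upward.
#'
#' @param w,h Width and height in mm; both must be positive.
#' @param center Numeric length-2 offset (mm) of the rectangle centroid from
#'   the aim point.
#' @return An object of class `target_shape`.
#' @seealso [circle_target()], [rect_hit_prob()]
#' @export
rect_target <- function(w, h, center = c(0, 0)) {
  stopifnot(is.numeric(w), is.numeric(h), length(w) == 1L, length(h) == 1L)
  if (!is.finite(w) || !is.finite(h) || w <= 0 || h <= 0)
    stop("rectangle sides must be positive and finite")
  stopifnot(is.numeric(center), length(center) == 2L, all(is.finite(center)))
  structure(list(kind = "rectangle", w = w, h = h, center = as.numeric(center)),
            class = "target_shape")
}

#' Circular target
#'
#' @param r Radius in mm; must be positive.
#' @param center Numeric length-2 offset (mm) of the circle center from the
#'   aim point.
#' @return An object of class `target_shape`.
#' @seealso [rect_target()], [circle_hit_prob()]
#' @export
circle_target <- function(r, center = c(0, 0)) {
  stopifnot(is.numeric(r), length(r) == 1L)
  if (!is.finite(r) || r <= 0) stop("circle radius must be positive and finite")
  stopifnot(is.numeric(center), length(center) == 2L, all(is.finite(center)))
  structure(list(kind = "circle", r = r, center = as.numeric(center)),
            class = "target_shape")
}

#' @export
print.target_shape <- function(x, ...) {
  if (x$kind == "rectangle") {
    cat(sprintf("<target> rectangle %g x %g mm, center (%g, %g)\n",
                x$w, x$h, x$center[1], x$center[2]))
  } else {
    cat(sprintf("<target> circle r = %g mm, center (%g, %g)\n",
                x$r, x$center[1], x$center[2]))
  }
  invisible(x)
}

is_rect <- function(x) inherits(x, "target_shape") && x$kind == "rectangle"
is_circle <- function(x) inherits(x, "target_shape") && x$kind == "circle"

#' Gaussian internal model of motor error
#'
#' The error distribution a chooser implicitly assumes about her own
#' endpoints: a centered bivariate Gaussian parameterized by a variance
#' parameter `sigma2_tilde` (geometric-mean variance, mm^2) and an anisotropy
#' parameter `eta_tilde` (vertical-to-horizontal SD ratio), so that the
#' per-axis SDs are `sqrt(sigma2_tilde / eta_tilde)` horizontally and
#' `sqrt(sigma2_tilde * eta_tilde)` vertically.
#'
#' @param sigma2_tilde Internal variance parameter in mm^2 (> 0).
#' @param eta_tilde Internal anisotropy parameter (> 0); 1 means isotropic.
#' @return An object of class `internal_model`.
#' @export
gaussian_internal_model <- function(sigma2_tilde, eta_tilde = 1) {
  stopifnot(is.numeric(sigma2_tilde), length(sigma2_tilde) == 1L,
            is.numeric(eta_tilde), length(eta_tilde) == 1L)
  if (!is.finite(sigma2_tilde) || sigma2_tilde <= 0)
    stop("sigma2_tilde must be positive")
  if (!is.finite(eta_tilde) || eta_tilde <= 0)
    stop("eta_tilde must be positive")
  structure(list(form = "gaussian", sigma2_tilde = sigma2_tilde,
                 eta_tilde = eta_tilde),
            class = "internal_model")
}

#' Area-matching internal model
#'
#' The limiting chooser who ranks targets purely by area; the infinite
#' variance limit of the Gaussian internal model. Has no shape parameters.
#'
#' @return An object of class `internal_model`.
#' @export
area_matching_model <- function() {
  structure(list(form = "area_matching"), class = "internal_model")
}

#' Uniform-disk internal model
#'
#' A chooser who assumes her endpoints fall uniformly inside a disk of fixed
#' radius centered on the aim point. A disk of radius R has per-axis SD R/2,
#' so a chooser who "knows her SD" sets `disk_radius = 2 * sd`.
#'
#' @param disk_radius Disk radius in mm (> 0).
#' @return An object of class `internal_model`.
#' @export
uniform_disk_model <- function(disk_radius) {
  stopifnot(is.numeric(disk_radius), length(disk_radius) == 1L)
  if (!is.finite(disk_radius) || disk_radius <= 0)
    stop("disk_radius must be positive")
  structure(list(form = "uniform_disk", disk_radius = disk_radius),
            class = "internal_model")
}

#' @export
print.internal_model <- function(x, ...) {
  switch(x$form,
    gaussian = cat(sprintf(
      "<internal model> Gaussian: sigma2~ = %.4g mm^2, eta~ = %.4g\n",
      x$sigma2_tilde, x$eta_tilde)),
    area_matching = cat("<internal model> area matching\n"),
    uniform_disk = cat(sprintf("<internal model> uniform disk, R = %.4g mm\n",
                               x$disk_radius)))
  invisible(x)
}

#' True motor error distribution
#'
#' A centered bivariate Gaussian description of reach endpoints. Alongside
#' the per-axis standard deviations and their correlation, the derived
#' quantities used throughout are stored: the variance parameter
#' `sigma2 = sigma_h * sigma_v` (mm^2), the anisotropy `eta =
#' sigma_v / sigma_h` and the mean standard deviation
#' `sigma_bar = (sigma_h + sigma_v) / 2` (mm), which sets the scale of the
#' choice-task rectangles.
#'
#' @param sigma_h,sigma_v Horizontal and vertical endpoint SD in mm (> 0).
#' @param rho Pearson correlation of the two axes, strictly inside (-1, 1).
#' @param n_used Number of endpoints the estimate is based on (optional).
#' @return An object of class `motor_error`.
#' @seealso [fit_true_distribution()]
#' @export
motor_error <- function(sigma_h, sigma_v, rho = 0, n_used = NA_integer_) {
  stopifnot(is.numeric(sigma_h), is.numeric(sigma_v), is.numeric(rho))
  if (!is.finite(sigma_h) || sigma_h <= 0) stop("sigma_h must be positive")
  if (!is.finite(sigma_v) || sigma_v <= 0) stop("sigma_v must be positive")
  if (!is.finite(rho) || abs(rho) >= 1) stop("rho must lie strictly in (-1, 1)")
  structure(list(sigma_h = sigma_h, sigma_v = sigma_v, rho = rho,
                 n_used = n_used,
                 sigma2 = sigma_h * sigma_v,
                 eta = sigma_v / sigma_h,
                 sigma_bar = (sigma_h + sigma_v) / 2),
            class = "motor_error")
}

#' @export
print.motor_error <- function(x, ...) {
  cat(sprintf(paste0(
    "<motor error> sigma_h = %.3f mm, sigma_v = %.3f mm, rho = %.3f\n",
    "  sigma2 = %.3f mm^2, eta = %.3f, sigma_bar = %.3f mm"),
    x$sigma_h, x$sigma_v, x$rho, x$sigma2, x$eta, x$sigma_bar))
  if (!is.na(x$n_used)) cat(sprintf("  (n = %d endpoints)", x$n_used))
  cat("\n")
  invisible(x)
}

# per-axis SDs implied by an internal Gaussian model
gaussian_model_sds <- function(model) {
  c(sigma_h = sqrt(model$sigma2_tilde / model$eta_tilde),
    sigma_v = sqrt(model$sigma2_tilde * model$eta_tilde))
}
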