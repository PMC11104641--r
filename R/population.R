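#' Bivariate Gaussian population
#'
#' The generating distribution of the on-screen samples: an anisotropic
#' bivariate Gaussian with independent axes, vertical variance `sigma2` (mm^2)
#' and horizontal variance `sigma2 / 2` unless overridden. All the analyses in
#' this package depend on the vertical coordinate only; the horizontal
#' coordinate is carried along because the displays are two-dimensional.
#'
#' @param mean numeric length-2, population mean in mm (default the origin,
#'   i.e. the trial start position).
#' @param vertical_variance vertical variance \eqn{\sigma^2} in mm^2, > 0.
#' @param horizontal_variance horizontal variance in mm^2; defaults to
#'   `vertical_variance / 2` (the anisotropy used throughout).
#' @return an object of class `gaussian_population`.
#' @export
#' @examples
#' pop <- gaussian_population(vertical_variance = 200)
#' pop$horizontal_variance  # 100
gaussian_population <- function(mean = c(0, 0), vertical_variance,
                                horizontal_variance = vertical_variance / 2) {
  stopifnot(length(mean) == 2, is.numeric(mean), all(is.finite(mean)))
  if (!is.numeric(vertical_variance) || vertical_variance <= 0)
    stop2("vertical_variance must be > 0")
  if (!is.numeric(horizontal_variance) || horizontal_variance <= 0)
    stop2("horizontal_variance must be > 0")
  structure(
    list(mean = as.numeric(mean),
         vertical_variance = as.numeric(vertical_variance),
         horizontal_variance = as.numeric(horizontal_variance)),
    class = "gaussian_population")
}

#' @export
print.gaussian_population <- function(x, ...) {
  cat(sprintf(
    "Gaussian population: mean (%.4g, %.4g) mm, var (h %.4g, v %.4g) mm^2\n",
    x$mean[1], x$mean[2], x$horizontal_variance, x$vertical_variance))
  invisible(x)
}

#' Vertical sample statistics
#'
#' Reduces a sample of points to the summary the parametric decision maker
#' uses: the vertical sample mean, the unbiased vertical sample variance
#' (N-1 denominator) and the sample size.
#'
#' @param points a numeric matrix or data frame with columns x, y (mm), or a
#'   numeric vector of vertical coordinates.
#' @return list with `mean_y`, `s2` and `n`.
#' @export
#' @examples
#' sample_statistics(cbind(x = c(0, 0), y = c(0, 2)))  # mean 1, s2 2
sample_statistics <- function(points) {
  y <- vertical_coords(points)
  n <- length(y)
  if (n < 2) stop2("sample_statistics needs at least 2 points")
  list(mean_y = mean(y), s2 = stats::var(y), n = n)
}

# Extract vertical coordinates from the accepted point representations.
vertical_coords <- function(points) {
  if (is.matrix(points) || is.data.frame(points)) {
    cn <- colnames(points)
    y <- if (!is.null(cn) && "y" %in% cn) points[, "y"] else points[, 2]
    as.numeric(y)
  } else {
    as.numeric(points)
  }
}
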