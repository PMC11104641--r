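#' Isotropic Gaussian endpoint model
#'
#' The distribution of movement end points around an aim point: an isotropic
#' bivariate Gaussian with standard deviation `sd` (mm).
#'
#' @param aim_point numeric length-2, aim point in mm.
#' @param sd isotropic standard deviation in mm, > 0.
#' @return an object of class `endpoint_model`.
#' @export
endpoint_model <- function(aim_point = c(0, 0), sd) {
  stopifnot(length(aim_point) == 2, all(is.finite(aim_point)))
  if (!is.numeric(sd) || sd <= 0) stop2("endpoint sd must be > 0")
  structure(list(aim_point = as.numeric(aim_point), sd = as.numeric(sd)),
            class = "endpoint_model")
}

#' Interval specification for the estimation tasks
#'
#' Intervals are expressed in multiples `w` of the population vertical
#' standard deviation, in one of three configurations: the symmetric interval
#' `[-w sigma, +w sigma]`, its upper half `[0, +w sigma]` or its lower half
#' `[-w sigma, 0]`. The two halves are disjoint and their union is the
#' symmetric interval.
#'
#' @param configuration one of "symmetric", "upper_half", "lower_half".
#' @param width_multiple the width multiple `w` (unitless), >= 0.
#' @return an object of class `interval_spec`.
#' @export
interval_spec <- function(configuration = c("symmetric", "upper_half",
                                            "lower_half"),
                          width_multiple) {
  configuration <- match.arg(configuration)
  if (!is.numeric(width_multiple) || !is.finite(width_multiple) ||
      width_multiple < 0)
    stop2("width_multiple must be finite and >= 0")
  structure(list(configuration = configuration,
                 width_multiple = as.numeric(width_multiple)),
            class = "interval_spec")
}

#' The nine interval width multiples used in the estimation tasks
#'
#' Symmetric-interval probabilities run from 0.1 to 0.9 in steps of 0.1;
#' upper/lower-half probabilities from 0.05 to 0.45.
#' @return numeric vector of length 9.
#' @export
estimation_widths <- function() {
  c(0.126, 0.253, 0.385, 0.524, 0.674, 0.842, 1.036, 1.282, 1.645)
}

#' Probability that a Gaussian draw lands in an interval
#'
#' For a draw centred at the interval's axis of symmetry, the symmetric
#' interval of half-width `w` sigma has probability `2 Phi(w) - 1`, and each
#' half interval has probability `Phi(w) - 1/2`. The result does not depend on
#' sigma because the width is expressed in sigma units.
#'
#' @param spec an [interval_spec()], or a configuration string when
#'   `width_multiple` is given separately.
#' @param width_multiple optional numeric, used with a string `spec`.
#' @return probability in `[0, 1]` (vectorised over `width_multiple`).
#' @export
#' @examples
#' interval_probability(interval_spec("symmetric", 1.645))   # ~0.90
#' interval_probability("upper_half", 1.645)                 # ~0.45
interval_probability <- function(spec, width_multiple = NULL) {
  if (is.character(spec)) {
    configuration <- match.arg(spec, c("symmetric", "upper_half", "lower_half"))
    w <- width_multiple
  } else {
    stopifnot(inherits(spec, "interval_spec"))
    configuration <- spec$configuration
    w <- spec$width_multiple
  }
  if (!is.numeric(w) || anyNA(w) || any(!is.finite(w)) || any(w < 0))
    stop2("width_multiple must be finite and >= 0")
  if (configuration == "symmetric") 2 * stats::pnorm(w) - 1
  else stats::pnorm(w) - 0.5
}

## ---- regions -------------------------------------------------------------

new_region <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "region")
}

#' Region constructors
#'
#' Planar regions over which endpoint probabilities are computed: the open
#' half plane above a horizontal line, a vertical interval (infinite strip),
#' a disc, an axis-aligned rectangle, and unions / differences of regions.
#' Unions declared `disjoint = TRUE` are validated before being used for
#' additivity claims.
#'
#' @param y0 boundary height in mm.
#' @param ylim,xlim numeric length-2 ranges in mm.
#' @param center numeric length-2 centre in mm.
#' @param radius disc radius in mm, > 0.
#' @param ... constituent regions for `region_union`.
#' @param disjoint logical; assert that the union constituents are pairwise
#'   disjoint (checked numerically by [region_probability()]).
#' @param a,b regions; `region_difference(a, b)` is the set difference a \\ b.
#' @return an object of class `region`.
#' @name regions
NULL

#' @rdname regions
#' @export
region_half_plane_above <- function(y0) new_region("half_plane_above",
                                                   y0 = as.numeric(y0))

#' @rdname regions
#' @export
region_interval <- function(ylim) {
  stopifnot(length(ylim) == 2, ylim[1] <= ylim[2])
  new_region("interval", ylim = as.numeric(ylim))
}

#' @rdname regions
#' @export
region_disc <- function(center, radius) {
  stopifnot(length(center) == 2, is.finite(radius), radius > 0)
  new_region("disc", center = as.numeric(center), radius = as.numeric(radius))
}

#' @rdname regions
#' @export
region_rect <- function(xlim, ylim) {
  stopifnot(length(xlim) == 2, length(ylim) == 2,
            xlim[1] <= xlim[2], ylim[1] <= ylim[2])
  new_region("rect", xlim = as.numeric(xlim), ylim = as.numeric(ylim))
}

#' @rdname regions
#' @export
region_union <- function(..., disjoint = FALSE) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "region")) parts <- parts[[1]]
  stopifnot(length(parts) >= 1, all(vapply(parts, inherits, TRUE, "region")))
  new_region("union", parts = parts, disjoint = isTRUE(disjoint))
}

#' @rdname regions
#' @export
region_empty <- function() new_region("empty")

#' @rdname regions
#' @export
region_difference <- function(a, b) {
  stopifnot(inherits(a, "region"), inherits(b, "region"))
  new_region("difference", a = a, b = b)
}

# Horizontal extent [xmin, xmax] of a region (may be infinite).
region_xrange <- function(region) {
  switch(region$kind,
    empty = c(0, 0),
    half_plane_above = c(-Inf, Inf),
    interval = c(-Inf, Inf),
    disc = region$center[1] + c(-1, 1) * region$radius,
    rect = region$xlim,
    union = {
      rs <- vapply(region$parts, region_xrange, numeric(2))
      c(min(rs[1, ]), max(rs[2, ]))
    },
    difference = region_xrange(region$a),
    stop2("unknown region kind: ", region$kind))
}

# Cross-section of a region at horizontal coordinate x: a 2-row matrix-less
# representation, list of y-intervals as a 2-column matrix (lo, hi).
region_yslice <- function(region, x) {
  switch(region$kind,
    empty = matrix(numeric(0), ncol = 2),
    half_plane_above = cbind(region$y0, Inf),
    interval = cbind(region$ylim[1], region$ylim[2]),
    disc = {
      dx2 <- region$radius^2 - (x - region$center[1])^2
      if (dx2 <= 0) matrix(numeric(0), ncol = 2)
      else cbind(region$center[2] - sqrt(dx2), region$center[2] + sqrt(dx2))
    },
    rect = {
      if (x < region$xlim[1] || x > region$xlim[2])
        matrix(numeric(0), ncol = 2)
      else cbind(region$ylim[1], region$ylim[2])
    },
    union = merge_intervals(do.call(
      rbind, lapply(region$parts, region_yslice, x = x))),
    difference = subtract_intervals(region_yslice(region$a, x),
                                    region_yslice(region$b, x)),
    stop2("unknown region kind: ", region$kind))
}

# Merge possibly overlapping y-intervals into a disjoint sorted set.
merge_intervals <- function(iv) {
  if (nrow(iv) <= 1) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (k in 2:nrow(iv)) {
    last <- nrow(out)
    if (iv[k, 1] <= out[last, 2]) out[last, 2] <- max(out[last, 2], iv[k, 2])
    else out <- rbind(out, iv[k, ])
  }
  out
}

# Set-subtract intervals b from intervals a (both disjoint sorted sets).
subtract_intervals <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(a)
  out <- matrix(numeric(0), ncol = 2)
  for (k in seq_len(nrow(a))) {
    pieces <- a[k, , drop = FALSE]
    for (j in seq_len(nrow(b))) {
      nxt <- matrix(numeric(0), ncol = 2)
      for (i in seq_len(nrow(pieces))) {
        lo <- pieces[i, 1]; hi <- pieces[i, 2]
        blo <- b[j, 1]; bhi <- b[j, 2]
        if (bhi <= lo || blo >= hi) nxt <- rbind(nxt, c(lo, hi))
        else {
          if (blo > lo) nxt <- rbind(nxt, c(lo, blo))
          if (bhi < hi) nxt <- rbind(nxt, c(bhi, hi))
        }
      }
      pieces <- nxt
    }
    out <- rbind(out, pieces)
  }
  out
}

# Total overlap between the y-slices of two regions at x (length measure).
slice_overlap_length <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  tot <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    lo <- max(a[i, 1], b[j, 1]); hi <- min(a[i, 2], b[j, 2])
    if (hi > lo) tot <- tot + (hi - lo)
  }
  tot
}

#' Probability that an endpoint lands in a region
#'
#' Rectangles and vertical intervals use closed-form products of 1-D Gaussian
#' CDF differences. Discs, unions, and differences are integrated by 1-D
#' adaptive quadrature over the horizontal coordinate, with the vertical
#' probability mass of each cross-section in closed form (absolute tolerance
#' 1e-7). A union declared disjoint is validated on a grid of cross-sections;
#' overlapping constituents raise an error.
#'
#' @param region a [region][regions] object.
#' @param model an [endpoint_model()].
#' @param abs_tol absolute quadrature tolerance.
#' @return probability in `[0, 1]`.
#' @export
#' @examples
#' m <- endpoint_model(c(0, 0), sd = 2)
#' region_probability(region_disc(c(0, 0), 2), m)  # 1 - exp(-1/2)
region_probability <- function(region, model, abs_tol = 1e-7) {
  stopifnot(inherits(region, "region"), inherits(model, "endpoint_model"))
  ax <- model$aim_point[1]; ay <- model$aim_point[2]; s <- model$sd
  switch(region$kind,
    empty = 0,
    half_plane_above = stats::pnorm((region$y0 - ay) / s, lower.tail = FALSE),
    interval = stats::pnorm((region$ylim[2] - ay) / s) -
               stats::pnorm((region$ylim[1] - ay) / s),
    rect = (stats::pnorm((region$xlim[2] - ax) / s) -
            stats::pnorm((region$xlim[1] - ax) / s)) *
           (stats::pnorm((region$ylim[2] - ay) / s) -
            stats::pnorm((region$ylim[1] - ay) / s)),
    union = {
      if (region$disjoint) {
        validate_disjoint(region, model)
        sum(vapply(region$parts, region_probability, 0,
                   model = model, abs_tol = abs_tol))
      } else {
        quad_region_probability(region, model, abs_tol)
      }
    },
    quad_region_probability(region, model, abs_tol))
}

# Numeric check that union constituents are pairwise disjoint.
validate_disjoint <- function(region, model) {
  parts <- region$parts
  if (length(parts) < 2) return(invisible(TRUE))
  xr <- region_xrange(region)
  lo <- max(xr[1], model$aim_point[1] - 12 * model$sd)
  hi <- min(xr[2], model$aim_point[1] + 12 * model$sd)
  if (!is.finite(lo)) lo <- model$aim_point[1] - 12 * model$sd
  if (!is.finite(hi)) hi <- model$aim_point[1] + 12 * model$sd
  xs <- seq(lo, hi, length.out = 201)
  for (i in seq_len(length(parts) - 1)) for (j in (i + 1):length(parts)) {
    ov <- vapply(xs, function(x)
      slice_overlap_length(region_yslice(parts[[i]], x),
                           region_yslice(parts[[j]], x)), 0)
    if (any(ov > 1e-9))
      stop2("region_union(disjoint = TRUE): constituents ", i, " and ", j,
            " overlap")
  }
  invisible(TRUE)
}

quad_region_probability <- function(region, model, abs_tol) {
  ax <- model$aim_point[1]; ay <- model$aim_point[2]; s <- model$sd
  xr <- region_xrange(region)
  lo <- max(xr[1], ax - 10 * s)
  hi <- min(xr[2], ax + 10 * s)
  if (!is.finite(lo)) lo <- ax - 10 * s
  if (!is.finite(hi)) hi <- ax + 10 * s
  if (hi <= lo) return(0)
  f <- function(x) {
    vapply(x, function(xi) {
      iv <- region_yslice(region, xi)
      if (nrow(iv) == 0) return(0)
      sum(stats::pnorm((iv[, 2] - ay) / s) - stats::pnorm((iv[, 1] - ay) / s))
    }, 0) * stats::dnorm(x, ax, s)
  }
  val <- stats::integrate(f, lo, hi, abs.tol = abs_tol,
                          subdivisions = 400L)$value
  min(max(val, 0), 1)
}
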