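#' Double-angle representation of astigmatism
#'
#' An astigmatism of magnitude `m` dioptres at axis `a` degrees maps to the
#' Cartesian point `(m cos 2a, m sin 2a)`. Doubling the angle makes
#' physically opposite astigmatisms antipodal, so astigmatism vectors add,
#' subtract and average like ordinary 2-vectors; this is the space in which
#' centroids, surgically induced astigmatism and double-angle plots live.
#'
#' @param magnitude Astigmatism magnitude in dioptres (>= 0).
#' @param axis Steep-meridian axis in degrees.
#' @return `to_double_angle()`: tibble with columns `x`, `y`.
#' @examples
#' to_double_angle(1, 90)          # (-1, 0)
#' from_double_angle(0, 1)         # 1 D @ 45
#' @export
to_double_angle <- function(magnitude, axis) {
  check_finite(magnitude = magnitude, axis = axis)
  if (any(magnitude < 0)) abort("`magnitude` must be non-negative.")
  a2 <- 2 * axis * pi / 180
  fast_df(x = magnitude * cos(a2), y = magnitude * sin(a2))
}

#' @rdname to_double_angle
#' @param x,y Double-angle Cartesian components (D).
#' @return `from_double_angle()`: tibble with columns `magnitude`, `axis`
#'   (degrees in `[0, 180)`; the axis of a zero vector canonicalises to 0).
#' @export
from_double_angle <- function(x, y) {
  check_finite(x = x, y = y)
  magnitude <- sqrt(x^2 + y^2)
  axis <- (atan2(y, x) * 180 / pi / 2) %% 180
  fast_df(magnitude = magnitude, axis = ifelse(magnitude <= 1e-15, 0, axis))
}

#' Centroid of a set of astigmatism vectors
#'
#' Component-wise mean in double-angle space, re-expressed as
#' magnitude-at-axis, with the sample standard deviations of the two
#' components (the "1.09 D @ 89 +/- 1.91 D" reporting style used with
#' double-angle plots).
#'
#' @param data Data frame with one astigmatism vector per row.
#' @param magnitude,axis Columns of `data` holding magnitude (D) and axis
#'   (degrees); tidy-eval, defaults `magnitude` and `axis`.
#' @return One-row tibble: `magnitude`, `axis`, `sd_x`, `sd_y`, `n`.
#' @examples
#' eyes <- tibble::tibble(magnitude = c(1, 1), axis = c(0, 45))
#' astig_centroid(eyes)    # about 0.71 D @ 22.5
#' @export
astig_centroid <- function(data, magnitude = magnitude, axis = axis) {
  mag <- dplyr::pull(data, {{ magnitude }})
  ax <- dplyr::pull(data, {{ axis }})
  if (!length(mag)) abort("`data` must contain at least one vector.")
  da <- to_double_angle(mag, ax)
  centre <- from_double_angle(mean(da$x), mean(da$y))
  tibble(
    magnitude = centre$magnitude,
    axis = centre$axis,
    sd_x = if (length(mag) > 1) sd(da$x) else 0,
    sd_y = if (length(mag) > 1) sd(da$y) else 0,
    n = length(mag)
  )
}

#' Difference of astigmatism vectors
#'
#' Component-wise subtraction `a - b` in double-angle space. The operation
#' is linear, so the difference of centroids equals the centroid of
#' per-eye differences.
#'
#' @param magnitude_a,axis_a,magnitude_b,axis_b Magnitudes (D) and axes
#'   (degrees) of the two vector sets (recycled as usual).
#' @return Tibble with columns `magnitude`, `axis`.
#' @examples
#' astig_difference(2, 0, 1, 0)   # 1 D @ 0
#' @export
astig_difference <- function(magnitude_a, axis_a, magnitude_b, axis_b) {
  a <- to_double_angle(magnitude_a, axis_a)
  b <- to_double_angle(magnitude_b, axis_b)
  from_double_angle(a$x - b$x, a$y - b$y)
}

#' Surgically induced astigmatism (SIA)
#'
#' The vector change in corneal astigmatism caused by surgery, computed in
#' double-angle space as postoperative minus preoperative. Sign convention:
#' the returned vector is the *induced* astigmatism (what the incision
#' added); the preoperative-minus-postoperative reduction is its negation
#' (same magnitude, axis + 90).
#'
#' @param preop_magnitude,preop_axis,postop_magnitude,postop_axis Pre- and
#'   postoperative corneal astigmatism.
#' @return Tibble with columns `magnitude`, `axis`.
#' @export
surgically_induced_astigmatism <- function(preop_magnitude, preop_axis,
                                           postop_magnitude, postop_axis) {
  astig_difference(postop_magnitude, postop_axis, preop_magnitude, preop_axis)
}

#' SIA prediction error
#'
#' Vector difference between the preoperatively assumed SIA and the
#' achieved SIA, per eye. Averaging per-eye errors (see [astig_centroid()])
#' equals the difference of the assumed vector and the achieved centroid,
#' by linearity.
#'
#' @param assumed_magnitude,assumed_axis Assumed SIA vector.
#' @param achieved_magnitude,achieved_axis Achieved SIA vector(s).
#' @return Tibble with columns `magnitude`, `axis`.
#' @export
sia_prediction_error <- function(assumed_magnitude, assumed_axis,
                                 achieved_magnitude, achieved_axis) {
  astig_difference(assumed_magnitude, assumed_axis,
                   achieved_magnitude, achieved_axis)
}

#' Angular misalignment between two cylinder axes
#'
#' Minimal absolute angular distance modulo 180 degrees, in `[0, 90]`.
#' Symmetric in its arguments and invariant to adding 180 to either axis.
#'
#' @param intended_axis,observed_axis Axes in degrees.
#' @return Numeric vector of misalignments in degrees.
#' @examples
#' axis_misalignment(179, 1)   # 2
#' @export
axis_misalignment <- function(intended_axis, observed_axis) {
  check_finite(intended_axis = intended_axis, observed_axis = observed_axis)
  d <- abs(intended_axis - observed_axis) %% 180
  pmin(d, 180 - d)
}

#' Cumulative percentages within thresholds
#'
#' For each threshold, the count and percentage of values whose absolute
#' value does not exceed it -- the construction behind "x% of eyes within
#' 0.5 D" tables and cumulative histograms (counts are reported alongside
#' percentages). Percentages are non-decreasing in the threshold.
#'
#' @param values Numeric vector (dioptres or degrees); absolute values are
#'   compared.
#' @param thresholds Sorted ascending numeric vector of thresholds.
#' @return Tibble with columns `threshold`, `n_within`, `pct_within`.
#' @examples
#' cumulative_within(c(0.2, 0.4, 0.8), c(0.25, 0.5, 1))
#' @export
cumulative_within <- function(values, thresholds) {
  check_finite(values = values, thresholds = thresholds)
  if (!length(values)) abort("`values` must be non-empty.")
  if (is.unsorted(thresholds)) abort("`thresholds` must be sorted ascending.")
  n_within <- vapply(thresholds,
                     function(t) sum(abs(values) <= t + 1e-9), integer(1))
  tibble(
    threshold = thresholds,
    n_within = n_within,
    pct_within = 100 * n_within / length(values)
  )
}

#' Coordinates for a double-angle plot
#'
#' Per-vector double-angle coordinates, the centroid, and a 95% ellipse
#' derived from the component covariance (chi-square quantile with 2 degrees
#' of freedom), i.e. the data ellipse of the standard astigmatism
#' double-angle plot. With fewer than two vectors the ellipse degenerates to
#' the centroid point.
#'
#' @inheritParams astig_centroid
#' @param conf Ellipse coverage level (default 0.95).
#' @return A list of class `double_angle_data`: `points` (tibble `x`, `y`,
#'   `magnitude`, `axis`), `centroid` (one row, with `sd_x`, `sd_y`),
#'   `ellipse` (closed path tibble `x`, `y`) and `ellipse_axes` (one-row
#'   tibble `semi_major`, `semi_minor`, `angle_deg`).
#' @seealso [plot_double_angle()]
#' @export
double_angle_plot_data <- function(data, magnitude = magnitude, axis = axis,
                                   conf = 0.95) {
  mag <- dplyr::pull(data, {{ magnitude }})
  ax <- dplyr::pull(data, {{ axis }})
  if (!length(mag)) abort("`data` must contain at least one vector.")
  da <- to_double_angle(mag, ax)
  pts <- dplyr::bind_cols(da, tibble(magnitude = mag, axis = ax))
  centre <- astig_centroid(tibble(magnitude = mag, axis = ax))
  cx <- mean(da$x)
  cy <- mean(da$y)
  if (length(mag) > 1) {
    sigma <- cov(cbind(da$x, da$y))
    eg <- eigen(sigma, symmetric = TRUE)
    radii <- sqrt(pmax(eg$values, 0) * qchisq(conf, df = 2))
    ang <- atan2(eg$vectors[2, 1], eg$vectors[1, 1])
  } else {
    radii <- c(0, 0)
    ang <- 0
  }
  theta <- seq(0, 2 * pi, length.out = 181)
  ellipse <- tibble(
    x = cx + radii[1] * cos(theta) * cos(ang) - radii[2] * sin(theta) * sin(ang),
    y = cy + radii[1] * cos(theta) * sin(ang) + radii[2] * sin(theta) * cos(ang)
  )
  structure(
    list(
      points = pts,
      centroid = dplyr::bind_cols(tibble(x = cx, y = cy), centre),
      ellipse = ellipse,
      ellipse_axes = tibble(semi_major = radii[1], semi_minor = radii[2],
                            angle_deg = (ang * 180 / pi) %% 180)
    ),
    class = "double_angle_data"
  )
}

#' Double-angle plot of astigmatism vectors
#'
#' Standard double-angle scatter: one point per eye, the centroid, and the
#' 95% covariance ellipse, with polar grid circles for reference.
#'
#' @inheritParams double_angle_plot_data
#' @param ring_step Radius step of the background grid circles, in dioptres.
#' @return A ggplot object.
#' @export
plot_double_angle <- function(data, magnitude = magnitude, axis = axis,
                              conf = 0.95, ring_step = 1) {
  dd <- double_angle_plot_data(data, {{ magnitude }}, {{ axis }}, conf = conf)
  autoplot(dd, ring_step = ring_step)
}

#' @rdname plot_double_angle
#' @param object A `double_angle_data` object.
#' @param ... Unused.
#' @method autoplot double_angle_data
#' @export
autoplot.double_angle_data <- function(object, ring_step = 1, ...) {
  r_max <- max(sqrt(object$points$x^2 + object$points$y^2),
               sqrt(object$ellipse$x^2 + object$ellipse$y^2), ring_step)
  rings <- tidyr::expand_grid(
    r = seq(ring_step, ceiling(r_max / ring_step) * ring_step, by = ring_step),
    theta = seq(0, 2 * pi, length.out = 181)
  ) |>
    dplyr::mutate(x = .data$r * cos(.data$theta),
                  y = .data$r * sin(.data$theta))
  ggplot2::ggplot() +
    ggplot2::geom_path(
      data = rings,
      ggplot2::aes(.data$x, .data$y, group = .data$r),
      colour = "grey80", linewidth = 0.3
    ) +
    ggplot2::geom_path(data = object$ellipse,
                       ggplot2::aes(.data$x, .data$y),
                       colour = "steelblue") +
    ggplot2::geom_point(data = object$points,
                        ggplot2::aes(.data$x, .data$y),
                        alpha = 0.7) +
    ggplot2::geom_point(data = object$centroid,
                        ggplot2::aes(.data$x, .data$y),
                        colour = "red", shape = 18, size = 3) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "cylinder (D), double-angle x",
                  y = "cylinder (D), double-angle y") +
    ggplot2::theme_minimal()
}
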