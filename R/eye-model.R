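#' Residual refraction of a pseudophakic eye by matrix vergence propagation
#'
#' Computes the sphero-cylindrical refraction that corrects a pseudophakic
#' eye, given the corneal power matrix, the implanted IOL (sphere, labelled
#' toricity at the IOL plane, implant axis) and the measured geometry. The
#' cornea is modelled as a thin astigmatic element at the anterior corneal
#' plane; the effective lens position (ELP) is the distance from that plane
#' to the IOL's principal plane.
#'
#' The chain runs backwards from the retina:
#' \enumerate{
#'   \item image vergence behind the IOL,
#'     \eqn{V_{img} = n_{vit} / (AL - ELP) \cdot I};
#'   \item vergence incident on the IOL, \eqn{V = V_{img} - F_{iol}};
#'   \item back-propagation across the ELP gap in aqueous
#'     (see [propagate_vergence()]);
#'   \item residual refraction at the corneal plane,
#'     \eqn{R = V_{cornea} - F_{cornea}};
#'   \item optional vertex change to the spectacle plane.
#' }
#' When the corneal and IOL principal axes coincide the matrix computation
#' reduces exactly to two independent scalar vergence chains, one per
#' meridian.
#'
#' @param cornea Corneal power matrix (tibble `f11`,`f12`,`f22` or 2x2
#'   matrix), on the index basis the model treats as physical (1.332 here).
#' @param iol_sphere IOL labelled sphere power at the IOL plane (D): the
#'   power along the implant axis meridian.
#' @param iol_cylinder IOL labelled toricity (D, >= 0), acting 90 degrees
#'   from the implant axis.
#' @param iol_axis Implant axis in degrees (clinically aligned with the
#'   corneal steep meridian).
#' @param axial_length,elp Axial length and effective lens position in
#'   metres, `0 < elp < axial_length`.
#' @param n_aqueous,n_vitreous Refractive indices of the ocular media
#'   (default 1.336).
#' @param plane Reporting plane, `"corneal"` (default) or `"spectacle"`.
#' @param vertex_distance Corneal-to-spectacle vertex distance in metres
#'   (default 0.012), used only for `plane = "spectacle"`.
#'
#' @return Tibble with columns `sphere`, `cylinder` (negative convention),
#'   `axis`.
#' @examples
#' cornea <- sphero_to_matrix(43)
#' residual_refraction(cornea, 21, 0, 0, 0.0235, 0.005)   # about -0.02 D
#' @export
residual_refraction <- function(cornea, iol_sphere, iol_cylinder = 0,
                                iol_axis = 0, axial_length, elp,
                                n_aqueous = 1.336, n_vitreous = 1.336,
                                plane = c("corneal", "spectacle"),
                                vertex_distance = 0.012) {
  plane <- match.arg(plane)
  cornea <- as_dpower(cornea)
  check_eye_geometry(axial_length, elp)
  check_finite(iol_sphere = iol_sphere, iol_cylinder = iol_cylinder,
               iol_axis = iol_axis)
  v_img <- n_vitreous / (axial_length - elp)
  f_iol <- sphero_to_matrix(iol_sphere, iol_cylinder, iol_axis)
  v_pre <- fast_df(f11 = v_img - f_iol$f11, f12 = -f_iol$f12,
                   f22 = v_img - f_iol$f22)
  v_cornea <- propagate_vergence(v_pre, elp, n_aqueous, "backward")
  r <- fast_df(f11 = v_cornea$f11 - cornea$f11,
               f12 = v_cornea$f12 - cornea$f12,
               f22 = v_cornea$f22 - cornea$f22)
  sc <- matrix_to_sphero(r, "negative")
  if (plane == "spectacle") {
    sc <- change_vertex(sc$sphere, sc$cylinder, sc$axis, -vertex_distance)
  }
  sc
}

#' Recommended toric IOL axis by exhaustive sweep
#'
#' Sweeps the implant axis over `[0, 180)` at `sweep_step` granularity and
#' returns the axis minimising the residual cylinder magnitude of
#' [residual_refraction()]. Ties (within 1e-9 D) break towards the smaller
#' axis, so an isotropic cornea returns 0.
#'
#' @inheritParams residual_refraction
#' @param sweep_step Sweep granularity in degrees (default 0.1).
#' @return One-row tibble: `axis` (recommended implant axis),
#'   `residual_sphere`, `residual_cylinder`, `residual_axis` (the residual
#'   refraction at that axis, corneal plane, negative cylinder).
#' @examples
#' cornea <- keratometry_to_matrix(42, 44, 90)
#' iol <- calculate_iol(cornea, 0.0235, 0.005)
#' recommended_axis(cornea, iol$sphere, iol$cylinder, 0.0235, 0.005)
#' @export
recommended_axis <- function(cornea, iol_sphere, iol_cylinder, axial_length,
                             elp, sweep_step = 0.1, n_aqueous = 1.336,
                             n_vitreous = 1.336) {
  if (length(iol_cylinder) != 1 || iol_cylinder <= 0) {
    abort("`recommended_axis()` needs a toric IOL (`iol_cylinder` > 0).")
  }
  cornea <- as_dpower(cornea)
  if (nrow(cornea) != 1) abort("`cornea` must be a single power matrix row.")
  check_eye_geometry(axial_length, elp)
  axes <- seq(0, 180 - sweep_step / 2, by = sweep_step)
  # lean vectorised sweep of the residual-cylinder magnitude (same chain as
  # residual_refraction, without the tibble plumbing)
  a <- axes * pi / 180
  f11 <- iol_sphere + iol_cylinder * sin(a)^2
  f12 <- -iol_cylinder * sin(a) * cos(a)
  f22 <- iol_sphere + iol_cylinder * cos(a)^2
  v_img <- n_vitreous / (axial_length - elp)
  p11 <- v_img - f11
  p12 <- -f12
  p22 <- v_img - f22
  k <- -elp / n_aqueous
  det <- (1 - k * p11) * (1 - k * p22) - (k * p12)^2
  r11 <- (p11 * (1 - k * p22) + k * p12^2) / det - cornea$f11
  r12 <- p12 / det - cornea$f12
  r22 <- (p22 * (1 - k * p11) + k * p12^2) / det - cornea$f22
  cyl_mag <- sqrt((r11 - r22)^2 + 4 * r12^2)
  best <- which(cyl_mag <= min(cyl_mag) + 1e-9)[1]
  res <- residual_refraction(cornea, iol_sphere, iol_cylinder, axes[best],
                             axial_length, elp, n_aqueous, n_vitreous)
  tibble(
    axis = axes[best],
    residual_sphere = res$sphere,
    residual_cylinder = res$cylinder,
    residual_axis = res$axis
  )
}

#' Vergence-based toric IOL power calculation
#'
#' Solves, per principal meridian, for the thin-lens IOL power that leaves
#' the requested target refraction: the target (moved to the corneal plane
#' if given at the spectacle plane) is added to the corneal power matrix,
#' propagated forward across the ELP gap, and subtracted from the required
#' image vergence,
#' \deqn{F_{iol} = V_{img} I - \mathrm{fwd}(T + F_{cornea},\ ELP).}
#' This is a generic paraxial calculator behind a pluggable interface;
#' proprietary formula internals (e.g. ELP prediction) are out of scope and
#' the ELP is supplied by the caller. Without step rounding the returned IOL
#' reproduces the target through [residual_refraction()] to numerical
#' precision.
#'
#' @inheritParams residual_refraction
#' @param target_sphere,target_cylinder,target_axis Target refraction
#'   (default plano).
#' @param target_plane Plane the target refraction is expressed on.
#' @param power_step Optional commercial power step in dioptres (e.g. 0.5)
#'   applied to sphere and cylinder; 0 (default) disables rounding.
#' @return One-row tibble: `sphere`, `cylinder` (>= 0), `axis` (implant
#'   axis, degrees).
#' @examples
#' calculate_iol(sphero_to_matrix(43), 0.0235, 0.005)   # about 20.97 D
#' @export
calculate_iol <- function(cornea, axial_length, elp, target_sphere = 0,
                          target_cylinder = 0, target_axis = 0,
                          target_plane = c("corneal", "spectacle"),
                          vertex_distance = 0.012, n_aqueous = 1.336,
                          n_vitreous = 1.336, power_step = 0) {
  target_plane <- match.arg(target_plane)
  cornea <- as_dpower(cornea)
  check_eye_geometry(axial_length, elp)
  if (target_plane == "spectacle") {
    t_c <- change_vertex(target_sphere, target_cylinder, target_axis,
                         vertex_distance)
    target_sphere <- t_c$sphere
    target_cylinder <- t_c$cylinder
    target_axis <- t_c$axis
  }
  v0 <- add_power(sphero_to_matrix(target_sphere, target_cylinder, target_axis),
                  cornea)
  v1 <- propagate_vergence(v0, elp, n_aqueous, "forward")
  v_img <- n_vitreous / (axial_length - elp)
  f_iol <- fast_df(f11 = v_img - v1$f11, f12 = -v1$f12, f22 = v_img - v1$f22)
  iol <- matrix_to_sphero(f_iol, "positive")
  if (power_step > 0) {
    iol$sphere <- round(iol$sphere / power_step) * power_step
    iol$cylinder <- round(iol$cylinder / power_step) * power_step
  }
  names(iol) <- c("sphere", "cylinder", "axis")
  iol
}

#' Prediction error of the spherical equivalent
#'
#' `PE = SE(calculated postoperative refraction) - predicted SE`, the
#' standard accuracy measure for IOL power calculation. Both quantities must
#' be expressed on the same reference plane.
#'
#' @param predicted_se Preoperatively predicted residual spherical
#'   equivalent (D).
#' @param sphere,cylinder Calculated postoperative refraction.
#' @return Numeric vector of prediction errors (D).
#' @examples
#' prediction_error(-0.25, 0, 0)   # +0.25 D
#' @export
prediction_error <- function(predicted_se, sphere, cylinder = 0) {
  spherical_equivalent(sphere, cylinder) - predicted_se
}

## ---- internal -------------------------------------------------------------

check_eye_geometry <- function(axial_length, elp) {
  check_finite(axial_length = axial_length, elp = elp)
  if (any(elp <= 0) || any(elp >= axial_length)) {
    abort("Need 0 < elp < axial_length (both in metres).")
  }
  if (any(axial_length < 0.018) || any(axial_length > 0.040)) {
    warn("Axial length outside the plausible 18-40 mm range; check units (metres).")
  }
  invisible(TRUE)
}
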