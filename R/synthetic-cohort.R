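#' Configuration of a synthetic toric-IOL cohort
#'
#' Defines the statistical structure of a simulated cohort of eyes
#' undergoing toric IOL implantation: true corneal optics, three device
#' readings (standard K and TK on the 1.332 keratometric basis, TCRP printed
#' on 1.3375), IOL selection, surgery with an assumed corneal SIA vector and
#' axis misalignment, and postoperative measurement. Defaults mirror the
#' clinical conditions the pipeline is meant to emulate: corneal astigmatism
#' of at least 1.00 D, a WTR-dominant axis mix (17:5:1 WTR:ATR:oblique),
#' K-vs-TK astigmatism differences of 0.04 +/- 0.17 D in magnitude and 1.6
#' degrees mean absolute axis difference, TCRP-vs-TK differences of -0.25 +/-
#' 0.47 D and 5.5 degrees, an assumed SIA of 0.37 D @ 2 and a mean absolute
#' IOL misalignment of 2.52 degrees.
#'
#' Absolute angular deviations (device axis differences, misalignment) are
#' modelled as signed zero-mean normals whose scale is set from the target
#' mean absolute deviation `m` via the half-normal relation
#' `sigma = m * sqrt(pi / 2)`.
#'
#' @param n_eyes Number of eyes (>= 1).
#' @param seed Integer seed; `generate_cohort()` seeds the RNG with it.
#' @param axis_class_probs Named numeric vector of WTR/ATR/oblique
#'   proportions (normalised internally).
#' @param cyl_mean,cyl_sd,cyl_floor Preoperative TCRP-measured corneal
#'   cylinder: parent normal mean/SD (D) and the inclusion floor enforced by
#'   resampling.
#' @param corneal_power_mean,corneal_power_sd Mean corneal power (D, on the
#'   1.332 total-power basis).
#' @param axial_length_mean,axial_length_sd Axial length (mm).
#' @param elp_mean,elp_sd True effective lens position (mm).
#' @param k_diff_mag_mean,k_diff_mag_sd K-minus-TK astigmatism magnitude
#'   difference (D).
#' @param k_diff_axis_mean Mean absolute K-vs-TK axis difference (degrees).
#' @param k_diff_se_sd SD of the K-vs-TK mean-power difference (D).
#' @param tcrp_diff_mag_mean,tcrp_diff_mag_sd,tcrp_diff_axis_mean,tcrp_diff_se_sd
#'   Same difference model for TCRP minus TK (on the common 1.332 basis).
#' @param tk_se_sd,tk_astig_sd TK measurement noise: SD of the mean-power
#'   error (D) and of each double-angle astigmatism component (D), relative
#'   to the true cornea.
#' @param sia_magnitude,sia_axis Assumed surgically induced astigmatism
#'   vector (D, degrees).
#' @param sia_component_sd Per-eye SD of each double-angle SIA component
#'   around the assumed vector (D).
#' @param misalignment_mean Mean absolute IOL axis misalignment (degrees).
#' @param elp_prediction_sd Preoperative ELP prediction error SD (mm).
#' @param elp_measure_sd Postoperative ELP measurement noise SD (mm).
#' @param postop_k_se_sd,postop_k_astig_sd Postoperative keratometry noise
#'   (mean power D; double-angle components D).
#' @param target_sphere,target_cylinder,target_axis Target refraction.
#' @param plane Reporting plane for predicted and achieved refraction.
#' @param vertex_distance Vertex distance (m) for spectacle-plane reporting.
#' @param n_aqueous,n_vitreous Ocular media indices.
#' @param iol_power_step Commercial IOL power step (D); 0 disables rounding.
#' @param sweep_step Axis sweep granularity (degrees) for the recommended
#'   axis.
#' @param index_k,index_tk,index_tcrp Keratometric index bases of the three
#'   sources.
#' @param max_batches Resampling batches before the inclusion floor is
#'   declared unsatisfiable.
#' @return A list of class `cohort_config`.
#' @seealso [generate_cohort()], [run_cohort_study()], [zero_noise_config()]
#' @export
cohort_config <- function(n_eyes = 23,
                          seed = 1L,
                          axis_class_probs = c(WTR = 17, ATR = 5, oblique = 1) / 23,
                          cyl_mean = 1.85, cyl_sd = 1.15, cyl_floor = 1.00,
                          corneal_power_mean = 43.3, corneal_power_sd = 1.3,
                          axial_length_mean = 23.8, axial_length_sd = 1.1,
                          elp_mean = 4.9, elp_sd = 0.4,
                          k_diff_mag_mean = 0.04, k_diff_mag_sd = 0.17,
                          k_diff_axis_mean = 1.6, k_diff_se_sd = 0.10,
                          tcrp_diff_mag_mean = -0.25, tcrp_diff_mag_sd = 0.47,
                          tcrp_diff_axis_mean = 5.5, tcrp_diff_se_sd = 0.15,
                          tk_se_sd = 0.05, tk_astig_sd = 0.05,
                          sia_magnitude = 0.37, sia_axis = 2,
                          sia_component_sd = 0.15,
                          misalignment_mean = 2.52,
                          elp_prediction_sd = 0.25, elp_measure_sd = 0.05,
                          postop_k_se_sd = 0.10, postop_k_astig_sd = 0.10,
                          target_sphere = 0, target_cylinder = 0,
                          target_axis = 0,
                          plane = c("corneal", "spectacle"),
                          vertex_distance = 0.012,
                          n_aqueous = 1.336, n_vitreous = 1.336,
                          iol_power_step = 0.5,
                          sweep_step = 0.1,
                          index_k = 1.332, index_tk = 1.332,
                          index_tcrp = 1.3375,
                          max_batches = 100) {
  plane <- match.arg(plane)
  if (n_eyes < 1) abort("`n_eyes` must be at least 1.")
  if (length(axis_class_probs) != 3 ||
      !setequal(names(axis_class_probs), c("WTR", "ATR", "oblique")) ||
      any(axis_class_probs < 0) || sum(axis_class_probs) <= 0) {
    abort("`axis_class_probs` must be non-negative proportions named WTR, ATR, oblique.")
  }
  axis_class_probs <- axis_class_probs / sum(axis_class_probs)
  sds <- c(cyl_sd = cyl_sd, corneal_power_sd = corneal_power_sd,
           axial_length_sd = axial_length_sd, elp_sd = elp_sd,
           k_diff_mag_sd = k_diff_mag_sd, k_diff_se_sd = k_diff_se_sd,
           tcrp_diff_mag_sd = tcrp_diff_mag_sd, tcrp_diff_se_sd = tcrp_diff_se_sd,
           tk_se_sd = tk_se_sd, tk_astig_sd = tk_astig_sd,
           sia_component_sd = sia_component_sd,
           elp_prediction_sd = elp_prediction_sd, elp_measure_sd = elp_measure_sd,
           postop_k_se_sd = postop_k_se_sd, postop_k_astig_sd = postop_k_astig_sd)
  if (any(sds < 0)) {
    abort(sprintf("`%s` must be non-negative.", names(sds)[which(sds < 0)[1]]))
  }
  if (cyl_floor < 0) abort("`cyl_floor` must be non-negative.")
  if (k_diff_axis_mean < 0 || tcrp_diff_axis_mean < 0 || misalignment_mean < 0) {
    abort("Mean absolute angular deviations must be non-negative.")
  }
  cfg <- as.list(environment())
  structure(cfg, class = "cohort_config")
}

#' @rdname cohort_config
#' @param ... Overrides passed on to [cohort_config()].
#' @details `zero_noise_config()` returns a configuration with every noise
#'   SD, every inter-device difference and the misalignment set to zero and
#'   IOL power rounding disabled, while keeping the assumed SIA vector. Under
#'   it the pipeline is deterministic per eye and every prediction error is
#'   zero to numerical precision -- the strongest end-to-end self-consistency
#'   check of the model chain.
#' @export
zero_noise_config <- function(n_eyes = 23, seed = 1L, ...) {
  cohort_config(
    n_eyes = n_eyes, seed = seed,
    k_diff_mag_mean = 0, k_diff_mag_sd = 0, k_diff_axis_mean = 0,
    k_diff_se_sd = 0,
    tcrp_diff_mag_mean = 0, tcrp_diff_mag_sd = 0, tcrp_diff_axis_mean = 0,
    tcrp_diff_se_sd = 0,
    tk_se_sd = 0, tk_astig_sd = 0,
    sia_component_sd = 0, misalignment_mean = 0,
    elp_prediction_sd = 0, elp_measure_sd = 0,
    postop_k_se_sd = 0, postop_k_astig_sd = 0,
    iol_power_step = 0,
    ...
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  eyes: %d (seed %s)\n", x$n_eyes, format(x$seed)))
  cat(sprintf("  preop cylinder: N(%.2f, %.2f) D, floor %.2f D\n",
              x$cyl_mean, x$cyl_sd, x$cyl_floor))
  cat(sprintf("  axis mix WTR/ATR/oblique: %.2f/%.2f/%.2f\n",
              x$axis_class_probs[["WTR"]], x$axis_class_probs[["ATR"]],
              x$axis_class_probs[["oblique"]]))
  cat(sprintf("  assumed SIA: %.2f D @ %g; misalignment mean %.2f deg\n",
              x$sia_magnitude, x$sia_axis, x$misalignment_mean))
  cat(sprintf("  reporting plane: %s\n", x$plane))
  invisible(x)
}

#' Generate a synthetic cohort of eyes with three keratometry readings
#'
#' Draws `n_eyes` eyes satisfying the inclusion criterion (TCRP-measured
#' corneal cylinder at or above `cyl_floor`, enforced by resampling) and
#' returns one row per eye: true corneal optics (on the 1.332 basis), axial
#' length, true ELP, and the K, TK and TCRP readings with the configured
#' inter-device difference structure. The TCRP reading is printed on its
#' native 1.3375 basis.
#'
#' The generator factorises around the inclusion-defining measurement: the
#' TCRP cylinder is drawn first (and floored), then TK is derived by
#' subtracting a TCRP-minus-TK difference draw, K by adding a K-minus-TK
#' draw, and the true cornea by removing the TK measurement noise. The
#' difference draws are therefore never conditioned on inclusion and their
#' configured moments are recovered at large n. Readings whose derived
#' cylinder would be negative are repaired by reflecting the magnitude and
#' rotating the axis 90 degrees.
#'
#' Deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return Tibble with one row per eye: `eye_id`, `axis_class`, `true_flat`,
#'   `true_steep`, `true_axis`, `al_mm`, `elp_mm`, and
#'   `{k,tk,tcrp}_{flat,steep,axis}`.
#' @examples
#' generate_cohort(cohort_config(n_eyes = 5, seed = 7))
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_eyes
  accepted <- 0L
  rows <- list()
  batches <- 0L
  while (accepted < n) {
    batches <- batches + 1L
    if (batches > config$max_batches) {
      abort(sprintf(
        "Could not draw %d eyes with cylinder >= %.2f D in %d batches; the floor appears unsatisfiable for N(%.2f, %.2f).",
        n, config$cyl_floor, config$max_batches, config$cyl_mean, config$cyl_sd
      ))
    }
    m <- max(2L * (n - accepted), 20L)
    cyl <- rnorm(m, config$cyl_mean, config$cyl_sd)
    keep <- which(cyl >= config$cyl_floor)
    if (!length(keep)) next
    keep <- keep[seq_len(min(length(keep), n - accepted))]
    rows[[batches]] <- cyl[keep]
    accepted <- accepted + length(keep)
  }
  tcrp_cyl <- unlist(rows)

  cls <- sample(c("WTR", "ATR", "oblique"), n, replace = TRUE,
                prob = config$axis_class_probs[c("WTR", "ATR", "oblique")])
  tcrp_axis <- draw_axis_by_class(cls)

  m_tk <- rnorm(n, config$corneal_power_mean, config$corneal_power_sd)
  al <- pmin(pmax(rnorm(n, config$axial_length_mean, config$axial_length_sd),
                  20), 30)
  elp <- pmin(pmax(rnorm(n, config$elp_mean, config$elp_sd), 3), 7)

  # device differences on the common 1.332 basis, never conditioned on inclusion
  d_mag_t <- rnorm(n, config$tcrp_diff_mag_mean, config$tcrp_diff_mag_sd)
  d_ax_t <- rnorm(n, 0, config$tcrp_diff_axis_mean * sqrt(pi / 2))
  d_se_t <- rnorm(n, 0, config$tcrp_diff_se_sd)
  d_mag_k <- rnorm(n, config$k_diff_mag_mean, config$k_diff_mag_sd)
  d_ax_k <- rnorm(n, 0, config$k_diff_axis_mean * sqrt(pi / 2))
  d_se_k <- rnorm(n, 0, config$k_diff_se_sd)

  tk <- repair_reading(tcrp_cyl - d_mag_t, (tcrp_axis - d_ax_t) %% 180)
  k <- repair_reading(tk$cyl + d_mag_k, (tk$axis + d_ax_k) %% 180)
  m_tcrp <- m_tk + d_se_t
  m_k <- m_tk + d_se_k

  # true cornea = TK reading minus its measurement noise
  noise_se <- rnorm(n, 0, config$tk_se_sd)
  noise_x <- rnorm(n, 0, config$tk_astig_sd)
  noise_y <- rnorm(n, 0, config$tk_astig_sd)
  tk_vec <- to_double_angle(tk$cyl, tk$axis)
  truth <- from_double_angle(tk_vec$x - noise_x, tk_vec$y - noise_y)
  m_true <- m_tk - noise_se

  ratio <- (config$index_tcrp - 1) / (config$index_tk - 1)
  tibble(
    eye_id = sprintf("eye_%04d", seq_len(n)),
    axis_class = classify_astigmatism(tcrp_axis),
    true_flat = m_true - truth$magnitude / 2,
    true_steep = m_true + truth$magnitude / 2,
    true_axis = truth$axis,
    al_mm = al,
    elp_mm = elp,
    k_flat = m_k - k$cyl / 2,
    k_steep = m_k + k$cyl / 2,
    k_axis = k$axis,
    tk_flat = m_tk - tk$cyl / 2,
    tk_steep = m_tk + tk$cyl / 2,
    tk_axis = tk$axis,
    tcrp_flat = (m_tcrp - tcrp_cyl / 2) * ratio,
    tcrp_steep = (m_tcrp + tcrp_cyl / 2) * ratio,
    tcrp_axis = tcrp_axis
  )
}

#' Simulate the three device readings for known true corneas
#'
#' Forward measurement model, one row per eye: TK is the true total corneal
#' power plus measurement noise (1.332 basis); K adds a K-minus-TK
#' difference draw; TCRP adds a TCRP-minus-TK difference draw and is printed
#' on the 1.3375 basis. With every noise SD and difference mean at zero the
#' three readings agree exactly after reindexing. Draws come from the
#' current RNG stream.
#'
#' @param true_eyes Tibble with columns `true_flat`, `true_steep`,
#'   `true_axis` (1.332 basis).
#' @inheritParams generate_cohort
#' @return Tibble of `{k,tk,tcrp}_{flat,steep,axis}` columns, with any
#'   other columns of `true_eyes` carried through.
#' @export
simulate_device_readings <- function(true_eyes, config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  need <- c("true_flat", "true_steep", "true_axis")
  if (!all(need %in% names(true_eyes))) {
    abort("`true_eyes` must have columns true_flat, true_steep, true_axis.")
  }
  n <- nrow(true_eyes)
  m_true <- (true_eyes$true_flat + true_eyes$true_steep) / 2
  true_cyl <- true_eyes$true_steep - true_eyes$true_flat
  true_vec <- to_double_angle(true_cyl, true_eyes$true_axis)

  tk_vec <- from_double_angle(true_vec$x + rnorm(n, 0, config$tk_astig_sd),
                              true_vec$y + rnorm(n, 0, config$tk_astig_sd))
  m_tk <- m_true + rnorm(n, 0, config$tk_se_sd)

  d_mag_k <- rnorm(n, config$k_diff_mag_mean, config$k_diff_mag_sd)
  d_ax_k <- rnorm(n, 0, config$k_diff_axis_mean * sqrt(pi / 2))
  k <- repair_reading(tk_vec$magnitude + d_mag_k, (tk_vec$axis + d_ax_k) %% 180)
  m_k <- m_tk + rnorm(n, 0, config$k_diff_se_sd)

  d_mag_t <- rnorm(n, config$tcrp_diff_mag_mean, config$tcrp_diff_mag_sd)
  d_ax_t <- rnorm(n, 0, config$tcrp_diff_axis_mean * sqrt(pi / 2))
  tcrp <- repair_reading(tk_vec$magnitude + d_mag_t,
                         (tk_vec$axis + d_ax_t) %% 180)
  m_tcrp <- m_tk + rnorm(n, 0, config$tcrp_diff_se_sd)

  ratio <- (config$index_tcrp - 1) / (config$index_tk - 1)
  dplyr::bind_cols(
    true_eyes,
    tibble(
      k_flat = m_k - k$cyl / 2, k_steep = m_k + k$cyl / 2, k_axis = k$axis,
      tk_flat = m_tk - tk_vec$magnitude / 2,
      tk_steep = m_tk + tk_vec$magnitude / 2,
      tk_axis = tk_vec$axis,
      tcrp_flat = (m_tcrp - tcrp$cyl / 2) * ratio,
      tcrp_steep = (m_tcrp + tcrp$cyl / 2) * ratio,
      tcrp_axis = tcrp$axis
    )
  )
}

#' Simulate IOL selection, surgery and postoperative measurement
#'
#' Completes a generated cohort through the operative part of the study
#' design, eye by eye:
#' \enumerate{
#'   \item predicted postoperative cornea per source = the reading's
#'     astigmatism (rebased to 1.332) plus the assumed SIA vector;
#'   \item the implanted toric IOL is calculated from the standard-K
#'     prediction (vergence solve, optional commercial power rounding) with
#'     a preoperatively *predicted* ELP (true ELP plus prediction noise);
#'   \item each source recommends an implant axis (residual-cylinder sweep)
#'     and a predicted residual refraction, whose spherical equivalent is
#'     that source's predicted SE;
#'   \item surgery applies a per-eye SIA draw (centred on the assumed
#'     vector) to the true cornea and rotates the IOL off the intended axis
#'     by a signed misalignment draw;
#'   \item postoperative keratometry and ELP are measured with noise and the
#'     achieved refraction is recomputed through the power-matrix chain, at
#'     each source's recommended axis (that source's achieved SE) and at the
#'     achieved axis (the reported postoperative refractive cylinder).
#' }
#' The per-source prediction error is `achieved SE - predicted SE`, on the
#' configured reporting plane.
#'
#' Draws come from the current RNG stream; [run_cohort_study()] seeds once
#' via [generate_cohort()] so the whole pipeline is reproducible.
#'
#' @param eyes Cohort tibble from [generate_cohort()].
#' @inheritParams generate_cohort
#' @return `eyes` with planning, surgery and outcome columns appended
#'   (implant power, per-source recommended axes, predicted and achieved SE
#'   and PE, achieved axis, misalignment, measured postoperative cornea and
#'   ELP, achieved SIA vector, postoperative refractive cylinder).
#' @export
simulate_surgery <- function(eyes, config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- nrow(eyes)
  assumed <- to_double_angle(config$sia_magnitude, config$sia_axis)

  # pre-draw all randomness, vectorised
  elp_est <- pmin(pmax(eyes$elp_mm + rnorm(n, 0, config$elp_prediction_sd),
                       2.5), 7.5)
  sia_x <- assumed$x + rnorm(n, 0, config$sia_component_sd)
  sia_y <- assumed$y + rnorm(n, 0, config$sia_component_sd)
  mis_draw <- rnorm(n, 0, config$misalignment_mean * sqrt(pi / 2))
  post_noise_se <- rnorm(n, 0, config$postop_k_se_sd)
  post_noise_x <- rnorm(n, 0, config$postop_k_astig_sd)
  post_noise_y <- rnorm(n, 0, config$postop_k_astig_sd)
  elp_meas <- pmin(pmax(eyes$elp_mm + rnorm(n, 0, config$elp_measure_sd),
                        2.5), 7.5)

  # postoperative true and measured corneas (1.332 basis)
  m_true <- (eyes$true_flat + eyes$true_steep) / 2
  true_vec <- to_double_angle(eyes$true_steep - eyes$true_flat, eyes$true_axis)
  post_vec <- from_double_angle(true_vec$x + sia_x + post_noise_x,
                                true_vec$y + sia_y + post_noise_y)
  post_mean <- m_true + post_noise_se
  post_flat <- post_mean - post_vec$magnitude / 2
  post_steep <- post_mean + post_vec$magnitude / 2

  # per-source preoperative astigmatism on the common basis
  rebase <- (config$index_tk - 1) / (config$index_tcrp - 1)
  src <- list(
    K = list(flat = eyes$k_flat, steep = eyes$k_steep, axis = eyes$k_axis),
    TK = list(flat = eyes$tk_flat, steep = eyes$tk_steep, axis = eyes$tk_axis),
    TCRP = list(flat = eyes$tcrp_flat * rebase,
                steep = eyes$tcrp_steep * rebase, axis = eyes$tcrp_axis)
  )
  # predicted postoperative cornea per source: reading astigmatism + assumed SIA
  pred <- purrr::map(src, function(s) {
    v <- to_double_angle(s$steep - s$flat, s$axis)
    pv <- from_double_angle(v$x + assumed$x, v$y + assumed$y)
    m <- (s$flat + s$steep) / 2
    list(flat = m - pv$magnitude / 2, steep = m + pv$magnitude / 2,
         axis = pv$axis)
  })

  out <- vector("list", n)
  for (i in seq_len(n)) {
    al_m <- eyes$al_mm[i] / 1000
    elp_est_m <- elp_est[i] / 1000
    pred_mats <- purrr::map(pred, function(p) {
      keratometry_to_matrix(p$flat[i], p$steep[i], p$axis[i], config$index_tk)
    })
    iol <- calculate_iol(
      pred_mats$K, al_m, elp_est_m,
      config$target_sphere, config$target_cylinder, config$target_axis,
      target_plane = config$plane, vertex_distance = config$vertex_distance,
      n_aqueous = config$n_aqueous, n_vitreous = config$n_vitreous,
      power_step = config$iol_power_step
    )
    plan <- purrr::map(pred_mats, function(m) {
      if (iol$cylinder > 0) {
        rec <- recommended_axis(m, iol$sphere, iol$cylinder, al_m, elp_est_m,
                                sweep_step = config$sweep_step,
                                n_aqueous = config$n_aqueous,
                                n_vitreous = config$n_vitreous)
        ax <- rec$axis
      } else {
        ax <- 0
      }
      res <- residual_refraction(m, iol$sphere, iol$cylinder, ax, al_m,
                                 elp_est_m, config$n_aqueous,
                                 config$n_vitreous, plane = config$plane,
                                 vertex_distance = config$vertex_distance)
      list(axis = ax, se = spherical_equivalent(res$sphere, res$cylinder))
    })
    achieved_axis <- (plan$K$axis + mis_draw[i]) %% 180
    post_mat <- keratometry_to_matrix(post_flat[i], post_steep[i],
                                      post_vec$axis[i], config$index_tk)
    achieved <- purrr::map(plan, function(p) {
      res <- residual_refraction(post_mat, iol$sphere, iol$cylinder, p$axis,
                                 al_m, elp_meas[i] / 1000, config$n_aqueous,
                                 config$n_vitreous, plane = config$plane,
                                 vertex_distance = config$vertex_distance)
      spherical_equivalent(res$sphere, res$cylinder)
    })
    post_ref <- residual_refraction(post_mat, iol$sphere, iol$cylinder,
                                    achieved_axis, al_m, elp_meas[i] / 1000,
                                    config$n_aqueous, config$n_vitreous,
                                    plane = "corneal")
    out[[i]] <- tibble(
      iol_sphere = iol$sphere, iol_cylinder = iol$cylinder,
      rec_axis_k = plan$K$axis, rec_axis_tk = plan$TK$axis,
      rec_axis_tcrp = plan$TCRP$axis,
      predicted_se_k = plan$K$se, predicted_se_tk = plan$TK$se,
      predicted_se_tcrp = plan$TCRP$se,
      achieved_axis = achieved_axis,
      postop_se_k = achieved$K, postop_se_tk = achieved$TK,
      postop_se_tcrp = achieved$TCRP,
      postop_ref_sphere = post_ref$sphere,
      postop_ref_cylinder = post_ref$cylinder,
      postop_ref_axis = post_ref$axis
    )
  }
  planned <- dplyr::bind_rows(out)

  # achieved SIA as measured: postoperative minus preoperative TK keratometry
  sia_meas <- surgically_induced_astigmatism(
    eyes$tk_steep - eyes$tk_flat, eyes$tk_axis,
    post_steep - post_flat, post_vec$axis
  )

  dplyr::bind_cols(
    eyes, planned,
    tibble(
      elp_est_mm = elp_est, elp_meas_mm = elp_meas,
      post_flat = post_flat, post_steep = post_steep,
      post_axis = post_vec$axis,
      sia_magnitude = sia_meas$magnitude, sia_axis = sia_meas$axis,
      misalignment_deg = axis_misalignment(planned$rec_axis_k,
                                           planned$achieved_axis),
      pe_k = planned$postop_se_k - planned$predicted_se_k,
      pe_tk = planned$postop_se_tk - planned$predicted_se_tk,
      pe_tcrp = planned$postop_se_tcrp - planned$predicted_se_tcrp
    )
  )
}

## ---- internal -------------------------------------------------------------

draw_axis_by_class <- function(cls) {
  n <- length(cls)
  ax <- numeric(n)
  wtr <- cls == "WTR"
  atr <- cls == "ATR"
  obl <- cls == "oblique"
  ax[wtr] <- runif(sum(wtr), 60, 120)
  ax[atr] <- runif(sum(atr), -30, 30) %% 180
  side <- runif(sum(obl)) < 0.5
  ax[obl] <- runif(sum(obl), 30, 60) + 90 * side
  ax
}

# Enforce cylinder >= 0 on a derived reading: reflect and rotate 90 degrees.
repair_reading <- function(cyl, axis) {
  neg <- cyl < 0
  list(cyl = ifelse(neg, -cyl, cyl),
       axis = ifelse(neg, (axis + 90) %% 180, axis %% 180))
}
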