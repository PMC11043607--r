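#' Analyse a completed toric-IOL cohort
#'
#' Runs the full outcomes analysis on a per-eye table that has been through
#' planning, surgery and postoperative measurement (the output of
#' [simulate_surgery()], or equivalently structured clinical data):
#' per-source prediction errors with group summaries, one-way ANOVA with
#' Tukey follow-up, Cochran's Q (overall and pairwise) on the
#' within-threshold indicators, double-angle centroids of pre- and
#' postoperative astigmatism, achieved SIA and its prediction error,
#' cylinder-reduction cumulative tables, and IOL misalignment statistics.
#'
#' @param eyes Per-eye tibble with the columns produced by
#'   [simulate_surgery()] (prediction errors `pe_k`, `pe_tk`, `pe_tcrp`,
#'   keratometry readings, `sia_magnitude`/`sia_axis`,
#'   `postop_ref_cylinder`, `misalignment_deg`, ...). Missing columns abort
#'   with the column named.
#' @param config The [cohort_config()] the cohort was built with (used for
#'   the assumed SIA vector, thresholds and index bases).
#' @param pe_thresholds Absolute-PE thresholds (D) for the summary and
#'   Cochran tables.
#' @param cyl_thresholds Thresholds (D) for the cylinder cumulative tables.
#' @param rotation_thresholds Thresholds (degrees) for the misalignment
#'   cumulative table.
#' @return An object of class `toric_study`; see [tidy.toric_study()],
#'   [glance.toric_study()] and [autoplot.toric_study()].
#' @export
analyze_study <- function(eyes, config = cohort_config(),
                          pe_thresholds = c(0.5, 1),
                          cyl_thresholds = c(0.25, 0.5, 1),
                          rotation_thresholds = c(5, 10)) {
  need <- c("eye_id", "pe_k", "pe_tk", "pe_tcrp",
            "predicted_se_k", "predicted_se_tk", "predicted_se_tcrp",
            "postop_se_k", "postop_se_tk", "postop_se_tcrp",
            "tk_flat", "tk_steep", "tk_axis",
            "tcrp_flat", "tcrp_steep", "tcrp_axis",
            "sia_magnitude", "sia_axis",
            "postop_ref_cylinder", "postop_ref_axis", "misalignment_deg")
  missing_cols <- setdiff(need, names(eyes))
  if (length(missing_cols)) {
    abort(paste0("`eyes` is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }

  pe <- eyes |>
    dplyr::select("eye_id", dplyr::matches("^(pe|predicted_se|postop_se)_")) |>
    tidyr::pivot_longer(-"eye_id",
                        names_to = c(".value", "source"),
                        names_pattern = "(pe|predicted_se|postop_se)_(.+)") |>
    dplyr::mutate(source = toupper(.data$source)) |>
    dplyr::select("eye_id", "source", "predicted_se", "postop_se", "pe")

  summary_tab <- summarize_pe(pe, thresholds = pe_thresholds)
  anova_tab <- one_way_anova(pe, .data$pe, .data$source)
  tukey_tab <- tukey_hsd(pe, .data$pe, .data$source)

  cochran <- purrr::map(pe_thresholds, function(thr) {
    ind <- pe |>
      dplyr::mutate(within = as.integer(abs(.data$pe) <= thr + 1e-9)) |>
      tidyr::pivot_wider(id_cols = "eye_id", names_from = "source",
                         values_from = "within")
    mat <- as.matrix(ind[-1])
    list(threshold = thr, overall = cochran_q(mat),
         pairwise = pairwise_cochran_q(mat))
  })
  names(cochran) <- paste0("within_", format(pe_thresholds), "D")

  # vector analysis: plus-cylinder axis of the postoperative refraction
  post_ref_mag <- abs(eyes$postop_ref_cylinder)
  post_ref_axis <- ifelse(eyes$postop_ref_cylinder < 0,
                          (eyes$postop_ref_axis + 90) %% 180,
                          eyes$postop_ref_axis %% 180)
  centroids <- dplyr::bind_rows(
    dplyr::mutate(astig_centroid(tibble(magnitude = eyes$tk_steep - eyes$tk_flat,
                                        axis = eyes$tk_axis)),
                  what = "preop_TK", .before = 1),
    dplyr::mutate(astig_centroid(tibble(magnitude = eyes$tcrp_steep - eyes$tcrp_flat,
                                        axis = eyes$tcrp_axis)),
                  what = "preop_TCRP", .before = 1),
    dplyr::mutate(astig_centroid(tibble(magnitude = post_ref_mag,
                                        axis = post_ref_axis)),
                  what = "postop_refractive", .before = 1)
  )

  sia_achieved <- astig_centroid(tibble(magnitude = eyes$sia_magnitude,
                                        axis = eyes$sia_axis))
  sia_err_eyes <- sia_prediction_error(config$sia_magnitude, config$sia_axis,
                                       eyes$sia_magnitude, eyes$sia_axis)
  sia <- list(
    assumed = tibble(magnitude = config$sia_magnitude, axis = config$sia_axis),
    achieved = sia_achieved,
    prediction_error = astig_centroid(sia_err_eyes),
    convention = "SIA = postoperative minus preoperative corneal astigmatism (double-angle space)"
  )

  cylinder <- list(
    preop_tcrp = cumulative_within(eyes$tcrp_steep - eyes$tcrp_flat,
                                   cyl_thresholds),
    postop_refractive = cumulative_within(post_ref_mag, cyl_thresholds),
    preop_mean = mean(eyes$tcrp_steep - eyes$tcrp_flat),
    preop_sd = sd(eyes$tcrp_steep - eyes$tcrp_flat),
    postop_mean = mean(post_ref_mag),
    postop_sd = sd(post_ref_mag)
  )

  misalignment <- list(
    mean = mean(eyes$misalignment_deg),
    sd = sd(eyes$misalignment_deg),
    cumulative = cumulative_within(eyes$misalignment_deg, rotation_thresholds)
  )

  structure(
    list(eyes = eyes, pe = pe, summary = summary_tab, anova = anova_tab,
         tukey = tukey_tab, cochran = cochran, centroids = centroids,
         sia = sia, cylinder = cylinder, misalignment = misalignment,
         config = config),
    class = "toric_study"
  )
}

#' Run the synthetic study pipeline end to end
#'
#' [generate_cohort()] (which seeds the RNG from `config$seed`), then
#' [simulate_surgery()], then [analyze_study()]. Deterministic for a fixed
#' configuration.
#'
#' @inheritParams generate_cohort
#' @param ... Passed on to [analyze_study()] (thresholds).
#' @return A `toric_study` object.
#' @examples
#' \donttest{
#' study <- run_cohort_study(cohort_config(n_eyes = 10, seed = 3))
#' glance(study)
#' }
#' @export
run_cohort_study <- function(config = cohort_config(), ...) {
  eyes <- generate_cohort(config)
  eyes <- simulate_surgery(eyes, config)
  analyze_study(eyes, config, ...)
}

#' Export a cohort in the biometry CSV interchange schema
#'
#' One row per eye per keratometry source, readable by
#' [read_biometry_table()]; values are written at full precision.
#'
#' @param eyes Cohort tibble from [generate_cohort()].
#' @inheritParams generate_cohort
#' @return Long tibble in the interchange schema.
#' @export
cohort_to_biometry <- function(eyes, config = cohort_config()) {
  idx <- c(K = config$index_k, TK = config$index_tk, TCRP = config$index_tcrp)
  purrr::map_dfr(c("K", "TK", "TCRP"), function(s) {
    p <- tolower(s)
    tibble(
      eye_id = eyes$eye_id,
      source = s,
      flat_power_D = eyes[[paste0(p, "_flat")]],
      steep_power_D = eyes[[paste0(p, "_steep")]],
      steep_axis_deg = eyes[[paste0(p, "_axis")]],
      index_basis = idx[[s]],
      axial_length_mm = eyes$al_mm,
      elp_mm = eyes$elp_mm
    )
  }) |>
    dplyr::arrange(.data$eye_id, .data$source)
}

## ---- toric_study methods --------------------------------------------------

#' @export
print.toric_study <- function(x, ...) {
  cat(sprintf("<toric_study> %d eyes, sources: %s\n",
              nrow(x$eyes), paste(unique(x$pe$source), collapse = ", ")))
  cat("\nPrediction error by keratometry source:\n")
  print(as.data.frame(x$summary), digits = 3, row.names = FALSE)
  cat(sprintf("\nANOVA: F(%d, %d) = %.2f, p = %.3g\n",
              x$anova$df1, x$anova$df2, x$anova$statistic, x$anova$p_value))
  ach <- x$sia$achieved
  cat(sprintf("SIA achieved centroid: %.2f D @ %.0f (assumed %.2f D @ %.0f)\n",
              ach$magnitude, ach$axis,
              x$sia$assumed$magnitude, x$sia$assumed$axis))
  cat(sprintf("IOL misalignment: %.2f deg (+/- %.2f)\n",
              x$misalignment$mean, x$misalignment$sd))
  invisible(x)
}

#' Broom-style accessors for `toric_study` objects
#'
#' `tidy()` returns the long per-eye prediction-error table (one row per
#' eye and keratometry source); `glance()` a one-row model-level summary.
#'
#' @param x A `toric_study` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy toric_study
#' @export
tidy.toric_study <- function(x, ...) {
  x$pe
}

#' @rdname tidy.toric_study
#' @method glance toric_study
#' @export
glance.toric_study <- function(x, ...) {
  tibble(
    n_eyes = nrow(x$eyes),
    statistic = x$anova$statistic,
    p_value = x$anova$p_value,
    sia_magnitude = x$sia$achieved$magnitude,
    sia_axis = x$sia$achieved$axis,
    misalignment_mean = x$misalignment$mean,
    postop_cyl_mean = x$cylinder$postop_mean
  )
}

#' Plot a `toric_study`
#'
#' `type = "pe"`: prediction-error distribution per keratometry source;
#' `type = "double_angle"`: double-angle plot of the preoperative TCRP
#' astigmatism; `type = "cumulative"`: cumulative pre/post cylinder
#' histogram.
#'
#' @param object A `toric_study`.
#' @param type Which panel to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot toric_study
#' @export
autoplot.toric_study <- function(object,
                                 type = c("pe", "double_angle", "cumulative"),
                                 ...) {
  type <- match.arg(type)
  if (type == "pe") {
    return(
      ggplot2::ggplot(object$pe,
                      ggplot2::aes(.data$source, .data$pe)) +
        ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
        ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
        ggplot2::geom_jitter(width = 0.15, alpha = 0.5) +
        ggplot2::labs(x = "keratometry source",
                      y = "prediction error (D)") +
        ggplot2::theme_minimal()
    )
  }
  if (type == "double_angle") {
    d <- tibble(magnitude = object$eyes$tcrp_steep - object$eyes$tcrp_flat,
                axis = object$eyes$tcrp_axis)
    return(plot_double_angle(d))
  }
  cum <- dplyr::bind_rows(
    dplyr::mutate(object$cylinder$preop_tcrp, stage = "preop corneal (TCRP)"),
    dplyr::mutate(object$cylinder$postop_refractive,
                  stage = "postop refractive")
  )
  ggplot2::ggplot(cum, ggplot2::aes(factor(.data$threshold),
                                    .data$pct_within, fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(ggplot2::aes(label = paste0("(", .data$n_within, ")")),
                       position = ggplot2::position_dodge(width = 0.9),
                       vjust = -0.3, size = 3) +
    ggplot2::labs(x = "cylinder threshold (D)", y = "% of eyes within") +
    ggplot2::theme_minimal()
}
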