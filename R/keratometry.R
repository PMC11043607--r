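#' Corneal radius of curvature to keratometric power
#'
#' Keratometric convention `P = (n - 1) / r` with the device's keratometric
#' index `n`. Standard K and TK readings use 1.332, Scheimpflug TCRP readings
#' 1.3375.
#'
#' @param radius_mm Radius of curvature in millimetres (> 0).
#' @param index Keratometric refractive index (> 1).
#' @return Power in dioptres.
#' @examples
#' radius_to_power(7.5, 1.3375)   # 45.00 D
#' radius_to_power(7.5, 1.332)    # 44.27 D
#' @export
radius_to_power <- function(radius_mm, index = 1.3375) {
  check_finite(radius_mm = radius_mm, index = index)
  if (any(radius_mm <= 0)) abort("`radius_mm` must be positive.")
  if (any(index <= 1)) abort("`index` must exceed 1.")
  (index - 1) / (radius_mm / 1000)
}

#' @rdname radius_to_power
#' @param power Keratometric power in dioptres (non-zero).
#' @export
power_to_radius <- function(power, index = 1.3375) {
  check_finite(power = power, index = index)
  if (any(index <= 1)) abort("`index` must exceed 1.")
  if (any(power == 0)) abort("`power` must be non-zero.")
  (index - 1) / power * 1000
}

#' Re-express a keratometric power on a different index basis
#'
#' Devices print corneal powers on different keratometric index bases
#' (1.332 for standard K and TK, 1.3375 for TCRP). Because `P = (n - 1)/r`,
#' the same cornea re-expressed on another basis scales by
#' `(n' - 1) / (n - 1)`.
#'
#' @param power Power in dioptres on the `from_index` basis.
#' @param from_index,to_index Keratometric indices (> 1).
#' @return Power on the `to_index` basis (D).
#' @examples
#' reindex_power(45, 1.3375, 1.332)   # 44.27 D
#' @export
reindex_power <- function(power, from_index, to_index) {
  check_finite(power = power, from_index = from_index, to_index = to_index)
  if (any(from_index <= 1) || any(to_index <= 1)) {
    abort("Refractive indices must exceed 1.")
  }
  power * (to_index - 1) / (from_index - 1)
}

#' Corneal power matrix from a keratometry reading
#'
#' Builds the dioptric power matrix of a cornea from flat/steep meridional
#' powers and the steep-meridian axis, optionally rebasing to a common
#' keratometric index first. The matrix has eigenvalue `flat_power` along the
#' flat meridian (`steep_axis + 90`) and `steep_power` along `steep_axis`.
#'
#' @param flat_power,steep_power Meridional powers in dioptres
#'   (`steep_power >= flat_power`).
#' @param steep_axis Steep-meridian axis, degrees.
#' @param index_basis Keratometric index the powers are expressed on.
#' @param target_index Index basis required by the downstream calculation;
#'   defaults to `index_basis` (no rebasing).
#' @return Power-matrix tibble (`f11`, `f12`, `f22`).
#' @examples
#' keratometry_to_matrix(42, 44, 90)                      # diag(42, 44)
#' keratometry_to_matrix(43.5, 45, 85, 1.3375, 1.332)     # TCRP rebased
#' @export
keratometry_to_matrix <- function(flat_power, steep_power, steep_axis,
                                  index_basis = 1.332,
                                  target_index = index_basis) {
  check_finite(flat_power = flat_power, steep_power = steep_power,
               steep_axis = steep_axis)
  if (any(steep_power < flat_power - 1e-9)) {
    abort("`steep_power` must be at least `flat_power`.")
  }
  flat <- reindex_power(flat_power, index_basis, target_index)
  steep <- reindex_power(steep_power, index_basis, target_index)
  sphero_to_matrix(flat, steep - flat, (steep_axis + 90) %% 180)
}

#' Classify corneal astigmatism orientation
#'
#' With-the-rule (WTR) for steep axes 60--120 degrees, against-the-rule (ATR)
#' for 0--30 or 150--180, oblique otherwise. Boundaries are assigned to the
#' WTR/ATR side (ATR `[0,30]` and `[150,180)`, WTR `[60,120]`), so every axis
#' in `[0, 180)` receives exactly one label.
#'
#' @param steep_axis Steep-meridian axis in degrees (reduced modulo 180).
#' @return Character vector with values `"WTR"`, `"ATR"` or `"oblique"`.
#' @examples
#' classify_astigmatism(c(90, 20, 45))
#' @export
classify_astigmatism <- function(steep_axis) {
  check_finite(steep_axis = steep_axis)
  a <- steep_axis %% 180
  dplyr::case_when(
    a >= 60 & a <= 120 ~ "WTR",
    a <= 30 | a >= 150 ~ "ATR",
    .default = "oblique"
  )
}

#' Read and validate a per-eye biometry table
#'
#' Reads the package's biometry CSV interchange format: comma-separated, dot
#' decimal, UTF-8, one header row, one row per eye per keratometry source.
#' Required columns: `eye_id`, `source` (one of `K`, `TK`, `TCRP`),
#' `flat_power_D`, `steep_power_D`, `steep_axis_deg`, `index_basis`,
#' `axial_length_mm`. Optional: `elp_mm`, `flat_radius_mm`,
#' `steep_radius_mm`. Every row is validated against the keratometry
#' invariants; violations abort with the offending row number. When both
#' radii and powers are present the powers win and the radii are
#' cross-checked (a warning is raised on more than 0.1 D disagreement).
#'
#' @param path Path to the CSV file.
#' @return A validated tibble with the columns above.
#' @seealso [write_biometry_table()], [generate_cohort()]
#' @examples
#' path <- system.file("extdata", "example_biometry.csv", package = "torimetry")
#' read_biometry_table(path)
#' @export
read_biometry_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("eye_id", "source", "flat_power_D", "steep_power_D",
                "steep_axis_deg", "index_basis", "axial_length_mm")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    abort(paste0("Biometry table is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  numeric_cols <- setdiff(required, c("eye_id", "source"))
  for (col in numeric_cols) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(tab[[col]]))))
    if (length(bad)) {
      abort(sprintf("Row %d: column `%s` is not a finite number.", bad[1], col))
    }
    tab[[col]] <- as.numeric(tab[[col]])
  }
  bad_source <- which(!tab$source %in% c("K", "TK", "TCRP"))
  if (length(bad_source)) {
    abort(sprintf("Row %d: `source` must be one of K, TK, TCRP (got \"%s\").",
                  bad_source[1], tab$source[bad_source[1]]))
  }
  bad_cyl <- which(tab$steep_power_D < tab$flat_power_D - 1e-9)
  if (length(bad_cyl)) {
    abort(sprintf("Row %d: steep power (%.3f D) is below flat power (%.3f D).",
                  bad_cyl[1], tab$steep_power_D[bad_cyl[1]],
                  tab$flat_power_D[bad_cyl[1]]))
  }
  bad_axis <- which(tab$steep_axis_deg < 0 | tab$steep_axis_deg >= 180)
  if (length(bad_axis)) {
    abort(sprintf("Row %d: `steep_axis_deg` must lie in [0, 180).", bad_axis[1]))
  }
  bad_index <- which(tab$index_basis <= 1)
  if (length(bad_index)) {
    abort(sprintf("Row %d: `index_basis` must exceed 1.", bad_index[1]))
  }
  bad_al <- which(tab$axial_length_mm <= 0)
  if (length(bad_al)) {
    abort(sprintf("Row %d: `axial_length_mm` must be positive.", bad_al[1]))
  }
  if (all(c("flat_radius_mm", "steep_radius_mm") %in% names(tab))) {
    have <- is.finite(tab$flat_radius_mm) & is.finite(tab$steep_radius_mm)
    if (any(have)) {
      p_flat <- radius_to_power(tab$flat_radius_mm[have], tab$index_basis[have])
      p_steep <- radius_to_power(tab$steep_radius_mm[have], tab$index_basis[have])
      off <- pmax(abs(p_flat - tab$flat_power_D[have]),
                  abs(p_steep - tab$steep_power_D[have]))
      if (any(off > 0.1)) {
        warn(sprintf(
          "Row %d: radii disagree with stated powers by %.2f D; powers are used.",
          which(have)[which(off > 0.1)[1]], max(off)))
      }
    }
  }
  as_tibble(tab)
}

#' @rdname read_biometry_table
#' @param data A biometry tibble in the interchange schema.
#' @export
write_biometry_table <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}
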