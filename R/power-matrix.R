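#' Sphero-cylindrical powers as dioptric power matrices
#'
#' A sphero-cylindrical power (sphere `S`, signed cylinder `C`, axis `alpha`
#' in degrees) is represented by the symmetric 2x2 dioptric power matrix
#'
#' \deqn{F = \begin{pmatrix} S + C\sin^2\alpha & -C\sin\alpha\cos\alpha \\
#'                           -C\sin\alpha\cos\alpha & S + C\cos^2\alpha
#'           \end{pmatrix}}
#'
#' whose eigenvalues are the two principal meridional powers (`S` along the
#' axis meridian, `S + C` perpendicular to it) and whose trace is twice the
#' spherical equivalent. Matrices make astigmatic powers additive and let
#' vergences propagate through the eye with ordinary linear algebra, which is
#' what the residual-refraction computation in [residual_refraction()] relies
#' on.
#'
#' Throughout the package a power matrix is a tibble with numeric columns
#' `f11`, `f12`, `f22` (one row per power; `f21 = f12` is implied by
#' symmetry). A plain 2x2 base matrix is accepted anywhere a power matrix is
#' expected and is checked for symmetry to 1e-9 D.
#'
#' Conventions: axes are TABO degrees (counterclockwise from horizontal,
#' observer's view), reduced modulo 180; distances are in metres and powers
#' in dioptres.
#'
#' @param sphere,cylinder,axis Numeric vectors: sphere (D), signed cylinder
#'   (D) and cylinder axis (degrees, reduced modulo 180). Vectors recycle
#'   against length 1.
#'
#' @return A tibble with columns `f11`, `f12`, `f22` (dioptres).
#'
#' @examples
#' sphero_to_matrix(1, 2, 45)                  # principal powers 1 and 3 D
#' sphero_to_matrix(0, -1, 90)                 # plano / -1.00 x 90
#' # transposed form denotes the same power:
#' sphero_to_matrix(-1, 1, 0)
#' @export
sphero_to_matrix <- function(sphere, cylinder = 0, axis = 0) {
  check_finite(sphere = sphere, cylinder = cylinder, axis = axis)
  a <- (axis %% 180) * pi / 180
  fast_df(
    f11 = sphere + cylinder * sin(a)^2,
    f12 = -cylinder * sin(a) * cos(a),
    f22 = sphere + cylinder * cos(a)^2
  )
}

#' Recover sphere/cylinder/axis from a dioptric power matrix
#'
#' Inverse of [sphero_to_matrix()] by eigen-decomposition, in closed form for
#' the symmetric 2x2 case. The requested cylinder sign convention decides
#' which principal power becomes the sphere; equal eigenvalues (a pure
#' sphere) canonicalise to cylinder 0, axis 0.
#'
#' @param m A power matrix: tibble/data frame with columns `f11`, `f12`,
#'   `f22`, or a 2x2 base matrix (symmetric to within `tol`).
#' @param cylinder_sign `"negative"` (default, refraction convention) or
#'   `"positive"`.
#' @param tol Symmetry tolerance in dioptres for 2x2 matrix input.
#'
#' @return Tibble with columns `sphere`, `cylinder`, `axis` (axis in
#'   `[0, 180)` degrees).
#'
#' @examples
#' matrix_to_sphero(sphero_to_matrix(1, 2, 45), "positive")
#' matrix_to_sphero(matrix(c(-1, 0, 0, 0), 2))   # 0 / -1.00 x 90
#' @export
matrix_to_sphero <- function(m, cylinder_sign = c("negative", "positive"),
                             tol = 1e-9) {
  cylinder_sign <- match.arg(cylinder_sign)
  m <- as_dpower(m, tol = tol)
  cyl_mag <- sqrt((m$f11 - m$f22)^2 + 4 * m$f12^2)
  if (cylinder_sign == "negative") {
    sphere <- (m$f11 + m$f22 + cyl_mag) / 2
    cylinder <- -cyl_mag
    two_alpha <- atan2(2 * m$f12, m$f11 - m$f22)
  } else {
    sphere <- (m$f11 + m$f22 - cyl_mag) / 2
    cylinder <- cyl_mag
    two_alpha <- atan2(-2 * m$f12, m$f22 - m$f11)
  }
  axis <- (two_alpha * 180 / pi / 2) %% 180
  pure_sphere <- cyl_mag <= 1e-12
  fast_df(
    sphere = ifelse(pure_sphere, (m$f11 + m$f22) / 2, sphere),
    cylinder = ifelse(pure_sphere, 0, cylinder),
    axis = ifelse(pure_sphere, 0, axis)
  )
}

#' Spherical equivalent of a sphero-cylindrical power
#'
#' `SE = sphere + cylinder / 2`, i.e. half the trace of the corresponding
#' power matrix; invariant under transposition of the sphero-cylinder.
#'
#' @inheritParams sphero_to_matrix
#' @return Numeric vector of spherical equivalents (D).
#' @examples
#' spherical_equivalent(0.5, -1)   # 0
#' @export
spherical_equivalent <- function(sphere, cylinder = 0) {
  sphere + cylinder / 2
}

#' Transposed form of a sphero-cylindrical power
#'
#' `(S, C, axis)` and `(S + C, -C, axis + 90)` denote the same power; this
#' returns the other form.
#'
#' @inheritParams sphero_to_matrix
#' @return Tibble with columns `sphere`, `cylinder`, `axis`.
#' @export
transpose_sphero <- function(sphere, cylinder = 0, axis = 0) {
  tibble(
    sphere = sphere + cylinder,
    cylinder = -cylinder,
    axis = (axis + 90) %% 180
  )
}

#' Propagate a vergence matrix across a homogeneous gap
#'
#' Forward propagation over a reduced gap of width `distance` in a medium of
#' refractive index `index` follows
#' \deqn{V' = V (I - (d/n) V)^{-1},}
#' and backward propagation is the exact inverse,
#' \deqn{V = V' (I + (d/n) V')^{-1}.}
#' Both reduce to the scalar vergence formula per principal meridian, so the
#' operation commutes with eigen-decomposition. The propagation is singular
#' when a principal meridian focuses inside the gap (the matrix
#' \eqn{I \mp (d/n)V} loses rank); this is reported as an error of class
#' `torimetry_singular`.
#'
#' @param v Vergence as a power matrix (tibble `f11`,`f12`,`f22` or 2x2
#'   matrix), dioptres.
#' @param distance Gap width in metres (non-negative).
#' @param index Refractive index of the gap medium.
#' @param direction `"forward"` (with the light) or `"backward"`.
#'
#' @return Power-matrix tibble of the propagated vergence.
#' @examples
#' v <- sphero_to_matrix(42.978)
#' propagate_vergence(v, 0.005, 1.336)           # about 51.22 D
#' @export
propagate_vergence <- function(v, distance, index = 1.336,
                               direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  check_finite(distance = distance, index = index)
  v <- as_dpower(v)
  k <- distance / index
  if (direction == "backward") k <- -k
  det <- (1 - k * v$f11) * (1 - k * v$f22) - (k * v$f12)^2
  if (any(abs(det) < 1e-10)) {
    abort(
      "Singular vergence propagation: a principal meridian focuses inside the gap.",
      class = "torimetry_singular"
    )
  }
  fast_df(
    f11 = (v$f11 * (1 - k * v$f22) + k * v$f12^2) / det,
    f12 = v$f12 / det,
    f22 = (v$f22 * (1 - k * v$f11) + k * v$f12^2) / det
  )
}

#' Add dioptric powers (thin-element refraction)
#'
#' Thin refraction in matrix form: `V_out = V_in + F`. Power matrices add
#' componentwise, so the operation is commutative and associative and the
#' zero matrix is the identity. This is how obliquely crossed cylinders
#' combine.
#'
#' @param v,f Power matrices (tibble `f11`,`f12`,`f22` or 2x2 matrix). Rows
#'   recycle against length 1.
#' @return Power-matrix tibble of the sum.
#' @examples
#' # crossed +1 D cylinders at 0 and 90 degrees make a +1 D sphere:
#' add_power(sphero_to_matrix(0, 1, 0), sphero_to_matrix(0, 1, 90))
#' @export
add_power <- function(v, f) {
  v <- as_dpower(v)
  f <- as_dpower(f)
  fast_df(f11 = v$f11 + f$f11, f12 = v$f12 + f$f12, f22 = v$f22 + f$f22)
}

#' Move a refraction between reference planes (vertex change)
#'
#' Applies the scalar vertex formula `P' = P / (1 - d P)` independently to
#' each principal meridian, in air. Positive `distance` moves the reference
#' plane towards the eye (e.g. spectacle plane to corneal plane with
#' `distance = 0.012`); negative moves it away. Errors (class
#' `torimetry_singular`) if a meridian focuses within the gap.
#'
#' @inheritParams sphero_to_matrix
#' @param distance Plane shift in metres, positive towards the eye.
#' @return Tibble with columns `sphere`, `cylinder`, `axis`.
#' @examples
#' change_vertex(-4, 0, 0, 0.012)   # -3.82 D at the cornea
#' @export
change_vertex <- function(sphere, cylinder = 0, axis = 0, distance = 0.012) {
  check_finite(sphere = sphere, cylinder = cylinder, axis = axis,
               distance = distance)
  p1 <- sphere
  p2 <- sphere + cylinder
  d1 <- 1 - distance * p1
  d2 <- 1 - distance * p2
  if (any(abs(d1) < 1e-10) || any(abs(d2) < 1e-10)) {
    abort("Singular vertex change: a meridian focuses within the gap.",
          class = "torimetry_singular")
  }
  q1 <- p1 / d1
  q2 <- p2 / d2
  cyl <- q2 - q1
  fast_df(
    sphere = q1,
    cylinder = cyl,
    axis = ifelse(abs(cyl) <= 1e-12, 0, axis %% 180)
  )
}

## ---- internal helpers -----------------------------------------------------

# Canonicalise power-matrix input to a tibble(f11, f12, f22).
as_dpower <- function(m, tol = 1e-9) {
  if (is.matrix(m)) {
    if (!all(dim(m) == c(2L, 2L))) {
      abort("A power matrix given as a base matrix must be 2x2.")
    }
    if (abs(m[1, 2] - m[2, 1]) > tol) {
      abort(
        sprintf("Power matrix is asymmetric beyond tolerance: |f12 - f21| = %.3g D.",
                abs(m[1, 2] - m[2, 1])),
        class = "torimetry_asymmetric"
      )
    }
    return(fast_df(f11 = m[1, 1], f12 = (m[1, 2] + m[2, 1]) / 2, f22 = m[2, 2]))
  }
  if (is.data.frame(m)) {
    missing_cols <- setdiff(c("f11", "f12", "f22"), names(m))
    if (length(missing_cols)) {
      abort(paste0("Power matrix data frame lacks column(s): ",
                   paste(missing_cols, collapse = ", "), "."))
    }
    check_finite(f11 = m$f11, f12 = m$f12, f22 = m$f22)
    return(fast_df(f11 = m$f11, f12 = m$f12, f22 = m$f22))
  }
  abort("A power matrix must be a data frame with columns f11/f12/f22 or a 2x2 matrix.")
}

# Minimal-overhead tibble constructor for the hot numeric paths: recycles
# against the longest column, skips quosure evaluation and name repair.
fast_df <- function(...) {
  cols <- list(...)
  n <- max(lengths(cols))
  for (i in seq_along(cols)) {
    if (length(cols[[i]]) != n) cols[[i]] <- rep_len(cols[[i]], n)
  }
  tibble::new_tibble(cols, nrow = n)
}

check_finite <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    x <- args[[nm]]
    if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
      abort(sprintf("`%s` must be finite numeric.", nm))
    }
  }
  invisible(TRUE)
}
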