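# Independent oracles, deliberately re-coded from first principles and kept
# free of the package's matrix machinery.

# Scalar vergence forward step: V' = V / (1 - (d/n) V)
scalar_forward <- function(v, d, n = 1.336) v / (1 - (d / n) * v)

# Scalar vergence backward step: V = V' / (1 + (d/n) V')
scalar_backward <- function(v, d, n = 1.336) v / (1 + (d / n) * v)

# Full scalar residual-refraction chain for one meridian of a pseudophakic
# eye: corneal power, IOL power, axial length and ELP in metres.
scalar_residual_chain <- function(cornea_power, iol_power, al, elp, n = 1.336) {
  v_img <- n / (al - elp)
  v_pre <- v_img - iol_power
  scalar_backward(v_pre, elp, n) - cornea_power
}

# Scalar IOL solve for one meridian: target refraction at the corneal plane.
scalar_iol_chain <- function(cornea_power, al, elp, target = 0, n = 1.336) {
  v_img <- n / (al - elp)
  v_img - scalar_forward(target + cornea_power, elp, n)
}

# Closed-form power matrix of (S, C, axis), written out independently.
oracle_matrix <- function(s, c, a_deg) {
  a <- a_deg * pi / 180
  matrix(c(s + c * sin(a)^2, -c * sin(a) * cos(a),
           -c * sin(a) * cos(a), s + c * cos(a)^2), 2, 2)
}

# Random sphero-cylinders spanning refractions and corneal-scale powers.
random_spheros <- function(n, sphere_range = c(-10, 10),
                           cyl_range = c(-6, 6)) {
  tibble::tibble(
    sphere = runif(n, sphere_range[1], sphere_range[2]),
    cylinder = runif(n, cyl_range[1], cyl_range[2]),
    axis = runif(n, 0, 180)
  )
}

expect_matrix_equal <- function(a, b, tol) {
  expect_lt(max(abs(a$f11 - b$f11), abs(a$f12 - b$f12), abs(a$f22 - b$f22)),
            tol)
}
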