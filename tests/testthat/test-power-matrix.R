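test_that("sphero_to_matrix matches the closed form and its worked cases", {
  # pure sphere is isotropic
  m <- sphero_to_matrix(2, 0, 37)
  expect_equal(unlist(m), c(f11 = 2, f12 = 0, f22 = 2))

  # plano / -1.00 x 90 concentrates the power on the horizontal meridian
  m <- sphero_to_matrix(0, -1, 90)
  expect_equal(unlist(m), c(f11 = -1, f12 = 0, f22 = 0), tolerance = 1e-12)
  # ... and equals its transposed form exactly
  tr <- transpose_sphero(0, -1, 90)
  expect_matrix_equal(m, sphero_to_matrix(tr$sphere, tr$cylinder, tr$axis),
                      1e-12)

  # +1.00 / +2.00 x 45 with principal powers 1 and 3
  m <- sphero_to_matrix(1, 2, 45)
  expect_equal(unlist(m), c(f11 = 2, f12 = -1, f22 = 2), tolerance = 1e-12)
  ev <- eigen(matrix(c(m$f11, m$f12, m$f12, m$f22), 2))$values
  expect_equal(sort(ev), c(1, 3), tolerance = 1e-12)

  # trace and determinant identities: 2S + C and S(S + C)
  sc <- random_spheros(50)
  m <- sphero_to_matrix(sc$sphere, sc$cylinder, sc$axis)
  expect_equal(m$f11 + m$f22, 2 * sc$sphere + sc$cylinder, tolerance = 1e-12)
  expect_equal(m$f11 * m$f22 - m$f12^2, sc$sphere * (sc$sphere + sc$cylinder),
               tolerance = 1e-10)

  expect_error(sphero_to_matrix(NA, 1, 0), "finite")
})

test_that("matrix_to_sphero inverts the closed form in both sign conventions", {
  expect_equal(
    unlist(matrix_to_sphero(matrix(c(2, 0, 0, 2), 2))),
    c(sphere = 2, cylinder = 0, axis = 0)
  )
  expect_equal(
    unlist(matrix_to_sphero(matrix(c(2, -1, -1, 2), 2), "positive")),
    c(sphere = 1, cylinder = 2, axis = 45),
    tolerance = 1e-12
  )
  expect_equal(
    unlist(matrix_to_sphero(matrix(c(-1, 0, 0, 0), 2), "negative")),
    c(sphere = 0, cylinder = -1, axis = 90),
    tolerance = 1e-12
  )
  expect_error(matrix_to_sphero(matrix(c(1, 0.5, 0, 1), 2)),
               class = "torimetry_asymmetric")
})

test_that("matrix <-> sphero round trips are exact for random powers", {
  set.seed(41)
  sc <- random_spheros(500)
  m <- sphero_to_matrix(sc$sphere, sc$cylinder, sc$axis)
  for (sign in c("negative", "positive")) {
    back <- matrix_to_sphero(m, sign)
    m2 <- sphero_to_matrix(back$sphere, back$cylinder, back$axis)
    expect_matrix_equal(m, m2, 1e-12)
  }
  # transposition invariance of the matrix representation
  tr <- transpose_sphero(sc$sphere, sc$cylinder, sc$axis)
  expect_matrix_equal(m, sphero_to_matrix(tr$sphere, tr$cylinder, tr$axis),
                      1e-12)
})

test_that("spherical equivalent is half the matrix trace and transposition-safe", {
  expect_equal(spherical_equivalent(0.5, -1), 0)
  expect_equal(spherical_equivalent(-0.25, -0.5), -0.5)
  set.seed(42)
  sc <- random_spheros(100)
  m <- sphero_to_matrix(sc$sphere, sc$cylinder, sc$axis)
  expect_equal(spherical_equivalent(sc$sphere, sc$cylinder),
               (m$f11 + m$f22) / 2, tolerance = 1e-12)
  tr <- transpose_sphero(sc$sphere, sc$cylinder, sc$axis)
  expect_equal(spherical_equivalent(tr$sphere, tr$cylinder),
               spherical_equivalent(sc$sphere, sc$cylinder), tolerance = 1e-12)
})

test_that("vergence propagation reduces to the scalar formula and inverts", {
  v <- sphero_to_matrix(42.978)
  expect_matrix_equal(propagate_vergence(v, 0, 1.336), v, 1e-15)

  out <- propagate_vergence(v, 0.005, 1.336)
  expect_equal(out$f11, scalar_forward(42.978, 0.005, 1.336),
               tolerance = 1e-12)
  expect_equal(out$f11, 51.2166, tolerance = 1e-4)

  set.seed(43)
  sc <- random_spheros(300, sphere_range = c(30, 55), cyl_range = c(0, 6))
  m <- sphero_to_matrix(sc$sphere, sc$cylinder, sc$axis)
  fwd <- propagate_vergence(m, 0.005, 1.336, "forward")
  back <- propagate_vergence(fwd, 0.005, 1.336, "backward")
  expect_matrix_equal(m, back, 1e-10)

  # matrix propagation equals per-eigenvalue scalar propagation
  p1 <- scalar_forward(sc$sphere, 0.005, 1.336)
  p2 <- scalar_forward(sc$sphere + sc$cylinder, 0.005, 1.336)
  expect_matrix_equal(fwd, sphero_to_matrix(p1, p2 - p1, sc$axis), 1e-10)

  # focal point inside the gap is a distinct error
  expect_error(propagate_vergence(sphero_to_matrix(267.2), 0.005, 1.336),
               class = "torimetry_singular")
})

test_that("thin powers add like matrices (obliquely crossed cylinders)", {
  v <- sphero_to_matrix(3, -2, 120)
  zero <- sphero_to_matrix(0)
  expect_matrix_equal(add_power(v, zero), v, 1e-15)

  s <- add_power(sphero_to_matrix(1, 0, 0), sphero_to_matrix(0, -1, 90))
  expect_matrix_equal(s, sphero_to_matrix(1, -1, 90), 1e-12)

  # crossed equal cylinders 90 degrees apart make a sphere
  s <- add_power(sphero_to_matrix(0, 1, 0), sphero_to_matrix(0, 1, 90))
  expect_matrix_equal(s, sphero_to_matrix(1), 1e-12)

  a <- sphero_to_matrix(2, -1, 10)
  b <- sphero_to_matrix(-1, 3, 75)
  expect_matrix_equal(add_power(a, b), add_power(b, a), 1e-15)
})

test_that("vertex changes act per principal meridian in air", {
  expect_equal(unlist(change_vertex(0, 0, 0, 0.05)),
               c(sphere = 0, cylinder = 0, axis = 0))
  expect_equal(change_vertex(-4, 0, 0, 0)$sphere, -4)
  # -4.00 D moved 12 mm from spectacle to corneal plane
  expect_equal(change_vertex(-4, 0, 0, 0.012)$sphere, -4 / (1 + 0.012 * 4),
               tolerance = 1e-12)
  expect_equal(change_vertex(-4, 0, 0, 0.012)$sphere, -3.8168,
               tolerance = 1e-4)
  # toric case: two independent meridional conversions
  out <- change_vertex(-2, -1.5, 40, 0.012)
  p1 <- -2 / (1 - 0.012 * -2)
  p2 <- -3.5 / (1 - 0.012 * -3.5)
  expect_equal(out$sphere, p1, tolerance = 1e-12)
  expect_equal(out$sphere + out$cylinder, p2, tolerance = 1e-12)
  expect_equal(out$axis, 40)
  expect_error(change_vertex(1 / 0.012, 0, 0, 0.012),
               class = "torimetry_singular")
})
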