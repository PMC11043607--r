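test_that("the spherical worked example matches the scalar vergence chain", {
  res <- residual_refraction(sphero_to_matrix(43), 21, 0, 0, 0.0235, 0.005)
  oracle <- scalar_residual_chain(43, 21, 0.0235, 0.005)
  expect_equal(res$sphere, oracle, tolerance = 1e-9)
  expect_equal(res$cylinder, 0, tolerance = 1e-12)
  expect_lt(abs(res$sphere - (-0.02)), 0.005)
})

test_that("aligned toric eyes reduce to two independent scalar chains", {
  set.seed(51)
  for (i in 1:50) {
    flat <- runif(1, 40, 46)
    cyl <- runif(1, 0.5, 4)
    steep_axis <- runif(1, 0, 180)
    al <- runif(1, 0.022, 0.026)
    elp <- runif(1, 0.004, 0.006)
    iol_s <- runif(1, 15, 24)
    iol_c <- runif(1, 0, 4)
    cornea <- keratometry_to_matrix(flat, flat + cyl, steep_axis)
    # implant axis on the steep corneal meridian: IOL sphere acts along it
    res <- residual_refraction(cornea, iol_s, iol_c, steep_axis, al, elp)
    r_steep <- scalar_residual_chain(flat + cyl, iol_s, al, elp)
    r_flat <- scalar_residual_chain(flat, iol_s + iol_c, al, elp)
    expect_matrix_equal(
      sphero_to_matrix(res$sphere, res$cylinder, res$axis),
      sphero_to_matrix(r_steep, r_flat - r_steep, steep_axis),
      1e-10
    )
  }
})

test_that("IOL calculation matches the scalar solve and inverts the eye model", {
  iol <- calculate_iol(sphero_to_matrix(43), 0.0235, 0.005)
  expect_equal(iol$sphere, scalar_iol_chain(43, 0.0235, 0.005),
               tolerance = 1e-9)
  expect_equal(iol$sphere, 20.97, tolerance = 0.005)
  expect_equal(iol$cylinder, 0, tolerance = 1e-9)

  # toric target with aligned axes = two scalar solves
  cornea <- keratometry_to_matrix(42, 44.5, 100)
  iol <- calculate_iol(cornea, 0.024, 0.0048)
  expect_equal(iol$axis, 100, tolerance = 1e-9)
  expect_equal(iol$sphere, scalar_iol_chain(44.5, 0.024, 0.0048),
               tolerance = 1e-9)
  expect_equal(iol$sphere + iol$cylinder,
               scalar_iol_chain(42, 0.024, 0.0048), tolerance = 1e-9)

  # inverse pair for random eyes and targets, before any rounding
  set.seed(52)
  for (i in 1:30) {
    cornea <- keratometry_to_matrix(runif(1, 40, 46),
                                    runif(1, 46, 48), runif(1, 0, 180))
    al <- runif(1, 0.022, 0.027)
    elp <- runif(1, 0.004, 0.006)
    tgt <- c(runif(1, -1, 0.5), -runif(1, 0, 1.5), runif(1, 0, 180))
    iol <- calculate_iol(cornea, al, elp, tgt[1], tgt[2], tgt[3])
    res <- residual_refraction(cornea, iol$sphere, iol$cylinder, iol$axis,
                               al, elp)
    expect_matrix_equal(sphero_to_matrix(res$sphere, res$cylinder, res$axis),
                        sphero_to_matrix(tgt[1], tgt[2], tgt[3]), 1e-9)
  }

  # commercial rounding snaps to the step
  iol <- calculate_iol(sphero_to_matrix(43), 0.0235, 0.005, power_step = 0.5)
  expect_equal(iol$sphere, 21)
})

test_that("thin-lens limit: at vanishing ELP powers simply add at the cornea", {
  cornea <- keratometry_to_matrix(42.5, 44, 60)
  al <- 0.0236
  elp <- 1e-8
  res <- residual_refraction(cornea, 20, 1.5, 60, al, elp)
  v_img <- 1.336 / (al - elp)
  direct <- matrix_to_sphero(
    tibble::tibble(
      f11 = v_img - sphero_to_matrix(20, 1.5, 60)$f11 - cornea$f11,
      f12 = -sphero_to_matrix(20, 1.5, 60)$f12 - cornea$f12,
      f22 = v_img - sphero_to_matrix(20, 1.5, 60)$f22 - cornea$f22
    ),
    "negative"
  )
  expect_equal(res$sphere, direct$sphere, tolerance = 1e-4)
  expect_equal(res$cylinder, direct$cylinder, tolerance = 1e-4)
})

test_that("recommended axis minimises residual cylinder with deterministic ties", {
  # exactly neutralising IOL aligns with the steep corneal meridian
  cornea <- keratometry_to_matrix(42, 44, 90)
  al <- 0.0235
  elp <- 0.005
  iol <- calculate_iol(cornea, al, elp)
  rec <- recommended_axis(cornea, iol$sphere, iol$cylinder, al, elp)
  expect_equal(rec$axis, 90)
  expect_lt(abs(rec$residual_cylinder), 1e-9)

  # isotropic cornea: all axes tie, the smaller axis wins
  rec <- recommended_axis(sphero_to_matrix(43), 21, 1.5, al, elp)
  expect_equal(rec$axis, 0)

  # sweep optimality against an explicit residual_refraction sweep
  cornea <- keratometry_to_matrix(41.8, 44.1, 37)
  rec <- recommended_axis(cornea, 20.5, 2.5, al, elp, sweep_step = 0.5)
  axes <- seq(0, 179.5, by = 0.5)
  sweep_cyl <- abs(residual_refraction(cornea[rep(1, length(axes)), ],
                                       20.5, 2.5, axes, al, elp)$cylinder)
  expect_lte(abs(rec$residual_cylinder), min(sweep_cyl) + 1e-12)

  expect_error(recommended_axis(cornea, 21, 0, al, elp), "toric")
})

test_that("residual cylinder grows monotonically with off-axis rotation", {
  set.seed(53)
  al <- 0.0240
  elp <- 0.0050
  for (i in 1:10) {
    cornea <- keratometry_to_matrix(runif(1, 41, 45), runif(1, 45, 47),
                                    runif(1, 0, 180))
    iol <- calculate_iol(cornea, al, elp)
    rec <- recommended_axis(cornea, iol$sphere, iol$cylinder, al, elp)
    offsets <- seq(0, 45, by = 5)
    cyl <- abs(residual_refraction(cornea[rep(1, length(offsets)), ],
                                   iol$sphere, iol$cylinder,
                                   rec$axis + offsets, al, elp)$cylinder)
    expect_true(all(diff(cyl) >= -1e-9))
  }
})

test_that("prediction error is the SE difference with the expected sign", {
  expect_equal(prediction_error(0, 0.5, -1), 0)
  expect_equal(prediction_error(-0.25, 0, 0), 0.25)
  # antisymmetry: swapping the roles negates the error
  se <- spherical_equivalent(-0.5, -0.5)
  expect_equal(prediction_error(se, -0.1, 0),
               -prediction_error(spherical_equivalent(-0.1, 0), -0.5, -0.5))
})

test_that("implausible eye geometry is rejected or flagged", {
  expect_error(residual_refraction(sphero_to_matrix(43), 21, 0, 0,
                                   0.0235, 0.03), "elp")
  expect_warning(residual_refraction(sphero_to_matrix(43), 21, 0, 0,
                                     23.5, 5), "plausible")
})
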