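test_that("polar coordinates follow the pixel-center definitions", {
  geom <- saxs_geometry(c(100, 100), 1000, c(256, 256), c(172, 172))
  p <- pixel_polar_coordinates(geom, row0 = c(100, 100, 99),
                               col0 = c(100, 200, 101))
  expect_equal(p$r[1], 0)
  expect_equal(p$r[2], 17.2)                 # 100 px * 172 um
  expect_equal(p$psi[2], 0)                  # straight right
  # anisotropic pixels: one step up-right
  ga <- saxs_geometry(c(10, 10), 1000, c(32, 32), c(100, 200))
  pa <- pixel_polar_coordinates(ga, row0 = 9, col0 = 11)
  expect_equal(pa$r, sqrt(0.1^2 + 0.2^2))
  full <- pixel_polar_coordinates(geom)
  expect_true(all(full$r >= 0))
  expect_true(all(full$psi >= 0 & full$psi < 2 * pi))
  expect_equal(sum(full$r == 0), 1)          # only the beam-center pixel
})

test_that("distortion angle satisfies its limit contracts", {
  polar <- structure(list(r = rep(10, 361), psi = seq(0, 2 * pi, length.out = 361)),
                     class = "saxs_polar")
  g0 <- saxs_geometry(c(0, 0), 100, c(4, 4), c(100, 100),
                      tilt_rotation = 123, tilt_angle = 0)
  expect_equal(distortion_angle(polar, g0)$alpha, rep(0, 361))
  # on the tilt axis (psi - phi = +/-90 deg) alpha vanishes for any tau
  g30 <- saxs_geometry(c(0, 0), 100, c(4, 4), c(100, 100),
                       tilt_rotation = 40, tilt_angle = 30)
  on_axis <- structure(list(r = c(5, 5), psi = (40 + c(90, -90)) * pi / 180),
                       class = "saxs_polar")
  expect_equal(distortion_angle(on_axis, g30)$alpha, c(0, 0),
               tolerance = 1e-12)
  # along the steepest-tilt direction alpha equals tau
  steep <- structure(list(r = 5, psi = 40 * pi / 180), class = "saxs_polar")
  expect_equal(distortion_angle(steep, g30)$alpha, 30 * pi / 180)
  # translation property: alpha(phi, tau, psi) = alpha(0, tau, psi - phi)
  gA <- saxs_geometry(c(0, 0), 100, c(4, 4), c(100, 100), 77, 20)
  gB <- saxs_geometry(c(0, 0), 100, c(4, 4), c(100, 100), 0, 20)
  psi <- seq(0, 2 * pi, length.out = 50)
  aA <- distortion_angle(structure(list(r = 1, psi = psi),
                                   class = "saxs_polar"), gA)$alpha
  aB <- distortion_angle(structure(list(r = 1, psi = psi - 77 * pi / 180),
                                   class = "saxs_polar"), gB)$alpha
  expect_equal(aA, aB)
  # 2*pi periodicity
  aC <- distortion_angle(structure(list(r = 1, psi = psi + 2 * pi),
                                   class = "saxs_polar"), gA)$alpha
  expect_equal(aA, aC)
})

test_that("light path reduces to Pythagoras untilted and matches the 3D oracle", {
  g <- saxs_geometry(c(0, 0), 1000, c(4, 4), c(100, 100))
  polar <- structure(list(r = c(100, 0), psi = c(0, 0)), class = "saxs_polar")
  dist <- distortion_angle(polar, g)
  expect_equal(light_path(polar, dist, g), c(sqrt(1010000), 1000))
  # tilted: compare against the ray construction at the same pixel
  gt <- saxs_geometry(c(0, 0), 1000, c(4, 4), c(1000, 1000),
                      tilt_rotation = 0, tilt_angle = 5)
  # pixel 100 mm to the right of the beam center: psi = 0 = phi, alpha = tau
  o <- oracle_ray(gt, 1.54, row0 = 0, col0 = 100)
  pt <- pixel_polar_coordinates(gt, row0 = 0, col0 = 100)
  lt <- light_path(pt, distortion_angle(pt, gt), gt)
  expect_equal(lt, o$l, tolerance = 1e-12)
})

test_that("q matches the closed form untilted and scales inversely with wavelength", {
  g <- saxs_geometry(c(0, 0), 1000, c(4, 4), c(100, 100))
  polar <- structure(list(r = 100, psi = 0), class = "saxs_polar")
  dist <- distortion_angle(polar, g)
  l <- light_path(polar, dist, g)
  qm <- scattering_vector(polar, dist, l, g, 1.54)
  expect_equal(qm$two_theta, atan(0.1))
  expect_equal(qm$two_theta * 180 / pi, 5.7106, tolerance = 1e-4)
  expect_equal(qm$q, 4.065, tolerance = 1e-3)
  expect_equal(qm$q, closed_form_q(100, 1000, 1.54))
  qm2 <- scattering_vector(polar, dist, l, g, 2 * 1.54)
  expect_equal(qm2$q * 2, qm$q)
  # r = 0 means q = 0
  p0 <- structure(list(r = 0, psi = 0), class = "saxs_polar")
  d0 <- distortion_angle(p0, g)
  expect_equal(scattering_vector(p0, d0, light_path(p0, d0, g), g, 1.54)$q, 0)
  expect_error(scattering_vector(polar, dist, l, g, -1), "wavelength")
})

test_that("untilted full-frame q agrees with the closed form to 1e-9 nm^-1", {
  geom <- default_geometry()
  qm <- build_qmap(geom, 1.54)
  expect_lt(max(abs(qm$q - closed_form_q(qm$r, geom$detector_distance, 1.54))),
            1e-9)
})

test_that("tilted q matches the independent 3D ray oracle", {
  withr::with_seed(21, {
    for (i in 1:8) {
      g <- rand_geometry(shape = c(48, 48), tilted = TRUE)
      grid <- expand.grid(row0 = seq(0, 47, by = 6), col0 = seq(0, 47, by = 6))
      o <- oracle_ray(g, 1.54, grid$row0, grid$col0)
      qi <- build_qmap(g, 1.54, row0 = grid$row0, col0 = grid$col0)
      expect_lt(max(abs(qi$q - o$q) / pmax(o$q, 1e-9)), 1e-6)
      expect_lt(max(abs(qi$l - o$l) / o$l), 1e-9)
    }
  })
})

test_that("pixels on the tilt axis keep their untilted q under any tau", {
  g0 <- saxs_geometry(c(64, 64), 800, c(128, 128), c(172, 172), 0, 0)
  gt <- saxs_geometry(c(64, 64), 800, c(128, 128), c(172, 172),
                      tilt_rotation = 35, tilt_angle = 25)
  # points along psi = phi + 90 deg
  t <- seq(-60, 60, by = 3)
  ang <- (35 + 90) * pi / 180
  row0 <- 64 - t * sin(ang)   # up-positive
  col0 <- 64 + t * cos(ang)
  q0 <- build_qmap(g0, 1.54, row0 = row0, col0 = col0)$q
  qt <- build_qmap(gt, 1.54, row0 = row0, col0 = col0)$q
  expect_lt(max(abs(q0 - qt)), 1e-9)
})

test_that("q is continuous in tau at zero tilt", {
  eps <- 1e-6
  g0 <- saxs_geometry(c(20, 30), 500, c(64, 64), c(172, 172), 123, 0)
  ge <- saxs_geometry(c(20, 30), 500, c(64, 64), c(172, 172), 123, eps)
  q0 <- build_qmap(g0, 1.1)$q
  qe <- build_qmap(ge, 1.1)$q
  expect_lt(max(abs(qe - q0)), 1e-6)
})

test_that("qmaps are deterministic, cached and tilt-consistent", {
  g <- saxs_geometry(c(20, 30), 500, c(64, 64), c(172, 172), 10, 0)
  a <- build_qmap(g, 1.54)
  b <- build_qmap(g, 1.54)
  expect_identical(a, b)
  # q strictly increases along a ray from the beam center at tau = 0
  qray <- build_qmap(g, 1.54, row0 = rep(20, 30), col0 = 30 + seq_len(30))$q
  expect_true(all(diff(qray) > 0))
  # tau = 0 equals a tilted geometry evaluated with tau = 0
  g2 <- saxs_geometry(c(20, 30), 500, c(64, 64), c(172, 172), 275, 0)
  expect_equal(a$q, build_qmap(g2, 1.54)$q)
})
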