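# Independent oracles and randomized-fixture helpers shared across tests.

# Full 3D ray-construction oracle for the tilted-detector geometry: place the
# detector plane in 3D by rotating its axes about the tilt axis, find each
# pixel's 3D position, and measure the angle between the incident ray and the
# sample-to-pixel ray. Entirely independent of the package's distortion-angle
# algebra. Axis orientation: the steepest-tilt direction (psi = phi) tips
# away from the sample for positive tau, the package's documented convention.
oracle_ray <- function(geom, wavelength, row0, col0) {
  phi <- geom$tilt_rotation * pi / 180
  tau <- geom$tilt_angle * pi / 180
  axis <- c(sin(phi), -cos(phi), 0)
  rodrigues <- function(v, a, th)
    v * cos(th) + pracma::cross(a, v) * sin(th) + a * sum(a * v) * (1 - cos(th))
  eh <- rodrigues(c(1, 0, 0), axis, tau)
  ev <- rodrigues(c(0, 1, 0), axis, tau)
  n <- c(0, 0, 1)
  dx <- (col0 - geom$beamcenter[2]) * geom$pixel_size[2] * 1e-3
  dy <- (geom$beamcenter[1] - row0) * geom$pixel_size[1] * 1e-3
  out <- vapply(seq_along(dx), function(i) {
    P <- geom$detector_distance * n + dx[i] * eh + dy[i] * ev
    l <- sqrt(sum(P^2))
    tt <- acos(min(1, sum(P * n) / l))
    c(l = l, two_theta = tt,
      q = (4 * pi / wavelength) * sin(tt / 2) * 10)
  }, c(l = 0, two_theta = 0, q = 0))
  list(l = unname(out["l", ]), two_theta = unname(out["two_theta", ]),
       q = unname(out["q", ]))
}

# Closed-form untilted q in nm^-1 (r, d in mm, wavelength in Angstroem).
closed_form_q <- function(r, d, wavelength)
  (4 * pi / wavelength) * sin(0.5 * atan(r / d)) * 10

rand_geometry <- function(shape = c(64, 64), tilted = FALSE) {
  saxs_geometry(
    beamcenter = c(runif(1, 0.2, 0.8) * shape[1], runif(1, 0.2, 0.8) * shape[2]),
    detector_distance = runif(1, 300, 1500),
    image_size = shape,
    pixel_size = c(runif(1, 100, 300), runif(1, 100, 300)),
    tilt_rotation = if (tilted) runif(1, 0, 360) else 0,
    tilt_angle = if (tilted) runif(1, 0, 30) else 0
  )
}

rand_mask <- function(shape, frac = 0.05) {
  matrix(runif(prod(shape)) < frac, shape[1], shape[2])
}

# A tiny engine-ready setup for integrator tests.
make_setup <- function(geom, wavelength = 1.54, mask = NULL, step = 1, k = 1) {
  qm <- build_qmap(geom, wavelength)
  bn <- build_binning(qm, mask, step, geom)
  W <- build_weight_matrix(qm, bn, mask, k, geom, wavelength)
  list(qmap = qm, binning = bn, W = W, geom = geom, wavelength = wavelength,
       mask = mask)
}

expect_curves_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$q, b$q, tolerance = tol)
  expect_equal(a$I, b$I, tolerance = tol)
  expect_equal(a$A, b$A, tolerance = tol)
}

# Random but valid calibration for round-trip property tests.
rand_calibration <- function(n_masks = sample(1:3, 1),
                             n_slices = sample(0:2, 1)) {
  geom <- rand_geometry(shape = c(sample(32:256, 1), sample(32:256, 1)),
                        tilted = runif(1) < 0.5)
  masks <- replicate(n_masks, saxs_mask_spec(
    path_to_file = sample(c("", "mask.msk", "m2.tif"), 1),
    oversampling = sample(c(1L, 2L, 4L, 8L), 1),
    pix_per_rad_element = runif(1, 0.5, 4),
    q_start = runif(1, 0, 1), q_stop = runif(1, 2, 9)), simplify = FALSE)
  slices <- replicate(n_slices, {
    dir <- sample(c("x", "y"), 1)
    lim <- if (dir == "x") geom$image_size[1] else geom$image_size[2]
    saxs_slice_spec(dir, sample(c("InPlane", "Vertical"), 1),
                    position = sample(0:(lim - 1), 1),
                    margin = sample(0:3, 1),
                    mask_reference = sample(0:(n_masks - 1), 1))
  }, simplify = FALSE)
  saxs_calibration(geometry = geom, masks = masks, slices = slices,
                   wavelength = runif(1, 0.5, 2),
                   directory = c("/data/run1", "/data/run2"),
                   threads = sample(1:8, 1))
}
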