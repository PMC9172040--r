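test_that("bin counts derive from the radial step in pixel units", {
  geom <- saxs_geometry(c(0, 0), 1000, c(2, 501), c(172, 172))
  qm <- build_qmap(geom, 1.54)
  # r_max is 500 pixels along the first row
  expect_equal(build_binning(qm, NULL, 1, geom)$n_bins, 500)
  expect_equal(build_binning(qm, NULL, 2, geom)$n_bins, 250)
  # a step wider than the frame still yields one bin
  expect_equal(build_binning(qm, NULL, 1e6, geom)$n_bins, 1)
  bn <- build_binning(qm, NULL, 1, geom)
  expect_true(all(diff(bn$q_edges) > 0))
  expect_true(all(bn$q_centers > bn$q_edges[-length(bn$q_edges)] &
                  bn$q_centers < bn$q_edges[-1]))
  expect_error(build_binning(qm, matrix(TRUE, 2, 501), 1, geom), "masked")
})

test_that("weight-matrix columns are unit partitions for unmasked in-range pixels", {
  withr::with_seed(31, {
    for (k in c(1L, 2L, 8L)) {
      geom <- rand_geometry(c(48, 48))
      mask <- rand_mask(c(48, 48), 0.05)
      s <- make_setup(geom, mask = mask, k = k)
      cs <- Matrix::colSums(s$W$C)
      expect_true(all(cs <= 1 + 1e-12))
      expect_true(all(cs[as.vector(mask)] == 0))
      # pixels fully inside the q range sum to exactly 1
      qm <- s$qmap
      interior <- !as.vector(mask) &
        as.vector(qm$q) < 0.9 * max(qm$q[!mask])
      expect_lt(max(abs(cs[interior] - 1)), 1e-12)
      expect_true(all(s$W$A >= 0))
      expect_equal(bin_areas(s$W), as.numeric(s$W$C %*% rep(1, ncol(s$W$C))))
    }
  })
})

test_that("k = 1 reproduces nearest-bin assignment of pixel centers", {
  withr::with_seed(32, {
    geom <- rand_geometry(c(32, 32))
    s <- make_setup(geom, k = 1)
    # binary matrix, one entry per pixel
    expect_true(all(s$W$C@x == 1))
    expect_equal(length(s$W$C@x), 32 * 32)
    qv <- as.vector(s$qmap$q)
    expected_bin <- findInterval(qv, s$binning$q_edges, rightmost.closed = TRUE)
    got_bin <- apply(as.matrix(s$W$C), 2, which.max)
    expect_equal(unname(got_bin), expected_bin)
  })
})

test_that("oversampling splits straddling pixels per brute-force subpixel counts", {
  geom <- saxs_geometry(c(0, 0), 1000, c(2, 64), c(172, 172))
  wl <- 1.54
  s <- make_setup(geom, wavelength = wl, k = 8L)
  # find a pixel in row 0 whose subpixel q values straddle a bin edge
  found <- FALSE
  for (col in 5:60) {
    offs <- (seq_len(8) - 0.5) / 8 - 0.5
    sub <- expand.grid(dv = offs, dh = offs)
    r_mm <- sqrt((sub$dv * 0.172)^2 + ((col + sub$dh) * 0.172)^2)
    qsub <- closed_form_q(r_mm, 1000, wl)
    bins <- findInterval(qsub, s$binning$q_edges, rightmost.closed = TRUE)
    if (length(unique(bins)) == 2) {
      counts <- table(bins)
      j <- 1 + col * 2   # column-major pixel index of (row 1, col+1)
      w <- s$W$C[, j]
      nz <- which(w != 0)
      expect_equal(sort(as.integer(names(counts))), sort(nz))
      expect_equal(unname(w[nz]), unname(as.numeric(counts[as.character(nz)]) / 64))
      expect_true(all(w[nz] > 0 & w[nz] < 1))
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("bin areas count pixels: partition of unity and mask decrements", {
  geom <- saxs_geometry(c(16, 16), 700, c(32, 32), c(172, 172))
  s <- make_setup(geom, k = 1)
  expect_equal(sum(s$W$A), 32 * 32)
  mask <- matrix(FALSE, 32, 32); mask[10, 11] <- TRUE
  s2 <- make_setup(geom, mask = mask, k = 1)
  expect_equal(sum(s2$W$A), 32 * 32 - 1)
  # k = 1 areas equal brute-force nearest-bin pixel counts
  qv <- as.vector(s$qmap$q)
  b <- findInterval(qv, s$binning$q_edges, rightmost.closed = TRUE)
  counts <- tabulate(b, nbins = s$binning$n_bins)
  expect_equal(s$W$A, as.numeric(counts))
})

test_that("constant frames integrate to constant curves for any k and mask", {
  withr::with_seed(33, {
    for (k in c(1L, 2L, 4L, 8L)) {
      geom <- rand_geometry(c(48, 48))
      mask <- rand_mask(c(48, 48), 0.1)
      s <- make_setup(geom, mask = mask, k = k)
      cv <- integrate_frame(make_flat_frame(c(48, 48), 7), s$W)
      expect_lt(max(abs(cv$I - 7)) / 7, 1e-9)
      expect_equal(cv$E, sqrt(7 / cv$A))
    }
  })
})

test_that("a single all-covering bin averages a uniform frame exactly", {
  geom <- saxs_geometry(c(0.5, 0.5), 1000, c(2, 2), c(172, 172))
  qm <- build_qmap(geom, 1.54)
  s <- make_setup(geom, step = 1e6, k = 1)
  cv <- integrate_frame(make_flat_frame(c(2, 2), 5), s$W)
  expect_equal(nrow(cv), 1)
  expect_equal(cv$I, 5)
  expect_equal(cv$A, 4)
  expect_equal(cv$E, sqrt(5 / 4))
})

test_that("k = 1 integration equals the per-pixel loop oracle on random frames", {
  withr::with_seed(34, {
    for (i in 1:6) {
      geom <- rand_geometry(c(64, 64), tilted = i %% 2 == 0)
      mask <- if (i > 3) rand_mask(c(64, 64), 0.05) else NULL
      s <- make_setup(geom, mask = mask, step = runif(1, 0.5, 3), k = 1)
      fr <- matrix(rpois(64 * 64, 40), 64, 64)
      got <- integrate_frame(fr, s$W)
      ref <- oracle_integrate(fr, s$qmap, s$binning, mask)
      expect_curves_equal(got, ref, tol = 1e-10)
    }
  })
})

test_that("integrated intensity is conserved for every oversampling factor", {
  withr::with_seed(35, {
    geom <- rand_geometry(c(48, 48))
    mask <- rand_mask(c(48, 48), 0.08)
    fr <- matrix(rpois(48 * 48, 25), 48, 48)
    for (k in c(1L, 2L, 4L, 8L)) {
      s <- make_setup(geom, mask = mask, k = k)
      cv <- integrate_frame(fr, s$W)
      # total counts among unmasked pixels, weighted by in-range coverage
      cs <- Matrix::colSums(s$W$C)
      expect_equal(sum(cv$I * cv$A), sum(as.vector(fr) * cs),
                   tolerance = 1e-9)
      # with full coverage this is exactly the unmasked total
      in_range <- abs(cs - 1) < 1e-12
      if (all(in_range[!as.vector(mask)]))
        expect_equal(sum(cv$I * cv$A), sum(fr[!mask]), tolerance = 1e-9)
    }
  })
})

test_that("masked pixels are opaque: their values never reach the curve", {
  withr::with_seed(36, {
    geom <- rand_geometry(c(32, 32))
    mask <- rand_mask(c(32, 32), 0.1)
    s <- make_setup(geom, mask = mask, k = 2)
    fr <- matrix(rpois(32 * 32, 10), 32, 32)
    cv1 <- integrate_frame(fr, s$W)
    fr2 <- fr
    fr2[mask] <- 99999
    cv2 <- integrate_frame(fr2, s$W)
    expect_identical(cv1$I, cv2$I)
    expect_identical(cv1$E, cv2$E)
  })
})

test_that("negative sentinel counts are excluded per frame", {
  geom <- saxs_geometry(c(16, 16), 700, c(32, 32), c(172, 172))
  s <- make_setup(geom, k = 1)
  fr <- make_flat_frame(c(32, 32), 4)
  fr[3, 3] <- -1  # gap marker
  cv <- integrate_frame(fr, s$W)
  expect_lt(max(abs(cv$I - 4)), 1e-12)       # flat despite the sentinel
  expect_equal(sum(cv$A), 32 * 32 - 1)
  sentinel_mask <- matrix(FALSE, 32, 32); sentinel_mask[3, 3] <- TRUE
  s2 <- make_setup(geom, mask = sentinel_mask, k = 1)
  cv2 <- integrate_frame(make_flat_frame(c(32, 32), 4), s2$W)
  expect_curves_equal(cv, cv2)
})

test_that("frames of the wrong shape or with non-finite counts are rejected", {
  s <- make_setup(saxs_geometry(c(8, 8), 500, c(16, 16), c(172, 172)))
  expect_error(integrate_frame(matrix(0, 8, 8), s$W), "shape")
  bad <- matrix(0, 16, 16); bad[1] <- NaN
  expect_error(integrate_frame(bad, s$W), "finite")
})

test_that("oversampling converges monotonically near the beam center", {
  geom <- saxs_geometry(c(64, 64), 1000, c(128, 128), c(172, 172))
  qm <- build_qmap(geom, 1.54)
  prof <- function(q) 100 * sphere_form_factor(q, 6)
  fr <- make_isotropic_frame(prof, geom, 1.54)
  bn <- build_binning(qm, NULL, 1, geom)
  near <- 2:12   # radial elements near the beam center, where aliasing bites
  curves <- lapply(c(1L, 2L, 4L, 8L, 32L), function(k)
    integrate_frame(fr, build_weight_matrix(qm, bn, NULL, k, geom, 1.54)))
  ref <- curves[[5]]  # heavily oversampled limit of the scheme
  errs <- sapply(curves[1:4], function(cv) max(abs(cv$I[near] - ref$I[near])))
  expect_true(all(diff(errs) < 0))
  # and the k = 8 curve sits much closer to the analytic profile than k = 1
  err_an <- sapply(curves[c(1, 4)], function(cv)
    max(abs(cv$I[near] - prof(cv$q[near]))))
  expect_lt(err_an[2], err_an[1] / 2)
})

test_that("sparsity matches the oversampling bound", {
  withr::with_seed(37, {
    geom <- rand_geometry(c(32, 32))
    mask <- rand_mask(c(32, 32), 0.1)
    n_unmasked <- sum(!mask)
    s1 <- make_setup(geom, mask = mask, k = 1)
    expect_equal(length(s1$W$C@x), n_unmasked)
    s4 <- make_setup(geom, mask = mask, k = 4)
    expect_lte(length(s4$W$C@x), 16 * n_unmasked)
  })
})

test_that("Poisson errors follow sqrt(I/A) with a zero floor", {
  expect_equal(poisson_errors(5, 4), sqrt(5 / 4))
  expect_equal(poisson_errors(5, 4), 1.1180, tolerance = 1e-4)
  expect_equal(poisson_errors(0, 10), 0)
  expect_equal(poisson_errors(c(1, 4, 9), c(1, 4, 9)), c(1, 1, 1))
})

test_that("the Monte-Carlo spread of a bin mean matches the Poisson error", {
  # 2000 frames of iid Poisson(9) pixels through a bin of effective area 100
  geom <- saxs_geometry(c(16, 16), 700, c(32, 32), c(172, 172))
  qm <- build_qmap(geom, 1.54)
  bn <- build_binning(qm, NULL, 4, geom)
  W0 <- build_weight_matrix(qm, bn, NULL, 1, geom, 1.54)
  j <- which(W0$A >= 100)[1]
  pix_in_bin <- which(W0$C[j, ] != 0)[1:100]
  mask <- matrix(TRUE, 32, 32); mask[pix_in_bin] <- FALSE
  W <- build_weight_matrix(qm, bn, mask, 1, geom, 1.54)
  means <- withr::with_seed(101, {
    vapply(1:2000, function(i) {
      fr <- matrix(rpois(32 * 32, 9), 32, 32)
      cv <- integrate_frame(fr, W)
      cv$I[cv$A == 100]
    }, numeric(1))
  })
  expect_equal(sd(means), sqrt(9 / 100), tolerance = 0.05)
})

test_that(".chi files round-trip and keep q strictly increasing", {
  s <- make_setup(saxs_geometry(c(16, 16), 700, c(32, 32), c(172, 172)))
  cv <- integrate_frame(matrix(rpois(32 * 32, 30), 32, 32), s$W)
  f <- withr::local_tempfile(fileext = ".chi")
  write_chi(cv, f, source = "frame_0001.tif")
  back <- read_chi(f)
  expect_curves_equal(cv, back, tol = 1e-10)
  expect_equal(back$E, cv$E, tolerance = 1e-10)
  expect_true(all(diff(back$q) > 0))
  txt <- readLines(f)
  expect_equal(sum(!startsWith(txt, "#")), nrow(cv))
  expect_match(txt[1], "frame_0001.tif")
  # empty curve: header only
  e <- cv[0, ]
  f2 <- withr::local_tempfile(fileext = ".chi")
  write_chi(e, f2)
  expect_equal(nrow(read_chi(f2)), 0)
  expect_true(all(startsWith(readLines(f2), "#")))
})

test_that("curve tidiers and plots expose the reduction result", {
  s <- make_setup(saxs_geometry(c(16, 16), 700, c(32, 32), c(172, 172)))
  cv <- integrate_frame(make_flat_frame(c(32, 32), 3), s$W)
  td <- tidy(cv)
  expect_named(td, c("q", "I", "E", "A"))
  gl <- glance(cv)
  expect_equal(gl$n_points, nrow(cv))
  expect_equal(gl$total_counts, sum(cv$I * cv$A))
  expect_s3_class(autoplot(cv), "ggplot")
})
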