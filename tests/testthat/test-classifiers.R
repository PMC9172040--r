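flat_curve <- function(n = 2001, q1 = 1, q2 = 2, value = 2)
  tibble::tibble(q = seq(q1, q2, length.out = n), I = value)

test_that("classifier integrals are trapezoid-exact on polynomial curves", {
  cv <- flat_curve()
  expect_equal(integral_intensity(cv, 1, 2), 2)
  expect_equal(porod_invariant(cv, 1, 2), 14 / 3, tolerance = 1e-6)
  expect_equal(correlation_length(cv, 1, 2), 9 * pi / 14, tolerance = 1e-6)
  # I(q) = q on [0, 1] at 1001 points
  lin <- tibble::tibble(q = seq(0, 1, length.out = 1001),
                        I = seq(0, 1, length.out = 1001))
  expect_equal(integral_intensity(lin, 0, 1), 0.5, tolerance = 1e-6)
  # I(q) = 1/q^2 on [1, 2], dense sampling
  inv2 <- tibble::tibble(q = seq(1, 2, length.out = 20001))
  inv2$I <- 1 / inv2$q^2
  expect_equal(porod_invariant(inv2, 1, 2), 1.0, tolerance = 1e-4)
})

test_that("classifiers are linear / scale-invariant as appropriate", {
  withr::with_seed(8, {
    cv <- tibble::tibble(q = seq(0.5, 3, length.out = 200),
                         I = runif(200, 0, 10))
    cv3 <- cv; cv3$I <- 3 * cv3$I
    expect_equal(integral_intensity(cv3, 1, 2), 3 * integral_intensity(cv, 1, 2))
    expect_equal(porod_invariant(cv3, 1, 2), 3 * porod_invariant(cv, 1, 2))
    expect_equal(correlation_length(cv3, 1, 2), correlation_length(cv, 1, 2))
  })
})

test_that("degenerate windows and zero curves are flagged as missing", {
  cv <- flat_curve()
  expect_true(is.na(integral_intensity(cv, 5, 6)))   # no points in window
  expect_true(is.na(porod_invariant(cv, 2 - 1e-5, 2)))  # single point
  zero <- flat_curve(value = 0)
  expect_equal(porod_invariant(zero, 1, 2), 0)
  expect_true(is.na(correlation_length(zero, 1, 2)))
  expect_error(integral_intensity(cv, 2, 1), "q1")
})

test_that("classifiers see only the configured window", {
  cv <- tibble::tibble(q = seq(0.2, 4, length.out = 500), I = 1)
  a <- porod_invariant(cv, 1, 2)
  cv2 <- cv
  cv2$I[cv2$q < 1 | cv2$q > 2] <- 1e6   # wild changes outside the window
  expect_equal(porod_invariant(cv2, 1, 2), a)
})

test_that("compute_classifiers composes the three values with the metadata", {
  ms <- saxs_mask_spec(q_start = 1, q_stop = 2)
  t0 <- as.POSIXct("2022-05-01 10:00:00", tz = "UTC")
  rec <- compute_classifiers(flat_curve(), ms, source = "a_00001.tif",
                             acquired_at = t0)
  expect_equal(rec$integral_intensity, 2)
  expect_equal(rec$invariant, 14 / 3, tolerance = 1e-6)
  expect_equal(rec$correlation_length, 9 * pi / 14, tolerance = 1e-6)
  expect_equal(rec$source, "a_00001.tif")
  expect_equal(rec$acquired_at, t0)
  expect_equal(compute_classifiers(flat_curve(), ms, "a_00001.tif", t0), rec)
})

test_that("history stays time-sorted regardless of insertion order", {
  ms <- saxs_mask_spec(q_start = 1, q_stop = 2)
  t0 <- as.POSIXct("2022-05-01 10:00:00", tz = "UTC")
  recs <- lapply(c(3, 1, 4, 2), function(i)
    compute_classifiers(flat_curve(value = i), ms,
                        sprintf("run_%05d.tif", i), t0 + i))
  h1 <- classifier_history(recs)
  h2 <- Reduce(history_add, recs[c(2, 4, 1, 3)], classifier_history())
  expect_equal(tibble::as_tibble(h1), tibble::as_tibble(h2))
  expect_true(!is.unsorted(h1$acquired_at))
})

test_that("history queries filter by data set without mutating", {
  ms <- saxs_mask_spec(q_start = 1, q_stop = 2)
  t0 <- as.POSIXct("2022-05-01 10:00:00", tz = "UTC")
  mk <- function(name, i) compute_classifiers(flat_curve(), ms,
                                              sprintf("%s_%04d.tif", name, i),
                                              t0 + i)
  h <- classifier_history(c(lapply(1:3, mk, name = "lyso"),
                            lapply(4:5, mk, name = "buffer")))
  expect_equal(nrow(query_history(h)), 5)
  expect_equal(nrow(query_history(h, dataset = "lyso")), 3)
  expect_equal(nrow(query_history(h, dataset = "nothing")), 0)
  both <- rbind(query_history(h, dataset = "lyso"),
                query_history(h, dataset = "buffer"))
  expect_equal(nrow(both), nrow(h))
  expect_equal(nrow(h), 5)  # original untouched
  expect_equal(dataset_id("lyso_0001.tif"), "lyso")
  expect_equal(dataset_id("/path/to/run7-123.tiff"), "run7")
})

test_that("history export and import preserve records", {
  ms <- saxs_mask_spec(q_start = 1, q_stop = 2)
  t0 <- as.POSIXct("2022-05-01 10:00:00", tz = "UTC")
  h <- classifier_history(lapply(1:3, function(i)
    compute_classifiers(flat_curve(value = i), ms,
                        sprintf("x_%02d.tif", i), t0 + i)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_history(h, f)
  back <- read_history(f)
  expect_equal(back$source, h$source)
  expect_equal(back$integral_intensity, h$integral_intensity)
  expect_equal(as.numeric(back$acquired_at), as.numeric(h$acquired_at))
  expect_s3_class(autoplot(h), "ggplot")
})
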