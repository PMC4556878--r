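test_that("optical density follows its log-ratio definition", {
  expect_equal(as.numeric(optical_density(100, 100)), 0)
  expect_equal(as.numeric(optical_density(10, 100)), 1)
  expect_equal(as.numeric(optical_density(50, 100)), log10(2))
  # noise can push I above I0; those points clip to zero and are counted
  od <- optical_density(c(120, 80), 100)
  expect_equal(as.numeric(od), c(0, -log10(0.8)))
  expect_equal(attr(od, "n_clipped"), 1L)
  expect_error(optical_density(0, 100), "positive")
  expect_error(optical_density(10, -1), "positive")
  # monotone decreasing in transmitted intensity
  expect_true(all(diff(as.numeric(optical_density(1:100, 100))) < 0))
})

test_that("height is linear in optical density with slope lambda", {
  expect_equal(height_from_od(0, 0.02), 0)
  expect_equal(height_from_od(2.5, 0.02), 0.05)
  expect_equal(height_from_od(1.3, 0.04), 2 * height_from_od(1.3, 0.02))
  expect_error(height_from_od(-1, 0.02), "non-negative")
  expect_error(height_from_od(1, 0), "positive")
})

test_that("noise-free synthetic profiles invert exactly", {
  pr <- synthesize_profile("dome", n = 50, lambda = 0.02, noise_level = 0)
  expect_equal(height_from_od(pr$od, 0.02), pr$h, tolerance = 1e-12)
  fit <- fit_attenuation_length(pr)
  expect_equal(fit$lambda, 0.02, tolerance = 1e-12)
  expect_lt(fit$rms, 1e-12)
  # flat slab: constant intensity, OD pinned at h0 / lambda
  fl <- synthesize_profile("flat", n = 20, h0 = 0.04, lambda = 0.02,
                           noise_level = 0)
  expect_equal(unique(round(fl$I, 9)), fl$I[1])
  expect_equal(fl$od, rep(2, 20), tolerance = 1e-12)
})

test_that("a single informative point determines lambda as the ratio h/OD", {
  pr <- calibration_profile(0, I = 10^(-2.5) * 1000, I0 = 1000, h = 0.05)
  fit <- fit_attenuation_length(pr)
  expect_equal(fit$lambda, 0.05 / 2.5, tolerance = 1e-12)
  expect_equal(unname(coef(fit)), fit$lambda)
})

test_that("lambda is recovered within 3% under 5% intensity noise", {
  pr <- synthesize_profile("plateau_rim", n = 200, lambda = 0.02,
                           noise_level = 0.05, seed = 20260101)
  fit <- fit_attenuation_length(pr)
  expect_lt(abs(fit$lambda - 0.02) / 0.02, 0.03)
  # independent route: the same no-intercept regression via lm
  ref <- unname(coef(lm(h ~ 0 + od, data = as.data.frame(pr))))
  expect_equal(fit$lambda, ref, tolerance = 1e-10)
})

test_that("recovery error grows with the noise level", {
  err_at <- function(noise) {
    mean(vapply(1:5, function(s) {
      f <- fit_attenuation_length(
        synthesize_profile("plateau_rim", n = 200, lambda = 0.02,
                           noise_level = noise, seed = 100 + s))
      abs(f$lambda - 0.02) / 0.02
    }, numeric(1)))
  }
  e0 <- err_at(0)
  e1 <- err_at(0.02)
  e2 <- err_at(0.3)
  expect_equal(e0, 0, tolerance = 1e-12)
  expect_lt(e1, e2)
})

test_that("degenerate profiles are rejected with clear errors", {
  flat0 <- calibration_profile(1:3, I = c(100, 100, 100), I0 = 100,
                               h = c(0, 0, 0))
  expect_error(fit_attenuation_length(flat0), "unidentifiable")
  no_h <- calibration_profile(1:3, I = c(50, 60, 70), I0 = 100)
  expect_error(fit_attenuation_length(no_h), "heights")
  expect_error(calibration_profile(1:3, I = c(1, 2), I0 = 100), "length")
  expect_error(synthesize_profile(noise_level = -0.1), ">= 0")
})

test_that("the synthetic generator is seed-deterministic and leaves the RNG alone", {
  a <- synthesize_profile(noise_level = 0.05, seed = 11)
  b <- synthesize_profile(noise_level = 0.05, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- synthesize_profile(noise_level = 0.05, seed = 12)
  expect_false(identical(a$I, c$I))
  set.seed(42)
  before <- runif(1)
  set.seed(42)
  invisible(synthesize_profile(noise_level = 0.05, seed = 13))
  expect_identical(runif(1), before)
})

test_that("the rimmed colony cross-section shows two OD maxima", {
  pr <- synthesize_profile("plateau_rim", n = 400, noise_level = 0)
  od <- pr$od
  interior <- which(diff(sign(diff(od))) == -2) + 1L
  # strict local maxima away from the plateau flats
  peaks <- interior[od[interior] > max(od) * 0.9]
  expect_equal(length(peaks), 2L)
})

test_that("profiles round-trip through tab-separated text", {
  pr <- synthesize_profile("dome", n = 30, noise_level = 0.05, seed = 3)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_profile(pr, tf)
  back <- read_profile(tf)
  expect_equal(back$I, pr$I, tolerance = 1e-10)
  expect_equal(back$h, pr$h, tolerance = 1e-10)
  expect_equal(fit_attenuation_length(back)$lambda,
               fit_attenuation_length(pr)$lambda, tolerance = 1e-8)
  writeLines("a\tb\n1\t2", tf)
  expect_error(read_profile(tf), "columns")
})

test_that("predict and residuals are consistent with the fitted line", {
  pr <- synthesize_profile("dome", n = 100, lambda = 0.015,
                           noise_level = 0.02, seed = 5)
  fit <- fit_attenuation_length(pr)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(unname(predict(fit, newdata = c(0, 1, 2))),
               c(0, 1, 2) * fit$lambda)
  expect_equal(residuals(fit), pr$h - pr$od * fit$lambda)
})
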