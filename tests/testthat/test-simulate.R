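test_that("trajectories start at the initial condition on a strictly increasing grid", {
  tr <- ref_sim10$trajectory
  init <- ref_sim10$init
  expect_equal(tr$t[1], 0)
  expect_equal(unlist(tr[1, c("L", "f", "S", "S_a")]),
               c(L = init$L, f = init$f, S = init$S, S_a = init$S_a))
  expect_true(all(diff(tr$t) > 0))
  expect_equal(tr$f_bar, 1 - 0.8 - tr$f)
})

test_that("integration is deterministic and invariant-respecting", {
  again <- simulate_biofilm(horizon = 10)
  expect_identical(again$trajectory, ref_sim10$trajectory)
  tr <- ref_sim10$trajectory
  eps_a <- ref_sim10$params$eps_a
  expect_true(all(tr$f >= 0 & tr$f <= 1 - eps_a + 1e-9))
  expect_true(all(diff(tr$L) >= 0))              # thickness never shrinks
  expect_true(all(tr$S >= 0 & tr$S_a >= 0))
  # the agar only drains while it is the richer compartment
  drain <- tr$S_a >= tr$S
  expect_true(all(diff(tr$S_a)[drain[-nrow(tr)]] <= 1e-12))
})

test_that("conserved mass drifts by far less than ten times the relative tolerance", {
  tr <- ref_sim10$trajectory
  drift <- max(abs(tr$conserved_mass - tr$conserved_mass[1])) /
    tr$conserved_mass[1]
  expect_lt(drift, 10 * ref_sim10$settings$rtol)
})

test_that("zero-nutrient initial conditions reduce to pure exponential decay", {
  sim <- simulate_biofilm(init = biofilm_state(S = 0, S_a = 0),
                          horizon = 10)
  tr <- sim$trajectory
  expect_equal(tr$L, rep(tr$L[1], nrow(tr)), tolerance = 1e-12)
  exact <- 0.15 * exp(-0.25 * tr$t)
  expect_lt(max(abs(tr$f - exact) / exact), 1e-6)
})

test_that("halving the tolerances leaves the solution unchanged to well within the looser one", {
  loose <- simulate_biofilm(settings = solver_settings(n_out = 201L))
  tight <- simulate_biofilm(settings = solver_settings(
    rtol = 5e-9, atol = c(f = 5e-13, L = 5e-13, S = 5e-11, S_a = 5e-11),
    n_out = 201L))
  for (v in c("L", "f")) {
    rel <- max(abs(loose$trajectory[[v]] - tight$trajectory[[v]]) /
                 pmax(abs(tight$trajectory[[v]]), 1e-12))
    expect_lt(rel, 1e-6)
  }
})

test_that("the three event detectors locate the reference features", {
  pk <- detect_peak_active_fraction(ref_sim30)
  expect_gt(pk$time, 0.5)
  expect_lt(pk$time, 1.5)
  expect_equal(round(pk$value, 2), 0.19)
  # analytic ceiling from the abundant-nutrient logistic equilibrium
  expect_lte(pk$value,
             quasi_steady_active_fraction(ref_sim30$params) + 1e-6)

  dp <- detect_substrate_depletion(ref_sim10)
  expect_true(dp$detected)
  dp_hi <- detect_substrate_depletion(ref_sim10, threshold_fraction = 0.999)
  expect_lt(dp_hi$time, dp$time)   # laxer threshold crossed earlier

  ss <- detect_steady_state(ref_sim10)
  expect_true(ss$detected)
  expect_equal(round(ss$value, 2), 0.06)
  expect_lte(ss$value, predicted_final_thickness(ref_sim10$params,
                                                 ref_sim10$init))
})

test_that("event detection on a decaying film degenerates to the span start", {
  sim <- simulate_biofilm(init = biofilm_state(S = 0, S_a = 0),
                          horizon = 5)
  expect_equal(detect_peak_active_fraction(sim)$time, 0)
  expect_equal(detect_peak_active_fraction(sim)$value, 0.15)
  expect_equal(detect_substrate_depletion(sim)$time, 0)
  ss <- detect_steady_state(sim)
  expect_equal(ss$time, 0)
  expect_equal(ss$value, 1e-4)
})

test_that("a never-met criterion reports 'not reached' instead of erroring", {
  short <- simulate_biofilm(settings = solver_settings(tspan = c(0, 0.1)))
  dp <- detect_substrate_depletion(short)
  expect_false(dp$detected)
  expect_true(is.na(dp$time))
  ss <- detect_steady_state(short, rel_rate_tol = 1e-12)
  expect_false(ss$detected)
})

test_that("event times are grid-independent because detection interpolates", {
  coarse <- simulate_biofilm(settings = solver_settings(n_out = 501L,
                                                        tspan = c(0, 10)))
  fine <- simulate_biofilm(settings = solver_settings(n_out = 1001L,
                                                      tspan = c(0, 10)))
  for (det in list(detect_peak_active_fraction, detect_substrate_depletion,
                   detect_steady_state)) {
    t1 <- det(coarse)$time
    t2 <- det(fine)$time
    expect_lt(abs(t1 - t2) / t2, 0.01)
  }
})

test_that("trajectory and run-summary exports are faithful plain text", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(ref_sim10, tf)
  back <- utils::read.table(tf, header = TRUE, sep = "\t")
  expect_equal(names(back),
               c("t", "L", "f", "f_bar", "S", "S_a", "conserved_mass"))
  expect_equal(back$L, ref_sim10$trajectory$L, tolerance = 1e-12)

  ts <- withr::local_tempfile(fileext = ".txt")
  write_run_summary(ref_sim10, ts)
  txt <- readLines(ts)
  expect_true(any(grepl("steady_state_reached", txt)))
  expect_true(any(grepl("rtol", txt)))
})

test_that("solver settings reject impossible requests", {
  expect_error(solver_settings(rtol = 0), "positive")
  expect_error(solver_settings(tspan = c(5, 1)), "start < end")
  expect_error(simulate_biofilm(horizon = -1), "horizon")
})
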