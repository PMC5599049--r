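test_that("sweeps record survival fractions and validate their inputs", {
  sys <- cistrome_preset("tiny_single")
  sw <- sweep_m(sys, "TfA", m_values = 1:4, n_runs = 60, timesteps = 200,
                seed = 1)
  expect_equal(sw$result$m, 1:4)
  expect_true(all(sw$result$survival_fraction >= 0 &
                    sw$result$survival_fraction <= 1))
  expect_equal(sw$result$survival_fraction[1], 0)
  expect_error(sweep_m(sys, "TfZ", 1:3), "target")
  expect_error(sweep_m(cistrome_preset("tiny_coupled"), "TfA", 1:3,
                       held = list(list(cistrome = "TfA", m = 2))),
               "distinct")
})

test_that("m = 0 gives survival fraction exactly zero", {
  sys <- cistrome_preset("tiny_single")
  sw <- sweep_m(sys, "TfA", m_values = c(0, 3), n_runs = 30,
                timesteps = 100, seed = 2)
  expect_equal(sw$result$survival_fraction[sw$result$m == 0], 0)
})

test_that("estimate_mcrit applies its rule and demands bracketing", {
  sys <- cistrome_preset("tiny_single")
  sw <- sweep_m(sys, "TfA", m_values = 1:4, n_runs = 60, timesteps = 200,
                seed = 1)
  est <- estimate_mcrit(sw)
  expect_s3_class(est, "criticality_estimate")
  expect_equal(est$m_crit, 3L)  # p/r = 2; noise pushes the integer value to 3
  # the fraction rule can only be more demanding
  est50 <- estimate_mcrit(sw, rule = "fraction", threshold = 0.5)
  expect_gte(est50$m_crit, est$m_crit)
  # all-zero and all-positive sweeps are errors, not guesses
  dead <- sweep_m(sys, "TfA", m_values = 1:2, n_runs = 30, timesteps = 150,
                  seed = 1)
  expect_error(estimate_mcrit(dead), "bracket")
  alive <- sweep_m(sys, "TfA", m_values = 4:5, n_runs = 30, timesteps = 150,
                   seed = 1)
  expect_error(estimate_mcrit(alive), "bracket")
})

test_that("the observed critical value is at least ceil(p/r)", {
  for (preset in c("tiny_single", "tiny_coupled")) {
    sys <- cistrome_preset(preset)
    nm <- sys$names[1]
    mcrit <- quick_mcrit(subset_system(sys, nm), nm, 1:6)
    expect_gte(mcrit, ceiling(sys$p[[nm]] / sys$r[[nm]]))
  }
})

test_that("m_crit is unchanged by s0 = r versus s0 = floor(r/2)", {
  sys <- cistrome_preset("tiny_single")
  full <- quick_mcrit(sys, "TfA", 1:6, n_runs = 150)
  half <- quick_mcrit(sys, "TfA", 1:6, n_runs = 150, s0_target = 10)
  expect_equal(half, full)
})

test_that("scaling (p, r) by 10 moves m_crit toward, never past, ceil(p/r)", {
  # with p/r fixed the infinite-limit value is unchanged; finite-size noise
  # raises the observed value above it, and that noise excess can only
  # shrink as the system grows (extinction at marginal m takes longer in
  # larger systems), so ceil(p/r) <= m_crit(10x) <= m_crit(1x)
  small <- cistrome_system(list(cistrome("TfA", 40, 20)))
  big <- cistrome_system(list(cistrome("TfA", 400, 200)))
  m_small <- quick_mcrit(small, "TfA", 1:6, n_runs = 150)
  m_big <- quick_mcrit(big, "TfA", 1:6, n_runs = 150)
  expect_lte(m_big, m_small)
  expect_gte(m_big, 2L)  # ceil(p/r)
})

test_that("ignition requires a transfer path: sigma = 0 never activates", {
  sys <- cistrome_system(list(cistrome("TfA", 40, 20),
                              cistrome("TfB", 30, 15)))
  ig <- ignition_experiment(sys, driver = list(cistrome = "TfA", m = 4),
                            driven = list(cistrome = "TfB", m = 4),
                            timesteps = 200, n_runs = 40, seed = 3)
  expect_equal(ig$fraction_ignited, 0)
  expect_true(all(is.na(ig$runs$time_to_ignition)))
})

test_that("a supercritical driver ignites a dissipated coupled partner", {
  ig <- ignition_experiment(cistrome_preset("tiny_coupled"),
                            driver = list(cistrome = "TfA", m = 4),
                            driven = list(cistrome = "TfB", m = 4),
                            timesteps = 300, n_runs = 60, seed = 4)
  expect_gt(ig$fraction_ignited, 0.9)
  expect_gt(ig$fraction_survived, 0.5)
  expect_lt(ig$median_time_to_ignition, 25)
})

test_that("coupling to a partner at its critical value lowers m_crit", {
  # the overlap must be large enough that the held partner genuinely
  # sacrifices its own production (own term m (r - sigma) / p < 1), as in
  # the ESC systems; otherwise the driven cistrome can never dissipate and
  # no coupled critical value exists
  nms <- c("TfA", "TfB")
  sig <- matrix(c(0L, 10L, 10L, 0L), 2, 2, dimnames = list(nms, nms))
  sys <- cistrome_system(list(cistrome("TfA", 40, 20),
                              cistrome("TfB", 30, 15)), sigma = sig)
  alone <- quick_mcrit(subset_system(sys, "TfB"), "TfB", 1:6, n_runs = 150)
  cr <- coupling_reduction(sys, "TfB",
                           partners = list(list(cistrome = "TfA", m = 3)),
                           m_values = 0:6, uncoupled_mcrit = alone,
                           n_runs = 150, timesteps = 300, seed = 5,
                           stop_at_first_survivor = TRUE)
  expect_lte(cr$coupled_mcrit, alone)
  expect_equal(cr$reduction, alone - cr$coupled_mcrit)
})

test_that("sweep results are reproducible byte-for-byte given the seed", {
  sys <- cistrome_preset("tiny_coupled")
  sw1 <- sweep_m(sys, "TfA", 1:4, n_runs = 50, timesteps = 150, seed = 11)
  sw2 <- sweep_m(sys, "TfA", 1:4, n_runs = 50, timesteps = 150, seed = 11)
  expect_identical(sw1$result, sw2$result)
})
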