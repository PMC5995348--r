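# Protocol integration, respirometry observables, mass-balance audits.

test_that("an event-free run keeps the oxygen trace flat", {
  sim <- simulate_protocol(default_model(), NULL, t_end = 10,
                           conditions = cond23())
  o2 <- sim$trajectory$O2.e
  expect_lt(abs(o2[length(o2)] / o2[1] - 1), 0.01)
})

test_that("ADP elicits state 3 and the canonical state-2/3/4 ordering", {
  s <- respiration_summary(sim_pm())
  expect_true(s$adp_depleted)
  expect_gt(s$ocr_state3, s$ocr_state2)
  expect_gt(s$ocr_state3, s$ocr_state4)
  expect_gt(s$rci_s3_s4, 1)   # coupled preparation
  expect_gt(s$rci_s3_s2, 1)
  expect_gt(s$state3_duration, 0.5)
  expect_lt(s$state3_duration, 3)
})

test_that("membrane potential dips on ADP addition and recovers after depletion", {
  tr <- sim_pm()$trajectory
  psi_s2 <- tr$dPsi[which.min(abs(tr$time - 3.4))]
  psi_s3 <- min(tr$dPsi[tr$time > 3.5 & tr$time < 5])
  psi_s4 <- tr$dPsi[which.min(abs(tr$time - 9.5))]
  expect_lt(psi_s3, psi_s2 - 10)
  expect_gt(psi_s4, psi_s3 + 10)
})

test_that("a larger ADP dose gives a longer state 3", {
  s_low <- respiration_summary(simulate_protocol(
    default_model(), pm_events(adp = 0.05), t_end = 10,
    conditions = cond23()))
  s_high <- respiration_summary(sim_pm())
  expect_gt(s_high$state3_duration, s_low$state3_duration)
})

test_that("ADP is consumed faster at higher temperature", {
  durs <- vapply(c(25, 35), function(TC) {
    respiration_summary(simulate_protocol(
      default_model(), pm_events(), t_end = 10,
      conditions = protocol_conditions(temperature_C = TC,
                                       leak_scale = 0.4)))$state3_duration
  }, 0)
  expect_lt(durs[2], durs[1])
})

test_that("buffer oxygen is non-increasing while complex IV runs forward", {
  sim <- sim_pm()
  civ_fwd <- sim$fluxes$CIV >= 0
  do2 <- diff(sim$trajectory$O2.e)
  expect_true(all(do2[civ_fwd[-1]] <= 1e-12))
})

test_that("buffer pyruvate depletion equals the integrated carrier flux", {
  # audit window avoids the stiff post-addition transient so composite
  # Simpson quadrature of the saved flux trace is accurate to < 1e-6
  sim <- simulate_protocol(
    default_model(),
    respirometry_events(c(PYR = 5, MAL = 5), substrate_time = 0, adp = NULL),
    t_end = 3, conditions = cond30(), dt = 0.0025)
  tr <- sim$trajectory
  fac <- 1e-3 * 1e6 / 0.7   # buffer nmol per mg per mM
  sel <- tr$time >= 0.25
  i <- which(sel)
  if (length(i) %% 2 == 0) i <- i[-1]  # Simpson needs an odd point count
  consumed <- (tr$PYR.e[i[1]] - tr$PYR.e[i[length(i)]]) * fac
  J <- sim$fluxes$PYRH[i]
  h <- diff(tr$time[i])[1]
  n <- length(i)
  transported <- h / 3 * (J[1] + J[n] + 4 * sum(J[seq(2, n - 1, by = 2)]) +
                          2 * sum(J[seq(3, n - 2, by = 2)]))
  expect_equal(consumed, transported, tolerance = 1e-6)
})

test_that("conserved pools stay constant along a 10-minute trajectory", {
  sim <- sim_fig2()
  m <- default_model()
  tr <- sim$trajectory
  p0 <- check_conservation_pools(state_at(sim, 0.01), m, 1e-3, 0.7)
  p1 <- check_conservation_pools(state_at(sim, 10), m, 1e-3, 0.7)
  expect_equal(p1, p0, tolerance = 1e-6)
  # concentrations remain (numerically) nonnegative
  expect_gt(min(as.matrix(tr[, 2:38])), -1e-12)
})

test_that("OCR is the sign-flipped slope of the buffer oxygen amount", {
  sim <- sim_pm()
  # synthetic linear trace: slope -5 nmol/min in 0.55 mg -> 9.09 nmol/min/mg
  fake <- sim
  vol_nmol_per_mM <- 0.55e-3 * 1e6
  fake$trajectory$O2.e <- 0.25 - 5 / vol_nmol_per_mM * fake$trajectory$time
  expect_equal(compute_ocr(fake, c(1, 3)), 5 / 0.55, tolerance = 1e-9)
  # flat trace -> 0
  fake$trajectory$O2.e <- 0.2
  expect_equal(compute_ocr(fake, c(1, 3)), 0, tolerance = 1e-12)
  expect_error(compute_ocr(sim, c(1, 1.005)), "3 grid points")
})

test_that("succinate drives faster respiration than pyruvate+malate", {
  s_pm <- respiration_summary(sim_pm())
  s_suc <- respiration_summary(sim_suc())
  expect_gt(s_suc$ocr_state2, s_pm$ocr_state2)
  expect_gt(s_suc$ocr_state3, s_pm$ocr_state3)
  expect_gt(s_suc$ocr_state4, s_pm$ocr_state4)
})

test_that("raising the proton leak lowers the respiratory control index", {
  rcis <- vapply(c(0.4, 1.7), function(ls) {
    respiration_summary(simulate_protocol(
      default_model(), pm_events(), t_end = 10,
      conditions = cond23(ls)))$rci_s3_s2
  }, 0)
  expect_lt(rcis[2], rcis[1])
})

test_that("halving solver tolerances leaves reported OCRs unchanged to 0.1%", {
  s1 <- respiration_summary(sim_pm())
  sim2 <- simulate_protocol(default_model(), pm_events(), t_end = 10,
                            conditions = cond23(),
                            solver_opts = list(rtol = 5e-9, atol = 5e-11))
  s2 <- respiration_summary(sim2)
  for (col in c("ocr_state2", "ocr_state3", "ocr_state4"))
    expect_equal(s2[[col]], s1[[col]], tolerance = 1e-3)
})

test_that("simulations are deterministic and events are validated", {
  a <- simulate_protocol(default_model(), pm_events(), 5, cond23())
  b <- simulate_protocol(default_model(), pm_events(), 5, cond23())
  expect_identical(a$trajectory, b$trajectory)
  bad <- pm_events(); bad$time <- rev(bad$time)
  expect_error(simulate_protocol(default_model(), bad, 5, cond23()))
  expect_error(respiration_summary(simulate_protocol(
    default_model(), respirometry_events(c(PYR = 10), adp = NULL), 2,
    cond23())), "no ADP event")
})
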