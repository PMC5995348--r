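# Generalized thermodynamically-constrained flux law, pH/temperature
# corrections, and GHK electrodiffusion.

test_that("flux vanishes exactly at the Haldane equilibrium for randomized specs", {
  set.seed(11)
  for (i in 1:25) {
    spec <- random_flux_spec(ns = sample(1:3, 1), np = sample(1:2, 1),
                             pair = i %% 2 == 0)
    conc <- rand_conc(spec)
    # scale the first product so the reaction quotient equals Keq exactly
    keq <- spec$keq0
    p1 <- spec$products$species[1]
    b1 <- spec$products$coef[1]
    conc[p1] <- conc[p1] * (keq / quotient(spec, conc))^(1 / b1)
    expect_equal(quotient(spec, conc), keq, tolerance = 1e-10)
    expect_equal(general_flux(spec, conc, keq), 0, tolerance = 1e-12)
  }
})

test_that("flux sign follows the displacement from equilibrium and is monotone", {
  set.seed(12)
  for (i in 1:20) {
    spec <- random_flux_spec(ns = 2, np = 2)
    conc <- rand_conc(spec)
    keq <- spec$keq0
    J <- general_flux(spec, conc, keq)
    expect_identical(J > 0, quotient(spec, conc) < keq)
    # increasing a substrate increases flux; increasing a product decreases it
    up_s <- conc; up_s[spec$substrates$species[1]] <- up_s[spec$substrates$species[1]] * 1.3
    up_p <- conc; up_p[spec$products$species[1]] <- up_p[spec$products$species[1]] * 1.3
    expect_gt(general_flux(spec, up_s, keq), J)
    expect_lt(general_flux(spec, up_p, keq), J)
  }
})

test_that("saturating substrates with no products drive the flux to Vmaxf", {
  spec <- flux_spec("sat", "reaction",
                    data.frame(species = c("A", "B"), coef = 1, K = c(0.2, 0.5)),
                    data.frame(species = "C", coef = 1, K = 1),
                    vmax = 12.5, keq0 = 1e6)
  conc <- c(A = 0.2 * 1e4, B = 0.5 * 1e4, C = 0)
  expect_equal(general_flux(spec, conc, 1e6), 12.5, tolerance = 1e-3)
})

test_that("1-substrate/1-product law matches an independent reversible MM oracle", {
  # independent closed form: V/Ks (S - P/Keq) / ((1+S/Ks)(1+P/Kp))
  rev_mm <- function(S, P, V, Ks, Kp, Keq) {
    V / Ks * (S - P / Keq) / ((1 + S / Ks) * (1 + P / Kp))
  }
  spec <- flux_spec("mm", "reaction",
                    data.frame(species = "S", coef = 1, K = 0.35),
                    data.frame(species = "P", coef = 1, K = 1.4),
                    vmax = 7.3, keq0 = 4.2)
  grid <- expand.grid(S = seq(0.01, 5, length.out = 10),
                      P = seq(0, 4, length.out = 10))
  for (i in seq_len(nrow(grid))) {
    expect_equal(general_flux(spec, c(S = grid$S[i], P = grid$P[i]), 4.2),
                 rev_mm(grid$S[i], grid$P[i], 7.3, 0.35, 1.4, 4.2),
                 tolerance = 1e-12)
  }
})

test_that("cofactor-pair members are omitted from the denominator", {
  base <- list(substrates = data.frame(species = c("S", "NAD"), coef = 1,
                                       K = c(0.5, 0.1)),
               products = data.frame(species = c("P", "NADH"), coef = 1,
                                     K = c(1, 0.2)))
  paired <- flux_spec("p", "reaction", base$substrates, base$products,
                      vmax = 5, keq0 = 10,
                      cofactor_pairs = list(c("NAD", "NADH")))
  conc <- c(S = 1, NAD = 0.8, P = 0.5, NADH = 0.4)
  # hand-built expectation: NAD/NADH terms absent from the denominator
  num <- 5 / (0.5 * 0.1) * (1 * 0.8 - 0.5 * 0.4 / 10)
  expect_equal(general_flux(paired, conc, 10),
               num / ((1 + 1 / 0.5) * (1 + 0.5 / 1)), tolerance = 1e-12)
})

test_that("flux spec validation rejects bad input", {
  good_s <- data.frame(species = "S", coef = 1, K = 0.5)
  good_p <- data.frame(species = "P", coef = 1, K = 1)
  expect_error(flux_spec("x", "reaction", transform(good_s, K = -1), good_p,
                         vmax = 1, keq0 = 1), "binding constants")
  expect_error(flux_spec("x", "reaction", transform(good_s, coef = 0.5),
                         good_p, vmax = 1, keq0 = 1), "positive integers")
  expect_error(flux_spec("x", "reaction", good_s, good_p, vmax = 1,
                         keq0 = 1, cofactor_pairs = list(c("A", "P"))),
               "cofactor pair")
  spec <- flux_spec("x", "reaction", good_s, good_p, vmax = 1, keq0 = 1)
  expect_error(general_flux(spec, c(S = 1), 1), "unknown species")
  expect_error(general_flux(spec, c(S = 1, P = 1), -2), "keq_apparent")
})

test_that("apparent Keq follows the pH conventions", {
  mk <- function(conv) flux_spec("k", "reaction",
                                 data.frame(species = "S", coef = 1, K = 1),
                                 data.frame(species = "P", coef = 1, K = 1),
                                 vmax = 1, keq0 = 3.7,
                                 proton_convention = conv)
  at_ph <- function(conv, pH, side = "matrix")
    apparent_keq(mk(conv), thermo_ctx(pH_matrix = pH, pH_buffer = pH), side)
  expect_identical(at_ph("releasing", 7), 3.7)
  expect_identical(at_ph("consuming", 7), 3.7)
  expect_identical(at_ph("neutral", 7.8), 3.7)
  expect_equal(at_ph("releasing", 7.4), 3.7 * 10^0.4, tolerance = 1e-12)
  expect_equal(at_ph("consuming", 6.6), 3.7 * 10^0.4, tolerance = 1e-12)
  # the compartment's pH is the one that applies
  ctx <- thermo_ctx(pH_matrix = 7.5, pH_buffer = 7.0)
  expect_equal(apparent_keq(mk("releasing"), ctx, "buffer"), 3.7)
})

test_that("Q10 scaling matches its definition and composes", {
  ctx <- thermo_ctx(reference_temperature = 303.15, Q10 = 2.5)
  expect_identical(q10_correction(ctx, 303.15), 1)
  expect_equal(q10_correction(ctx, 313.15), 2.5, tolerance = 1e-12)
  expect_equal(q10_correction(ctx, 296.15), 2.5^(-0.7), tolerance = 1e-12)
  # composition: scaling T1->T2 then T2->T3 equals T1->T3
  ctx2 <- thermo_ctx(reference_temperature = 296.15, Q10 = 2.5)
  expect_equal(q10_correction(ctx, 296.15) * q10_correction(ctx2, 310),
               q10_correction(ctx, 310), tolerance = 1e-12)
})

test_that("GHK flux has the Fick limit, the Nernst zero, and antisymmetry", {
  ctx <- thermo_ctx(temperature = 296.15)
  # Fick limit at vanishing potential
  expect_equal(ghk_cation_flux(0, 2e-7, 5e-8, p = 1.38, ctx = ctx),
               1.38 * (2e-7 - 5e-8), tolerance = 1e-10)
  expect_equal(ghk_cation_flux(1e-9, 2e-7, 5e-8, p = 1.38, ctx = ctx),
               1.38 * (2e-7 - 5e-8), tolerance = 1e-6)
  # Nernst equilibrium: C_in/C_out = e^w gives zero flux
  w <- 96485.33212 * 0.120 / (8.314462618 * 296.15)
  expect_equal(ghk_cation_flux(120, 1e-7, 1e-7 * exp(w), p = 2, ctx = ctx),
               0, tolerance = 1e-10 * 2 * 1e-7)
  # antisymmetry J(dPsi, a, b) = -J(-dPsi, b, a)
  set.seed(3)
  for (i in 1:10) {
    a <- stats::runif(1); b <- stats::runif(1); v <- stats::runif(1, -200, 200)
    expect_equal(ghk_cation_flux(v, a, b, p = 1, ctx = ctx),
                 -ghk_cation_flux(-v, b, a, p = 1, ctx = ctx),
                 tolerance = 1e-12 * max(a, b))
  }
})

test_that("GHK uptake value matches an independent evaluation of the formula", {
  # z = 1, 140 mV, 296.15 K, C_out = 200 nM, C_in = 0, p = 1.38
  ctx <- thermo_ctx(temperature = 296.15)
  w <- 96485.33212 * 0.140 / (8.314462618 * 296.15)
  oracle <- 1.38 * w * 2e-7 * exp(w) / (exp(w) - 1)
  got <- ghk_cation_flux(140, 2e-7, 0, p = 1.38, z = 1, ctx = ctx)
  expect_gt(got, 0)  # uptake-positive
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("proton leak has no flux without a driving force and scales linearly", {
  ctx <- thermo_ctx(temperature = 296.15)
  lk <- leak_spec(36, 0.4)
  expect_equal(proton_leak_flux(lk, 0, 1e-7, 1e-7, ctx), 0, tolerance = 1e-15)
  J1 <- proton_leak_flux(lk, 150, 6.3e-8, 5e-8, ctx)
  J2 <- proton_leak_flux(leak_spec(36, 0.8), 150, 6.3e-8, 5e-8, ctx)
  expect_equal(J2, 2 * J1, tolerance = 1e-12)
  # monotone increasing in deltaPsi
  psi <- seq(-50, 200, by = 10)
  Js <- vapply(psi, function(v) proton_leak_flux(lk, v, 6.3e-8, 5e-8, ctx), 0)
  expect_true(all(diff(Js) > 0))
})
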