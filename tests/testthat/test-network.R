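# Network assembly, parameterization, conserved pools, engines.

test_that("the default model carries the published extrinsic rates", {
  m <- default_model()
  expect_equal(m$params$Tmaxf_LEAK, 36)
  expect_equal(m$params$Vmaxf_PDH, 307)
  expect_equal(m$params$Tmaxf_ANT, 523.9)
  expect_length(m$fluxes, 24)  # 15 reactions + 9 carriers; leak separate
  expect_equal(m$leak$Tmaxf_leak, 36)
  # 37 metabolite states + 2 H+ + deltaPsi handled by the simulator
  expect_equal(nrow(m$species), 37)
})

test_that("parameter overrides apply last and unknown names error", {
  m <- build_lung_model(list(Tmaxf_LEAK = 36 * 0.40))
  expect_equal(m$leak$Tmaxf_leak, 14.4)
  expect_error(build_lung_model(list(Tmaxf_LEEK = 1)), "unknown parameter")
})

test_that("content converts to concentration through the 1 ul/mg volume", {
  expect_identical(content_to_concentration(1.73), 1.73)
  expect_identical(content_to_concentration(6.4), 6.4)
  expect_identical(content_to_concentration(0), 0)
  expect_error(content_to_concentration(-1), "nonnegative")
})

test_that("stoichiometric matrix closes every conserved pool", {
  m <- default_model()
  S <- stoichiometric_matrix(m)
  Sm <- as.matrix(S[-1]); rownames(Sm) <- S$state
  for (pool in m$pools) {
    expect_equal(unname(colSums(Sm[pool, , drop = FALSE])),
                 rep(0, ncol(Sm)), tolerance = 1e-12)
  }
})

test_that("initial pools equal the published totals and drift is detected", {
  m <- default_model()
  y0 <- stats::setNames(m$species$initial, m$species$state)
  pools <- check_conservation_pools(y0, m)
  expect_equal(unname(pools["pyridine"]), 1.73)
  expect_equal(unname(pools["flavin"]), 0.7)
  expect_equal(unname(pools["adenine"]), 6.4)
  expect_equal(unname(pools["coenzymeA"]), 0.93)
  expect_equal(unname(pools["cytochrome_c"]), 0.33)
  expect_equal(unname(pools["ubiquinone"]), 0.52)
  expect_equal(unname(pools["asp_glu"]), 12)
  # negative control: NADH bumped without NAD compensation shows up
  y_bad <- y0; y_bad["NADH.m"] <- y_bad["NADH.m"] + 0.05
  expect_equal(unname(check_conservation_pools(y_bad, m)["pyridine"]), 1.78)
})

test_that("compiled and reference engines agree at randomized states", {
  m <- default_model()
  comp <- lungmito:::compile_network(m, temperature = 296.15, pH_buffer = 7.2,
                                     buffer_volume_l = 0.55e-3,
                                     protein_mg = 0.55, leak_scale = 0.4)
  eng <- lungmito:::make_rhs(comp, "compiled")
  y0 <- lungmito:::initial_state(m, protocol_conditions())
  set.seed(21)
  for (i in 1:10) {
    y <- y0 * stats::runif(length(y0), 0.5, 2)
    y[length(y)] <- stats::runif(1, 20, 190)  # deltaPsi
    Jr <- lungmito:::eval_network_fluxes(comp, y)
    Jc <- eng$fluxes(y)
    expect_equal(Jc, Jr, tolerance = 1e-10)
    dr <- lungmito:::network_rhs_r(0, y, comp)[[1]]
    dc <- eng$rhs(0, y, NULL)[[1]]
    expect_equal(dc, dr, tolerance = 1e-10)
  }
})

test_that("pool closure holds analytically in the assembled RHS", {
  # d/dt of each conserved pool is exactly zero at arbitrary states
  m <- default_model()
  comp <- lungmito:::compile_network(m, 303.15, 7.4, 1e-3, 0.7, 1)
  y0 <- lungmito:::initial_state(m, cond30())
  fac <- c(matrix = 1, ims = 0.1, buffer = 1e-3 * 1e6 / 0.7)
  w <- stats::setNames(fac[m$species$compartment], m$species$state)
  set.seed(22)
  for (i in 1:5) {
    y <- y0 * stats::runif(length(y0), 0.5, 2)
    dy <- lungmito:::network_rhs_r(0, y, comp)[[1]]
    names(dy) <- names(y0)
    for (pool in m$pools)
      expect_equal(sum(dy[pool] * w[pool]), 0, tolerance = 1e-10)
  }
})
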