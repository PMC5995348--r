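# Fitting objective, GA, intrinsic least squares, identifiability metrics.

test_that("the objective is zero when model solutions equal the data", {
  f <- objective(list(), list(ds_cheap()))
  expect_lt(f, 1e-12)
})

test_that("the objective matches its closed form on scaled observations", {
  # scaling all observations by 1/(1+d) makes every relative residual d,
  # so f = sum_j d_j^2 regardless of the trace values
  tight <- list(rtol = 1e-8, atol = 1e-10)  # match the generator's solver
  d1 <- 0.10; d2 <- -0.05
  a <- ds_cheap(); b <- ds_cheap()
  a$data$value <- a$data$value / (1 + d1)
  b$data$value <- b$data$value / (1 + d2)
  f <- objective(list(), list(a, b), solver_opts = tight)
  expect_equal(f, d1^2 + d2^2, tolerance = 1e-6)
  # one observation, model = 2 * data -> f = 1
  one <- ds_cheap()
  one$data <- one$data[3, ]
  one$data$value <- one$data$value / 2
  expect_equal(objective(list(), list(one), solver_opts = tight), 1,
               tolerance = 1e-6)
})

test_that("zero-valued observations are excluded with a warning", {
  a <- ds_cheap()
  a$data$value[2] <- 0
  expect_warning(f <- objective(list(), list(a)), "zero-valued")
  expect_lt(f, 1e-12)
})

test_that("the objective is invariant to dataset ordering", {
  a <- ds_noisy(); b <- ds_cheap()
  expect_equal(objective(list(), list(a, b)), objective(list(), list(b, a)),
               tolerance = 1e-14)
})

test_that("normalized sensitivity reproduces closed forms", {
  th <- c(a = 2, b = 0.5)
  S2 <- sensitivity_coefficients(th, fun = function(t) t[["a"]]^2 + 0 * t[["b"]])
  expect_equal(S2$S[S2$parameter == "a"], 2, tolerance = 1e-6)
  expect_equal(S2$S[S2$parameter == "b"], 0, tolerance = 1e-9)
  # delta-robustness on a smooth function: S at 0.05% and 0.2% agree
  cube <- function(t) t[["a"]]^3 * t[["b"]]
  Sa <- sensitivity_coefficients(th, fun = cube, delta = 5e-4)
  Sb <- sensitivity_coefficients(th, fun = cube, delta = 2e-3)
  expect_equal(Sa$S, Sb$S, tolerance = 0.05)
  expect_equal(Sa$S[Sa$parameter == "a"], 3, tolerance = 1e-5)
})

test_that("a carrier absent from the protocol has near-zero sensitivity", {
  th <- unlist(lung_model_params()[c("Tmaxf_LEAK", "Tmaxf_GLUH")])
  S <- sensitivity_coefficients(th, list(ds_noisy()))
  s_leak <- abs(S$S[S$parameter == "Tmaxf_LEAK"])
  s_gluh <- abs(S$S[S$parameter == "Tmaxf_GLUH"])
  expect_lt(s_gluh, 0.05 * s_leak)  # no glutamate anywhere in the protocol
})

test_that("the correlation matrix is a valid correlation matrix", {
  th <- unlist(lung_model_params()[c("Tmaxf_LEAK", "Vmaxf_CI")])
  CC <- correlation_matrix(th, list(ds_noisy()))
  expect_equal(unname(diag(CC)), c(1, 1))
  expect_equal(CC, t(CC))
  expect_true(all(abs(CC) <= 1))
})

test_that("intrinsic least squares recovers binding constants", {
  tmpl <- flux_spec("iso", "reaction",
                    data.frame(species = "S", coef = 1, K = 1),
                    data.frame(species = "P", coef = 1, K = 2),
                    vmax = 10, keq0 = 8)
  truth <- flux_spec("iso", "reaction",
                     data.frame(species = "S", coef = 1, K = 0.42),
                     data.frame(species = "P", coef = 1, K = 1.3),
                     vmax = 6.5, keq0 = 8)
  grid <- expand.grid(S = c(0.05, 0.1, 0.25, 0.5, 1, 2, 5),
                      P = c(0, 0.5, 2))
  rate <- vapply(seq_len(nrow(grid)), function(i)
    general_flux(truth, c(S = grid$S[i], P = grid$P[i]), 8), 0)
  ds <- mito_dataset("iso", "enzyme_kinetics",
                     cbind(grid, rate = rate))
  fit <- fit_intrinsic_ls(ds, tmpl)
  expect_equal(unname(fit$K["S"]), 0.42, tolerance = 1e-6)
  expect_equal(unname(fit$K["P"]), 1.3, tolerance = 1e-6)
  expect_equal(fit$vmax, 6.5, tolerance = 1e-6)
})

test_that("intrinsic least squares tolerates 5% noise at n = 50", {
  truth <- flux_spec("iso", "reaction",
                     data.frame(species = "S", coef = 1, K = 0.42),
                     data.frame(species = "P", coef = 1, K = 2),
                     vmax = 6.5, keq0 = 1e6)
  set.seed(31)
  S <- stats::runif(50, 0.02, 5)
  rate <- vapply(S, function(s) general_flux(truth, c(S = s, P = 0), 1e6), 0)
  rate <- rate * (1 + stats::rnorm(50, 0, 0.05))
  ds <- mito_dataset("iso", "enzyme_kinetics", data.frame(S = S, rate = rate))
  tmpl <- truth; tmpl$substrates$K <- 1; tmpl$vmax <- 10
  fit <- fit_intrinsic_ls(ds, tmpl, fit_constants = "S")
  expect_lt(abs(fit$K[["S"]] / 0.42 - 1), 0.15)
})

test_that("a flat design is rejected as non-identifiable", {
  tmpl <- flux_spec("iso", "reaction",
                    data.frame(species = "S", coef = 1, K = 1),
                    data.frame(species = "P", coef = 1, K = 2),
                    vmax = 10, keq0 = 8)
  flat <- mito_dataset("flat", "enzyme_kinetics",
                       data.frame(S = rep(1, 8), rate = rep(3, 8)))
  expect_error(fit_intrinsic_ls(flat, tmpl), "non-identifiable")
})

test_that("the genetic algorithm is seeded-deterministic and improves", {
  opts <- list(pop_size = 8, generations = 3, polish = FALSE)
  f1 <- fit_extrinsic_ga(list(ds_noisy()), bounds = c(0.5, 2),
                         params_to_fit = "Tmaxf_LEAK", ga_opts = opts,
                         seed = 99)
  f2 <- fit_extrinsic_ga(list(ds_noisy()), bounds = c(0.5, 2),
                         params_to_fit = "Tmaxf_LEAK", ga_opts = opts,
                         seed = 99)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$objective, f2$objective)
  expect_lte(f1$objective, f1$initial_best)
  # broom-style accessors
  td <- tidy(f1)
  expect_identical(td$term, "Tmaxf_LEAK")
  expect_true(all(c("estimate", "lower", "upper") %in% names(td)))
  gl <- glance(f1)
  expect_identical(gl$seed, 99)
  expect_identical(gl$n_params, 1L)
})
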