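# Parameter estimation: weighted relative-residual objective, seeded genetic
# algorithm for the extrinsic maximal rates, nonlinear least squares for
# intrinsic binding constants, and identifiability diagnostics (normalized
# sensitivities, parameter correlation matrix).

#' Bundle one experimental (or synthetic) dataset for fitting
#'
#' @param id Dataset label.
#' @param kind One of `"respirometry_trace"` (buffer O2 concentration vs
#'   time), `"uptake_rate"` (average uptake/release rates over an
#'   incubation), `"r123_trace"` (buffer R123 nM vs time) or
#'   `"enzyme_kinetics"` (initial rates vs concentrations, for
#'   [fit_intrinsic_ls()]).
#' @param data Tibble of observations. Trace kinds need `time` and `value`;
#'   `uptake_rate` needs `species` and `value` plus any substrate columns
#'   named `<SPECIES>_mM` defining the incubation; `enzyme_kinetics` needs
#'   one column per species concentration plus `rate`.
#' @param events,conditions,t_end Protocol under which the model is simulated
#'   to predict the observations (trace kinds and as the template for
#'   `uptake_rate`).
#' @param window Averaging window for `uptake_rate` (default whole run).
#' @param r123 Optional [r123_params()] for `r123_trace` datasets.
#' @return A list of class `mito_dataset`.
#' @export
mito_dataset <- function(id, kind = c("respirometry_trace", "uptake_rate",
                                      "r123_trace", "enzyme_kinetics"),
                         data, events = NULL,
                         conditions = protocol_conditions(), t_end = 10,
                         window = NULL, r123 = NULL) {
  kind <- match.arg(kind)
  data <- tibble::as_tibble(data)
  if (nrow(data) < 1) stop("dataset ", id, " has no observations")
  structure(list(id = id, kind = kind, data = data, events = events,
                 conditions = conditions, t_end = t_end, window = window,
                 r123 = r123), class = "mito_dataset")
}

# Relaxed tolerances and a small step budget for fitting simulations:
# infeasible parameter combinations must fail fast.
fit_solver_defaults <- function() {
  list(rtol = 1e-6, atol = 1e-8, maxsteps = 2000,
       fallback_methods = "lsoda", dt = 0.05)
}

# Model predictions aligned with a dataset's observation vector.
predict_dataset <- function(model, ds, solver_opts = fit_solver_defaults()) {
  dt <- solver_opts$dt %||% 0.02
  if (ds$kind == "respirometry_trace") {
    sim <- simulate_protocol(model, events = ds$events, t_end = ds$t_end,
                             conditions = ds$conditions, dt = dt,
                             solver_opts = solver_opts)
    stats::approx(sim$trajectory$time, sim$trajectory$O2.e,
                  xout = ds$data$time, rule = 2)$y
  } else if (ds$kind == "r123_trace") {
    sim <- simulate_protocol(model, events = ds$events, t_end = ds$t_end,
                             conditions = ds$conditions, dt = dt,
                             solver_opts = solver_opts, r123 = ds$r123)
    stats::approx(sim$trajectory$time, sim$trajectory$R123.e * 1e9,
                  xout = ds$data$time, rule = 2)$y
  } else if (ds$kind == "uptake_rate") {
    sub_cols <- grep("_mM$", names(ds$data), value = TRUE)
    conds <- unique(ds$data[sub_cols])
    out <- numeric(nrow(ds$data))
    for (r in seq_len(nrow(conds))) {
      subs <- stats::setNames(as.numeric(conds[r, ]),
                              sub("_mM$", "", sub_cols))
      ev <- respirometry_events(substrates = subs[subs > 0],
                                substrate_time = 0, adp = NULL)
      sim <- simulate_protocol(model, events = ev, t_end = ds$t_end,
                               conditions = ds$conditions, dt = dt,
                               solver_opts = solver_opts)
      sel <- rep(TRUE, length(sub_cols))
      for (k in seq_along(sub_cols))
        sel <- sel & ds$data[[sub_cols[k]]] == conds[[k]][r]
      sp <- ds$data$species[sel]
      rates <- uptake_rates(sim, unique(sp), window = ds$window)
      # release species are reported as positive production rates
      rates <- abs(rates)
      out[sel] <- rates[sp]
    }
    out
  } else stop("enzyme_kinetics datasets are fitted with fit_intrinsic_ls()")
}

# Weighted relative residuals across datasets: ((x - X)/X)/sqrt(N_j),
# so that sum(r^2) equals the fitting objective.
dataset_residuals <- function(theta, datasets, base_overrides = list(),
                              solver_opts = fit_solver_defaults()) {
  ov <- utils::modifyList(base_overrides, as.list(theta))
  model <- build_lung_model(ov)
  unlist(lapply(datasets, function(ds) {
    X <- ds$data$value
    keep <- X != 0
    x <- predict_dataset(model, ds, solver_opts)
    ((x[keep] - X[keep]) / X[keep]) / sqrt(sum(keep))
  }))
}

#' Weighted relative-residual objective
#'
#' `f = sum_j (1/N_j) sum_i ((x_ij - X_ij) / X_ij)^2` over datasets `j` with
#' `N_j` points each, where `x` are model solutions under each dataset's
#' protocol and `X` the observations. Observations equal to zero are excluded
#' (relative residual undefined) with a warning.
#'
#' @param theta Named vector/list of parameter overrides (see
#'   [lung_model_params()] names).
#' @param datasets List of [mito_dataset()] objects.
#' @param base_overrides Parameter overrides applied under `theta` (fixed
#'   during fitting).
#' @param solver_opts Solver tolerances used for the fitting simulations.
#' @return The scalar objective `f` (dimensionless).
#' @export
objective <- function(theta, datasets, base_overrides = list(),
                      solver_opts = fit_solver_defaults()) {
  for (ds in datasets) {
    nz <- sum(ds$data$value == 0)
    if (nz > 0)
      warning("dataset ", ds$id, ": ", nz,
              " zero-valued observation(s) excluded from relative residuals")
  }
  sum(dataset_residuals(theta, datasets, base_overrides, solver_opts)^2)
}

ga_defaults <- function() {
  list(pop_size = 50, generations = 200, elite = 2, tournament = 2,
       blx_alpha = 0.3, p_mutate = 0.25, mutate_sd = 0.15,
       polish = TRUE, polish_maxit = 200, failure_penalty = 1e6)
}

#' Genetic-algorithm estimation of extrinsic maximal rates
#'
#' Minimizes [objective()] over a named set of extrinsic parameters
#' (`Vmaxf_*` / `Tmaxf_*`) within multiplicative bounds, using a seeded
#' real-coded genetic algorithm in log10 parameter space (tournament
#' selection, BLX-alpha crossover, Gaussian mutation, elitism), optionally
#' followed by a Nelder-Mead polish of the best individual. Reproducible
#' given `seed`.
#'
#' @param datasets List of [mito_dataset()] objects.
#' @param bounds Named list of `c(lower, upper)` per parameter, or a single
#'   numeric `c(lo_mult, hi_mult)` interpreted as multiplicative bounds
#'   around the registry defaults for the parameters in `params_to_fit`.
#' @param params_to_fit Parameter names (needed when `bounds` is a
#'   multiplier pair).
#' @param ga_opts Named list overriding [ga_defaults()].
#' @param seed Integer seed controlling the whole run.
#' @param base_overrides Fixed parameter overrides.
#' @param solver_opts Solver tolerances for fitting simulations.
#' @return A `mito_fit` object: `theta` (estimates), `objective`,
#'   `history` (best objective per generation), `evals`, `bounds`, `seed`.
#' @export
fit_extrinsic_ga <- function(datasets, bounds, params_to_fit = names(bounds),
                             ga_opts = list(), seed = 1,
                             base_overrides = list(),
                             solver_opts = fit_solver_defaults()) {
  go <- utils::modifyList(ga_defaults(), ga_opts)
  if (!is.list(bounds)) {
    stopifnot(length(bounds) == 2, all(bounds > 0), !is.null(params_to_fit))
    defaults <- lung_model_params()[params_to_fit]
    bounds <- lapply(defaults, function(v) v * sort(bounds))
    names(bounds) <- params_to_fit
  }
  if (length(datasets) == 0) stop("no datasets supplied")
  if (any(vapply(bounds, function(b) any(b <= 0), TRUE)))
    stop("bounds must be positive")
  pn <- names(bounds)
  lo <- log10(vapply(bounds, `[`, 0, 1))
  hi <- log10(vapply(bounds, `[`, 0, 2))
  np <- length(pn)
  evals <- 0L
  fobj <- function(lg) {
    evals <<- evals + 1L
    th <- stats::setNames(10^pmin(pmax(lg, lo), hi), pn)
    val <- tryCatch(
      suppressWarnings(objective(th, datasets, base_overrides, solver_opts)),
      error = function(e) go$failure_penalty)
    if (!is.finite(val)) val <- go$failure_penalty
    val
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  pop <- matrix(stats::runif(go$pop_size * np, rep(lo, each = go$pop_size),
                             rep(hi, each = go$pop_size)),
                nrow = go$pop_size)
  fit <- apply(pop, 1, fobj)
  if (all(fit >= go$failure_penalty))
    stop("all individuals in the initial population are infeasible; ",
         "check bounds and datasets")
  init_best <- min(fit)
  history <- numeric(go$generations)
  for (g in seq_len(go$generations)) {
    ord <- order(fit)
    newpop <- pop[ord[seq_len(go$elite)], , drop = FALSE]
    while (nrow(newpop) < go$pop_size) {
      pick <- function() {
        cand <- sample.int(go$pop_size, go$tournament)
        cand[which.min(fit[cand])]
      }
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      d <- abs(p1 - p2)
      ch <- stats::runif(np, pmin(p1, p2) - go$blx_alpha * d,
                         pmax(p1, p2) + go$blx_alpha * d)
      mut <- stats::runif(np) < go$p_mutate
      ch[mut] <- ch[mut] + stats::rnorm(sum(mut), 0,
                                        go$mutate_sd * (hi - lo)[mut])
      newpop <- rbind(newpop, pmin(pmax(ch, lo), hi))
    }
    keep_fit <- fit[ord[seq_len(go$elite)]]
    new_fit <- apply(newpop[-seq_len(go$elite), , drop = FALSE], 1, fobj)
    pop <- newpop
    fit <- c(keep_fit, new_fit)
    history[g] <- min(fit)
  }
  best <- pop[which.min(fit), ]
  best_f <- min(fit)
  if (isTRUE(go$polish)) {
    # Levenberg-Marquardt on the residual vector (quadratic convergence in
    # the sloppy valley the GA lands in); soft wall residuals keep the step
    # inside the bounds, and the finite-difference step is set well above
    # the ODE-solver noise floor
    pol_solver <- utils::modifyList(solver_opts,
                                    list(rtol = 1e-8, atol = 1e-10))
    rss <- function(lg) {
      th <- stats::setNames(10^pmin(pmax(lg, lo), hi), pn)
      r <- tryCatch(suppressWarnings(dataset_residuals(
        th, datasets, base_overrides, pol_solver)),
        error = function(e) NULL)
      if (is.null(r) || !all(is.finite(r)))
        r <- rep(sqrt(go$failure_penalty), 8)
      c(r, 30 * pmax(0, lg - hi), 30 * pmax(0, lo - lg))
    }
    pol <- tryCatch(minpack.lm::nls.lm(
      par = best, fn = rss,
      control = minpack.lm::nls.lm.control(maxiter = go$polish_maxit,
                                           epsfcn = 1e-6, ftol = 1e-14,
                                           ptol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(pol)) {
      par <- pmin(pmax(pol$par, lo), hi)
      val <- fobj(par)
      if (val < best_f) { best <- par; best_f <- val }
    }
  }
  structure(list(theta = stats::setNames(10^best, pn), objective = best_f,
                 initial_best = init_best, history = history, evals = evals,
                 bounds = bounds, seed = seed, ga_opts = go,
                 base_overrides = base_overrides, datasets = datasets,
                 solver_opts = solver_opts),
            class = "mito_fit")
}

#' @export
print.mito_fit <- function(x, ...) {
  cat(sprintf("<mito_fit> %d parameter(s), objective %.6g after %d evaluations (seed %d)\n",
              length(x$theta), x$objective, x$evals, x$seed))
  print(tidy(x), ...)
  invisible(x)
}

#' Least-squares estimation of intrinsic binding constants
#'
#' Fits the binding constants (and a nuisance maximal rate, discarded for the
#' integrated model) of a single flux law to isolated-enzyme initial-rate
#' data by Levenberg-Marquardt least squares in log-parameter space.
#'
#' @param curve_data A `mito_dataset` of kind `enzyme_kinetics`: one column
#'   per species concentration (named as in the spec) plus `rate`.
#' @param flux_spec_template A [flux_spec()] whose binding constants are the
#'   starting values.
#' @param fit_constants Species names whose `K` is estimated (default: all
#'   substrates and products appearing as data columns).
#' @param keq_apparent Apparent equilibrium constant under the assay
#'   conditions (default the template's `keq0`).
#' @return List with `K` (named estimates, mM), `vmax` (nuisance),
#'   `fitted`, `residuals`, and the `nls.lm` convergence info.
#' @export
fit_intrinsic_ls <- function(curve_data, flux_spec_template,
                             fit_constants = NULL, keq_apparent = NULL) {
  stopifnot(inherits(curve_data, "mito_dataset"),
            curve_data$kind == "enzyme_kinetics")
  df <- curve_data$data
  if (!"rate" %in% names(df)) stop("enzyme_kinetics data need a 'rate' column")
  spp <- c(flux_spec_template$substrates$species,
           flux_spec_template$products$species)
  cols <- intersect(spp, names(df))
  if (!length(cols)) stop("no species concentration columns found")
  if (is.null(fit_constants)) fit_constants <- cols
  if (stats::var(df$rate) < 1e-20 ||
      all(vapply(cols, function(cl) stats::var(df[[cl]]) < 1e-20, TRUE)))
    stop("non-identifiable design: response or concentrations do not vary")
  keq <- keq_apparent %||% flux_spec_template$keq0
  conc_rows <- lapply(seq_len(nrow(df)), function(i) {
    v <- stats::setNames(rep(0, length(spp)), spp)
    v[cols] <- as.numeric(df[i, cols])
    v
  })
  template <- flux_spec_template
  start <- log(c(vmax = template$vmax,
                 stats::setNames(vapply(fit_constants, function(s) {
                   tb <- rbind(template$substrates, template$products)
                   tb$K[match(s, tb$species)]
                 }, 0), fit_constants)))
  model_rates <- function(lp) {
    p <- exp(lp)
    sp <- template
    sp$vmax <- p[["vmax"]]
    for (s in fit_constants) {
      i <- match(s, sp$substrates$species)
      if (!is.na(i)) sp$substrates$K[i] <- p[[s]]
      j <- match(s, sp$products$species)
      if (!is.na(j)) sp$products$K[j] <- p[[s]]
    }
    vapply(conc_rows, function(cv) general_flux(sp, cv, keq), 0)
  }
  res <- minpack.lm::nls.lm(par = start,
                            fn = function(lp) model_rates(lp) - df$rate,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  est <- exp(res$par)
  list(K = est[fit_constants], vmax = unname(est[["vmax"]]),
       fitted = model_rates(res$par), residuals = res$fvec,
       info = res$info, message = res$message, deviance = res$deviance)
}

#' Normalized local sensitivity coefficients
#'
#' `S_i = (theta_i / E) * dE/dtheta_i`, with `E` the fitting objective
#' ([objective()]) and the derivative approximated by central differences
#' with a relative perturbation `delta` (default 0.1%).
#'
#' @param theta_hat Named parameter vector (evaluation point).
#' @param datasets List of [mito_dataset()] objects.
#' @param base_overrides,solver_opts As in [objective()].
#' @param delta Relative perturbation (default 1e-3).
#' @param fun Optional scalar function `E(theta)` overriding the default
#'   objective (used by closed-form micro-oracles in tests).
#' @return Tibble with `parameter`, `S`, and `failed` (TRUE if the model
#'   could not be evaluated at a perturbed point).
#' @export
sensitivity_coefficients <- function(theta_hat, datasets = NULL,
                                     base_overrides = list(),
                                     solver_opts = list(rtol = 1e-6,
                                                        atol = 1e-8),
                                     delta = 1e-3, fun = NULL) {
  E <- fun %||% function(th) suppressWarnings(
    objective(th, datasets, base_overrides, solver_opts))
  E0 <- E(theta_hat)
  if (!is.finite(E0) || E0 <= 0)
    stop("objective at theta_hat must be finite and > 0 for normalization")
  rows <- lapply(names(theta_hat), function(pn) {
    thp <- thm <- theta_hat
    thp[pn] <- theta_hat[[pn]] * (1 + delta)
    thm[pn] <- theta_hat[[pn]] * (1 - delta)
    up <- tryCatch(E(thp), error = function(e) NA_real_)
    dn <- tryCatch(E(thm), error = function(e) NA_real_)
    failed <- !is.finite(up) || !is.finite(dn)
    S <- if (failed) NA_real_ else
      (up - dn) / (2 * delta * theta_hat[[pn]]) * theta_hat[[pn]] / E0
    tibble::tibble(parameter = pn, S = S, failed = failed)
  })
  dplyr::bind_rows(rows)
}

#' Parameter correlation matrix from the residual Jacobian
#'
#' Builds the finite-difference Jacobian of the weighted relative residuals
#' at `theta_hat`, forms `HH = (J^T J)^-1` (pseudo-inverse with a warning if
#' singular), and returns `CC_ij = HH_ij / sqrt(HH_ii HH_jj)`.
#'
#' @inheritParams sensitivity_coefficients
#' @param delta Relative finite-difference step (default 1e-3, matching the
#'   sensitivity convention).
#' @return A symmetric matrix with unit diagonal and entries in `[-1, 1]`;
#'   attribute `pseudo_inverse` flags a rank-deficient `J^T J`.
#' @export
correlation_matrix <- function(theta_hat, datasets,
                               base_overrides = list(),
                               solver_opts = fit_solver_defaults(),
                               delta = 1e-3) {
  resid_fun <- function(th) dataset_residuals(th, datasets, base_overrides,
                                              solver_opts)
  r0 <- resid_fun(theta_hat)
  Jm <- vapply(names(theta_hat), function(pn) {
    thp <- thm <- theta_hat
    thp[pn] <- theta_hat[[pn]] * (1 + delta)
    thm[pn] <- theta_hat[[pn]] * (1 - delta)
    (resid_fun(thp) - resid_fun(thm)) / (2 * delta * theta_hat[[pn]])
  }, r0)
  JtJ <- crossprod(Jm)
  HH <- tryCatch(solve(JtJ), error = function(e) NULL)
  pseudo <- is.null(HH)
  if (pseudo) {
    warning("J^T J is singular; using the Moore-Penrose pseudo-inverse")
    s <- svd(JtJ)
    pos <- s$d > max(s$d) * 1e-12
    HH <- s$v[, pos, drop = FALSE] %*% diag(1 / s$d[pos], sum(pos)) %*%
      t(s$u[, pos, drop = FALSE])
  }
  d <- sqrt(pmax(diag(HH), .Machine$double.eps))
  CC <- HH / tcrossprod(d)
  CC <- (CC + t(CC)) / 2
  diag(CC) <- 1
  CC[CC > 1] <- 1; CC[CC < -1] <- -1
  dimnames(CC) <- list(names(theta_hat), names(theta_hat))
  attr(CC, "pseudo_inverse") <- pseudo
  CC
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy method for genetic-algorithm fits
#'
#' @param x A `mito_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `lower`, `upper`.
#' @export
tidy.mito_fit <- function(x, ...) {
  tibble::tibble(term = names(x$theta), estimate = unname(x$theta),
                 lower = vapply(x$bounds[names(x$theta)], `[`, 0, 1),
                 upper = vapply(x$bounds[names(x$theta)], `[`, 0, 2))
}

#' Glance method for genetic-algorithm fits
#'
#' @param x A `mito_fit`.
#' @param ... Unused.
#' @return One-row tibble with objective value, evaluation count,
#'   generations, and seed.
#' @export
glance.mito_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, initial_best = x$initial_best,
                 evals = x$evals, generations = length(x$history),
                 n_params = length(x$theta), seed = x$seed)
}

#' Desk-scale parameter-recovery harness
#'
#' Builds the noiseless synthetic datasets used to exercise the genetic
#' algorithm: buffer-oxygen traces for the pyruvate+malate and succinate
#' respirometry protocols (room temperature, tightly coupled preparation),
#' simulated at `true_params`. Two protocols are needed because a single
#' trace leaves the extrinsic parameters badly correlated (the parameter
#' interdependence the correlation matrix quantifies).
#'
#' @param model Base model.
#' @param true_params Ground-truth overrides for the generator.
#' @param t_end Protocol length, min (ADP at 3.5 min).
#' @param cadence Sampling interval, min.
#' @return List of two [mito_dataset()] objects.
#' @export
recovery_harness_datasets <- function(model = build_lung_model(),
                                      true_params = list(), t_end = 6,
                                      cadence = 0.25) {
  cond <- protocol_conditions(leak_scale = 0.4)
  mk <- function(subs, seed) generate_synthetic_respirometry(
    synthetic_spec(events = respirometry_events(subs, substrate_time = 0.5,
                                                adp = 0.1, adp_time = 3.5),
                   conditions = cond, t_end = t_end,
                   noise_sd_relative = 0, cadence = cadence, seed = seed),
    model = build_lung_model(utils::modifyList(as.list(model$params),
                                               true_params)))
  list(pyr_mal = mk(c(PYR = 10, MAL = 5), 1L),
       suc = mk(c(SUC = 7), 2L))
}
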