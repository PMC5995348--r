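# Seeded synthetic-data generation emulating the shapes of isolated-lung-
# mitochondria experiments: respirometry O2 traces with state 2/3/4
# transitions, 10-minute TCA uptake/release rates over substrate grids, and
# rhodamine-123 buffer traces. Noise is multiplicative Gaussian, matching
# the relative-residual fitting objective.

#' Specification of a synthetic experiment
#'
#' @param events,conditions,t_end Protocol to simulate (see
#'   [simulate_protocol()]).
#' @param true_params Named parameter overrides defining the ground truth.
#' @param noise_sd_relative Relative SD of the multiplicative Gaussian noise
#'   (0 = noiseless).
#' @param replicates Number of replicate traces (>= 1).
#' @param cadence Sampling interval, min.
#' @param seed Integer seed; every random draw flows through it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(events = respirometry_events(),
                           conditions = protocol_conditions(), t_end = 10,
                           true_params = list(), noise_sd_relative = 0.05,
                           replicates = 1, cadence = 0.1, seed = 1) {
  stopifnot(noise_sd_relative >= 0, replicates >= 1, cadence > 0)
  structure(list(events = events, conditions = conditions, t_end = t_end,
                 true_params = true_params,
                 noise_sd_relative = noise_sd_relative,
                 replicates = replicates, cadence = cadence, seed = seed),
            class = "synthetic_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

apply_noise <- function(values, rel_sd, replicates) {
  if (rel_sd == 0)
    return(lapply(seq_len(replicates), function(r) values))
  lapply(seq_len(replicates), function(r)
    values * (1 + stats::rnorm(length(values), 0, rel_sd)))
}

#' Synthetic respirometry trace dataset
#'
#' Simulates the protocol at the true parameters, samples the buffer O2
#' concentration at the stated cadence, and applies multiplicative Gaussian
#' noise per replicate.
#'
#' @param spec A [synthetic_spec()].
#' @param model Base model (true parameters are applied on top).
#' @return A [mito_dataset()] of kind `respirometry_trace`; column
#'   `replicate` distinguishes replicates, `value` is buffer O2 in mM.
#' @export
generate_synthetic_respirometry <- function(spec, model = build_lung_model()) {
  model_true <- build_lung_model(utils::modifyList(as.list(model$params),
                                                  spec$true_params))
  sim <- simulate_protocol(model_true, events = spec$events,
                           t_end = spec$t_end, conditions = spec$conditions)
  tt <- seq(0, spec$t_end, by = spec$cadence)
  o2 <- stats::approx(sim$trajectory$time, sim$trajectory$O2.e, xout = tt,
                      rule = 2)$y
  reps <- with_seed(spec$seed,
                    apply_noise(o2, spec$noise_sd_relative, spec$replicates))
  data <- dplyr::bind_rows(lapply(seq_along(reps), function(r)
    tibble::tibble(time = tt, replicate = r, value = reps[[r]])))
  mito_dataset(id = "synthetic_respirometry", kind = "respirometry_trace",
               data = data, events = spec$events,
               conditions = spec$conditions, t_end = spec$t_end)
}

#' Synthetic TCA uptake/release rate dataset
#'
#' Average pyruvate uptake, malate uptake and citrate production rates over a
#' 10-minute incubation, on a grid of buffer pyruvate and malate
#' concentrations (default the 0-10 mM design: varying PYR at 5 mM MAL and
#' varying MAL at 5 mM PYR).
#'
#' @param spec A [synthetic_spec()] (its `events` field is ignored; the grid
#'   defines the protocols).
#' @param model Base model.
#' @param pyr_grid,mal_grid Varied concentrations, mM.
#' @param fixed_pyr,fixed_mal Fixed co-substrate concentrations, mM.
#' @return A [mito_dataset()] of kind `uptake_rate` with columns `species`,
#'   `PYR_mM`, `MAL_mM`, `replicate`, `value` (nmol min-1 mg-1; uptakes and
#'   the citrate release both positive).
#' @export
generate_synthetic_tca_uptake <- function(spec, model = build_lung_model(),
                                          pyr_grid = c(0, 0.5, 1, 5, 10),
                                          mal_grid = c(0, 0.5, 1, 5, 10),
                                          fixed_pyr = 5, fixed_mal = 5) {
  model_true <- build_lung_model(utils::modifyList(as.list(model$params),
                                                   spec$true_params))
  grid <- unique(rbind(data.frame(PYR_mM = pyr_grid, MAL_mM = fixed_mal),
                       data.frame(PYR_mM = fixed_pyr, MAL_mM = mal_grid)))
  rows <- list()
  for (r in seq_len(nrow(grid))) {
    subs <- c(PYR = grid$PYR_mM[r], MAL = grid$MAL_mM[r])
    ev <- respirometry_events(substrates = subs[subs > 0],
                              substrate_time = 0, adp = NULL)
    sim <- simulate_protocol(model_true, events = ev, t_end = spec$t_end,
                             conditions = spec$conditions)
    rates <- abs(uptake_rates(sim, c("PYR", "MAL", "CIT")))
    rows[[r]] <- tibble::tibble(species = c("PYR", "MAL", "CIT"),
                                PYR_mM = grid$PYR_mM[r],
                                MAL_mM = grid$MAL_mM[r],
                                value = unname(rates))
  }
  base <- dplyr::bind_rows(rows)
  reps <- with_seed(spec$seed, apply_noise(base$value,
                                           spec$noise_sd_relative,
                                           spec$replicates))
  data <- dplyr::bind_rows(lapply(seq_along(reps), function(rr)
    dplyr::mutate(base, replicate = rr, value = reps[[rr]])))
  mito_dataset(id = "synthetic_tca_uptake", kind = "uptake_rate",
               data = data, conditions = spec$conditions, t_end = spec$t_end)
}

#' Synthetic rhodamine-123 buffer trace dataset
#'
#' @param spec A [synthetic_spec()].
#' @param model Base model.
#' @param params An [r123_params()].
#' @return A [mito_dataset()] of kind `r123_trace` (`value` in nM).
#' @export
generate_synthetic_r123 <- function(spec, model = build_lung_model(),
                                    params = r123_params()) {
  model_true <- build_lung_model(utils::modifyList(as.list(model$params),
                                                   spec$true_params))
  sim <- simulate_r123(model_true, params = params, events = spec$events,
                       t_end = spec$t_end, conditions = spec$conditions)
  tt <- seq(0, spec$t_end, by = spec$cadence)
  r123 <- stats::approx(sim$trajectory$time, sim$trajectory$R123.e * 1e9,
                        xout = tt, rule = 2)$y
  reps <- with_seed(spec$seed, apply_noise(r123, spec$noise_sd_relative,
                                           spec$replicates))
  data <- dplyr::bind_rows(lapply(seq_along(reps), function(r)
    tibble::tibble(time = tt, replicate = r, value = reps[[r]])))
  mito_dataset(id = "synthetic_r123", kind = "r123_trace", data = data,
               events = spec$events, conditions = spec$conditions,
               t_end = spec$t_end, r123 = params)
}
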