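# Shared fixtures: one default model, and lazily cached canonical protocol
# simulations reused across test files (simulations are deterministic).

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .cache)) assign(key, force(expr), .cache)
  get(key, .cache)
}

default_model <- function() cached("model", build_lung_model())

cond23 <- function(leak_scale = 0.4) protocol_conditions(leak_scale = leak_scale)

# Fig-4A-like protocol: PYR+MAL, ADP at 3.5 min, optional FCCP at 6.5 min
pm_events <- function(adp = 0.1, fccp = FALSE)
  respirometry_events(c(PYR = 10, MAL = 5), substrate_time = 0.5,
                      adp = adp, adp_time = 3.5, fccp = fccp,
                      fccp_time = 6.5)

sim_pm <- function() cached("sim_pm", simulate_protocol(
  default_model(), pm_events(), t_end = 10, conditions = cond23()))

sim_pm_fccp <- function() cached("sim_pm_fccp", simulate_protocol(
  default_model(), pm_events(fccp = TRUE), t_end = 10, conditions = cond23()))

sim_suc <- function() cached("sim_suc", simulate_protocol(
  default_model(), respirometry_events(c(SUC = 7), substrate_time = 0.5,
                                       adp = 0.1, adp_time = 3.5),
  t_end = 10, conditions = cond23()))

# Fig-2-like incubation: 30 C, pH 7.4, 1 ml, 0.7 mg, 4 mM Pi, 5+5 mM PYR/MAL
cond30 <- function() protocol_conditions(temperature_C = 30, pH_buffer = 7.4,
                                         buffer_volume_ml = 1, protein_mg = 0.7,
                                         pi_mM = 4, o2_mM = 0.22,
                                         leak_scale = 1)

sim_fig2 <- function() cached("sim_fig2", simulate_protocol(
  default_model(),
  respirometry_events(c(PYR = 5, MAL = 5), substrate_time = 0, adp = NULL),
  t_end = 10, conditions = cond30()))

state_at <- function(sim, t) {
  i <- which.min(abs(sim$trajectory$time - t))
  stats::setNames(as.numeric(sim$trajectory[i, -1]),
                  names(sim$trajectory)[-1])
}

fluxes_at <- function(sim, t) {
  i <- which.min(abs(sim$fluxes$time - t))
  stats::setNames(as.numeric(sim$fluxes[i, -1]), names(sim$fluxes)[-1])
}

# random flux spec generator for property-style tests
random_flux_spec <- function(ns = 2, np = 2, pair = FALSE) {
  subs <- data.frame(species = paste0("S", seq_len(ns)),
                     coef = sample(1:2, ns, replace = TRUE),
                     K = stats::runif(ns, 0.05, 2))
  prods <- data.frame(species = paste0("P", seq_len(np)),
                      coef = sample(1:2, np, replace = TRUE),
                      K = stats::runif(np, 0.05, 2))
  pairs <- if (pair) list(c("S1", "P1")) else list()
  flux_spec(paste0("rnd", ns, np), "reaction", subs, prods,
            vmax = stats::runif(1, 1, 100),
            keq0 = 10^stats::runif(1, -2, 2), cofactor_pairs = pairs)
}

rand_conc <- function(spec) {
  sp <- c(spec$substrates$species, spec$products$species)
  stats::setNames(stats::runif(length(sp), 0.01, 5), sp)
}

quotient <- function(spec, conc) {
  prod(conc[spec$products$species]^spec$products$coef) /
    prod(conc[spec$substrates$species]^spec$substrates$coef)
}

cheap_spec <- function(noise = 0, seed = 7) synthetic_spec(
  events = respirometry_events(c(PYR = 10, MAL = 5), substrate_time = 0.5,
                               adp = NULL),
  conditions = cond23(), t_end = 3, noise_sd_relative = noise,
  cadence = 0.5, seed = seed)

ds_cheap <- function() cached("ds_cheap",
  generate_synthetic_respirometry(cheap_spec(), default_model()))

ds_noisy <- function() cached("ds_noisy",
  generate_synthetic_respirometry(cheap_spec(noise = 0.02), default_model()))

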