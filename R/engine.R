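# Network compilation and the reference (pure-R) right-hand side.
#
# The network is "compiled" once per protocol segment into flat index arrays:
# maximal rates are Q10-scaled to the protocol temperature, buffer fluxes get
# the nmol/min/mg -> mM/min conversion for the protocol's buffer volume and
# protein mass, and every flux's substrate/product indices, binding constants
# and thermodynamic couplings are resolved against the state layout. The same
# structure drives both the reference R evaluator below and the compiled
# (C++) fast path used by the integrator; a test pins their agreement.

compile_network <- function(model, temperature = 303.15, pH_buffer = 7.2,
                            buffer_volume_l = 0.55e-3, protein_mg = 0.55,
                            leak_scale = NULL, r123 = NULL) {
  p <- model$params
  ctx <- thermo_ctx(temperature = temperature, pH_buffer = pH_buffer,
                    pH_matrix = p$pH_matrix0)
  q10 <- q10_correction(ctx, temperature)
  states <- model$species$state
  n_sp <- length(states)
  fac <- c(matrix = 1, ims = 10, buffer = protein_mg / (buffer_volume_l * 1e6))
  state_fac <- unname(fac[model$species$compartment])
  nf <- length(model$fluxes)
  iHm <- n_sp + 1L; iHe <- n_sp + 2L; iPsi <- n_sp + 3L
  n_states <- n_sp + 3L + if (!is.null(r123)) 2L else 0L

  S <- matrix(0, nrow = n_states, ncol = nf + 1L,
              dimnames = list(NULL, c(names(model$fluxes), "LEAK")))
  idx_of <- stats::setNames(seq_len(n_sp), states)
  fx <- vector("list", nf)
  for (k in seq_len(nf)) {
    f <- model$fluxes[[k]]
    pair <- paired_species(f)
    si <- unname(idx_of[f$substrates$species])
    pi_ <- unname(idx_of[f$products$species])
    for (j in seq_along(si))
      S[si[j], k] <- S[si[j], k] - f$substrates$coef[j] * state_fac[si[j]]
    for (j in seq_along(pi_))
      S[pi_[j], k] <- S[pi_[j], k] + f$products$coef[j] * state_fac[pi_[j]]
    if (f$o2_stoich != 0) {
      io2 <- idx_of[["O2.e"]]
      S[io2, k] <- S[io2, k] - f$o2_stoich * state_fac[io2]
    }
    fx[[k]] <- list(
      id = f$id,
      vmax = f$vmax * q10,
      prefK = f$vmax * q10 / prod(f$substrates$K^f$substrates$coef),
      keq0 = f$keq0,
      ph_sign = switch(f$proton_convention, releasing = 1, consuming = -1, 0),
      ph_matrix = f$ph_side == "matrix",
      n_charge = f$n_charge, n_h_in = f$n_h_in,
      h_matrix = f$h_matrix, h_buffer = f$h_buffer,
      sub_idx = si, sub_coef = f$substrates$coef, sub_K = f$substrates$K,
      sub_dnm = !(f$substrates$species %in% pair$sub),
      prod_idx = pi_, prod_coef = f$products$coef, prod_K = f$products$K,
      prod_dnm = !(f$products$species %in% pair$prod),
      o2_km = f$o2_km, o2_idx = idx_of[["O2.e"]])
  }
  leak_scale <- leak_scale %||% model$leak$leak_scale
  list(model = model, states = states, n_sp = n_sp, n_states = n_states,
       iHm = iHm, iHe = iHe, iPsi = iPsi,
       flux_names = c(names(model$fluxes), "LEAK"),
       fluxes = fx, S = S,
       leak_pref = model$leak$Tmaxf_leak * leak_scale * q10 / model$leak$h_ref,
       charge_coef = c(vapply(fx, `[[`, 0, "n_charge"), -1) / p$Cimm,
       hm_coef = c(vapply(fx, `[[`, 0, "h_matrix"), 1),
       he_coef = c(vapply(fx, `[[`, 0, "h_buffer"), -1),
       fac_e = unname(fac["buffer"]),
       beta_matrix = p$beta_matrix, beta_buffer = p$beta_buffer,
       RT = .RGAS * temperature, F_RT_mV = .FARADAY * 1e-3 / (.RGAS * temperature),
       protein_mg = protein_mg, buffer_volume_l = buffer_volume_l,
       temperature = temperature, q10 = q10,
       r123 = if (!is.null(r123)) {
         list(iRm = n_sp + 4L, iRe = n_sp + 5L, p = r123$p, z = r123$z,
              dm = 60 / r123$V_m_apparent_ul,
              de = 60 * protein_mg * 1e-6 / r123$V_e_apparent_l)
       })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reference evaluator: all 25 network fluxes plus the proton leak, at one
# state vector. Returns a named vector in nmol min-1 mg-1.
eval_network_fluxes <- function(comp, y) {
  conc <- pmax(y[seq_len(comp$n_sp)], 0)
  Hm <- max(y[comp$iHm], 1e-12); He <- max(y[comp$iHe], 1e-12)
  psi <- y[comp$iPsi]
  J <- numeric(length(comp$fluxes) + 1L)
  for (k in seq_along(comp$fluxes)) {
    f <- comp$fluxes[[k]]
    keq <- f$keq0
    if (f$ph_sign != 0) {
      pH <- -log10(if (f$ph_matrix) Hm else He)
      keq <- keq * 10^(f$ph_sign * (pH - 7))
    }
    if (f$n_charge != 0) keq <- keq * exp(-f$n_charge * psi * comp$F_RT_mV)
    if (f$n_h_in != 0) keq <- keq * (He / Hm)^f$n_h_in
    cs <- conc[f$sub_idx]; cp <- conc[f$prod_idx]
    num <- prod(cs^f$sub_coef) - prod(cp^f$prod_coef) / keq
    dn <- prod(1 + (cs[f$sub_dnm] / f$sub_K[f$sub_dnm])^f$sub_coef[f$sub_dnm]) *
      prod(1 + (cp[f$prod_dnm] / f$prod_K[f$prod_dnm])^f$prod_coef[f$prod_dnm])
    Jk <- f$prefK * num / dn
    if (!is.na(f$o2_km)) {
      o2 <- conc[f$o2_idx]
      Jk <- Jk * o2 / (f$o2_km + o2)
    }
    J[k] <- Jk
  }
  # proton leak, GHK form, positive IMS -> matrix
  w <- psi * comp$F_RT_mV
  J[length(J)] <- if (abs(w) < 1e-6) {
    comp$leak_pref * ((He - Hm) + w * (He + Hm) / 2)
  } else {
    ew <- exp(w)
    comp$leak_pref * w * (He * ew - Hm) / (ew - 1)
  }
  names(J) <- comp$flux_names
  J
}

# Reference RHS (deSolve signature) built on eval_network_fluxes.
network_rhs_r <- function(t, y, comp) {
  J <- eval_network_fluxes(comp, y)
  dy <- as.vector(comp$S %*% J)
  Hm <- max(y[comp$iHm], 1e-12); He <- max(y[comp$iHe], 1e-12)
  dy[comp$iHm] <- Hm * log(10) * sum(comp$hm_coef * J) / comp$beta_matrix
  dy[comp$iHe] <- He * log(10) * sum(comp$he_coef * J) * comp$fac_e /
    comp$beta_buffer
  dy[comp$iPsi] <- sum(comp$charge_coef * J)
  if (!is.null(comp$r123)) {
    r <- comp$r123
    w <- r$z * y[comp$iPsi] * comp$F_RT_mV
    Jr <- if (abs(w) < 1e-6) {
      r$p * ((y[r$iRe] - y[r$iRm]) + w * (y[r$iRe] + y[r$iRm]) / 2)
    } else {
      ew <- exp(w)
      r$p * w * (y[r$iRe] * ew - y[r$iRm]) / (ew - 1)
    }
    dy[r$iRm] <- Jr * r$dm
    dy[r$iRe] <- -Jr * r$de
  }
  list(dy)
}

# Build the fast RHS closure: compiled C++ network unless engine = "R".
make_rhs <- function(comp, engine = c("compiled", "R")) {
  engine <- match.arg(engine)
  if (engine == "R") {
    return(list(rhs = function(t, y, parms) network_rhs_r(t, y, comp),
                fluxes = function(y) eval_network_fluxes(comp, y)))
  }
  ptr <- net_compile(comp_to_cpp(comp))
  list(rhs = function(t, y, parms) list(net_rhs(ptr, t, y)),
       fluxes = function(y) {
         stats::setNames(net_fluxes(ptr, y), comp$flux_names)
       })
}

# Flatten the compiled network into the arrays the C++ engine expects.
comp_to_cpp <- function(comp) {
  fx <- comp$fluxes
  rag <- function(field) lapply(fx, `[[`, field)
  r123 <- comp$r123
  list(
    n_states = comp$n_states, n_sp = comp$n_sp,
    iHm = comp$iHm - 1L, iHe = comp$iHe - 1L, iPsi = comp$iPsi - 1L,
    prefK = vapply(fx, `[[`, 0, "prefK"),
    keq0 = vapply(fx, `[[`, 0, "keq0"),
    ph_sign = vapply(fx, `[[`, 0, "ph_sign"),
    ph_matrix = vapply(fx, function(f) as.integer(f$ph_matrix), 0L),
    n_charge = vapply(fx, `[[`, 0, "n_charge"),
    n_h_in = vapply(fx, `[[`, 0, "n_h_in"),
    o2_km = vapply(fx, function(f) if (is.na(f$o2_km)) -1 else f$o2_km, 0),
    o2_idx = vapply(fx, function(f) f$o2_idx - 1L, 0L),
    sub_idx = lapply(rag("sub_idx"), function(v) as.integer(v - 1L)),
    sub_coef = rag("sub_coef"), sub_K = rag("sub_K"),
    sub_dnm = lapply(rag("sub_dnm"), as.integer),
    prod_idx = lapply(rag("prod_idx"), function(v) as.integer(v - 1L)),
    prod_coef = rag("prod_coef"), prod_K = rag("prod_K"),
    prod_dnm = lapply(rag("prod_dnm"), as.integer),
    S = comp$S,
    charge_coef = comp$charge_coef, hm_coef = comp$hm_coef,
    he_coef = comp$he_coef,
    leak_pref = comp$leak_pref, fac_e = comp$fac_e,
    beta_matrix = comp$beta_matrix, beta_buffer = comp$beta_buffer,
    F_RT_mV = comp$F_RT_mV,
    r123 = if (!is.null(r123)) {
      c(iRm = r123$iRm - 1L, iRe = r123$iRe - 1L, p = r123$p, z = r123$z,
        dm = r123$dm, de = r123$de)
    } else numeric(0))
}
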