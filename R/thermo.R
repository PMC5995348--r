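# Physical constants (SI)
.RGAS <- 8.314462618   # J mol-1 K-1
.FARADAY <- 96485.33212  # C mol-1

#' Thermodynamic context for flux evaluation
#'
#' Bundles the temperature, the pH of the two proton pools, and the physical
#' constants needed by the flux laws. Maximal rates in the shipped model are
#' referenced to 30 degrees C; simulations at other temperatures scale every
#' Vmax/Tmax by [q10_correction()].
#'
#' @param temperature Absolute temperature in kelvin.
#' @param pH_buffer pH of the extra-mitochondrial buffer (also the IMS, which
#'   equilibrates with the buffer across the porous outer membrane).
#' @param pH_matrix pH of the mitochondrial matrix.
#' @param Q10 Temperature coefficient applied to maximal rates (default 2.5).
#' @param reference_temperature Temperature (K) at which the maximal rates are
#'   defined; default 303.15 K (30 degrees C).
#' @param R Gas constant, J mol-1 K-1.
#' @param F Faraday constant, C mol-1.
#' @return An object of class `thermo_ctx`.
#' @export
#' @examples
#' ctx <- thermo_ctx(temperature = 296.15, pH_buffer = 7.2)
#' q10_correction(ctx, 296.15 + 10)
thermo_ctx <- function(temperature = 303.15, pH_buffer = 7.2, pH_matrix = 7.35,
                       Q10 = 2.5, reference_temperature = 303.15,
                       R = .RGAS, F = .FARADAY) {
  stopifnot(temperature > 0, Q10 > 0, reference_temperature > 0,
            pH_buffer > 0, pH_buffer < 14, pH_matrix > 0, pH_matrix < 14)
  structure(list(temperature = temperature, pH_buffer = pH_buffer,
                 pH_matrix = pH_matrix, Q10 = Q10,
                 reference_temperature = reference_temperature, R = R, F = F),
            class = "thermo_ctx")
}

#' @export
print.thermo_ctx <- function(x, ...) {
  cat(sprintf("<thermo_ctx> T = %.2f K (%.1f degC), pH buffer %.2f / matrix %.2f, Q10 %.2f (ref %.2f K)\n",
              x$temperature, x$temperature - 273.15, x$pH_buffer, x$pH_matrix,
              x$Q10, x$reference_temperature))
  invisible(x)
}

#' pH correction of an apparent equilibrium constant
#'
#' Proton-releasing reactions have `K'eq = K'eq0 * 10^(pH - 7)`; proton
#' consuming reactions `K'eq = K'eq0 * 10^(7 - pH)`; pH-neutral reactions keep
#' `K'eq0`. `K'eq0` is the apparent equilibrium constant at pH 7 (equivalently
#' `exp(-DrG'0 / RT)`).
#'
#' @param spec A [flux_spec()] (uses its `keq0` and `proton_convention`).
#' @param ctx A [thermo_ctx()].
#' @param side Which pool's pH applies: `"matrix"` or `"buffer"`.
#' @return Dimensionless apparent equilibrium constant.
#' @export
apparent_keq <- function(spec, ctx, side = c("matrix", "buffer")) {
  side <- match.arg(side)
  pH <- if (side == "matrix") ctx$pH_matrix else ctx$pH_buffer
  keq_ph_correct(spec$keq0, spec$proton_convention, pH)
}

keq_ph_correct <- function(keq0, convention, pH) {
  switch(convention,
         releasing = keq0 * 10^(pH - 7),
         consuming = keq0 * 10^(7 - pH),
         neutral = keq0,
         stop("unknown proton convention: ", convention))
}

#' Q10 temperature scaling of maximal rates
#'
#' Returns the multiplicative correction `Q10^((T2 - T1)/10)` applied to every
#' maximal reaction and transport rate when simulating at a temperature `T2`
#' different from the reference temperature `T1` of the rate table.
#'
#' @param ctx A [thermo_ctx()] supplying `Q10` and the reference temperature.
#' @param target_temperature Temperature (K) of the simulated experiment.
#' @return Dimensionless scale factor.
#' @export
q10_correction <- function(ctx, target_temperature) {
  stopifnot(target_temperature > 0)
  ctx$Q10^((target_temperature - ctx$reference_temperature) / 10)
}

#' Goldman-Hodgkin-Katz electrodiffusion flux for a cation
#'
#' Flux of a permeant cation across the inner membrane under a membrane
#' potential, positive for uptake into the matrix (the matrix side is
#' electrically negative when `deltaPsi > 0`):
#' `J = p * w * (C_out * e^w - C_in) / (e^w - 1)`, with `w = z F dPsi / RT`.
#' The Fick limit `p * (C_out - C_in)` is recovered as `deltaPsi -> 0`
#' (handled by a second-order series below `|w| < 1e-6`), and the flux
#' vanishes at the Nernst ratio `C_in / C_out = e^w`.
#'
#' @param deltaPsi Membrane potential in mV (positive: matrix negative).
#' @param C_out,C_in Concentrations outside / inside the matrix (any unit;
#'   flux is in `p`'s rate unit times that concentration unit).
#' @param p Permeability coefficient.
#' @param z Valence of the transported ion.
#' @param ctx A [thermo_ctx()] (supplies temperature, R, F).
#' @return Flux, positive for uptake into the matrix.
#' @export
#' @examples
#' ctx <- thermo_ctx(temperature = 296.15)
#' ghk_cation_flux(140, C_out = 200e-9, C_in = 0, p = 1.38, z = 1, ctx = ctx)
ghk_cation_flux <- function(deltaPsi, C_out, C_in, p, z = 1, ctx = thermo_ctx()) {
  stopifnot(C_out >= 0, C_in >= 0)
  w <- z * ctx$F * deltaPsi * 1e-3 / (ctx$R * ctx$temperature)
  if (abs(w) < 1e-6) {
    # 2nd-order expansion around w = 0, avoids 0/0
    return(p * ((C_out - C_in) + w * (C_out + C_in) / 2))
  }
  ew <- exp(w)
  p * w * (C_out * ew - C_in) / (ew - 1)
}
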