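#' Specification of one reaction or transporter flux
#'
#' Describes a single enzymatic reaction or carrier-mediated transport step
#' under the generalized thermodynamically-constrained rapid-equilibrium rate
#' law (see [general_flux()]). Substrates and products are given with their
#' stoichiometric coefficients and binding constants (mM, in the compartment
#' where binding occurs). Cofactor pairs (e.g. NAD/NADH, ATP/ADP) share a
#' binding site, so their saturation terms are omitted from the denominator;
#' when every species is paired the law degenerates to reversible mass action
#' with rate constant `vmax / prod(K_S^alpha)`.
#'
#' @param id Flux name (e.g. `"PDH"`, `"ANT"`).
#' @param kind `"reaction"`, `"transporter"` or `"leak"`.
#' @param substrates,products Data frames with columns `species` (state name,
#'   e.g. `"PYR.m"`), `coef` (positive integer stoichiometry) and `K`
#'   (binding constant, mM).
#' @param vmax Maximal forward rate, nmol min-1 mg-1 at the reference
#'   temperature.
#' @param keq0 Apparent equilibrium constant at pH 7 in mM-consistent units.
#'   Alternatively give `drg0` (standard transformed Gibbs energy, kJ/mol,
#'   1 M standard state) and the mM conversion is applied from the
#'   stoichiometry.
#' @param drg0 Optional `DrG'0` (kJ/mol) used to derive `keq0`.
#' @param proton_convention `"releasing"`, `"consuming"` or `"neutral"`;
#'   controls the pH correction of the apparent Keq ([apparent_keq()]).
#' @param ph_side Compartment whose pH applies (`"matrix"` or `"buffer"`).
#' @param cofactor_pairs List of `c(substrate_id, product_id)` pairs sharing a
#'   binding site; both members drop out of the denominator.
#' @param mechanism Kinetic mechanism flag. `"generalized"` is the
#'   random-ordered rapid-equilibrium law; `"sequential_ordered"` and
#'   `"ping_pong"` are accepted and currently evaluated with the generalized
#'   denominator (the generalized law encompasses them as special cases at
#'   the level of apparent constants).
#' @param n_charge Elementary charges moved matrix -> IMS per unit forward
#'   flux (enters the apparent Keq as `exp(-n_charge * F * dPsi / RT)` and the
#'   membrane-potential balance).
#' @param n_h_in Protons transported into the matrix per unit forward flux
#'   (enters the apparent Keq as `(H_e / H_m)^n_h_in`).
#' @param h_matrix,h_buffer Net H+ bookkeeping coefficients (flux units) for
#'   the matrix and buffer proton pools.
#' @param o2_km Optional Michaelis constant (mM) for a multiplicative oxygen
#'   dependence `[O2]/(K + [O2])` (used by complex IV).
#' @param o2_stoich Buffer O2 consumed per unit forward flux (e.g. 0.5 for a
#'   2-electron complex IV flux unit).
#' @return An object of class `flux_spec`.
#' @export
flux_spec <- function(id, kind = c("reaction", "transporter", "leak"),
                      substrates, products, vmax,
                      keq0 = NULL, drg0 = NULL,
                      proton_convention = c("neutral", "releasing", "consuming"),
                      ph_side = c("matrix", "buffer"),
                      cofactor_pairs = list(),
                      mechanism = c("generalized", "sequential_ordered", "ping_pong"),
                      n_charge = 0, n_h_in = 0, h_matrix = 0, h_buffer = 0,
                      o2_km = NA_real_, o2_stoich = 0) {
  kind <- match.arg(kind)
  proton_convention <- match.arg(proton_convention)
  ph_side <- match.arg(ph_side)
  mechanism <- match.arg(mechanism)
  substrates <- as.data.frame(substrates)
  products <- as.data.frame(products)
  for (tb in list(substrates, products)) {
    stopifnot(all(c("species", "coef", "K") %in% names(tb)))
    if (nrow(tb)) {
      if (any(tb$K <= 0)) stop("flux ", id, ": binding constants must be > 0")
      if (any(tb$coef <= 0 | tb$coef != round(tb$coef)))
        stop("flux ", id, ": stoichiometric coefficients must be positive integers")
    }
  }
  if (vmax < 0) stop("flux ", id, ": vmax must be >= 0")
  if (is.null(keq0)) {
    if (is.null(drg0)) stop("flux ", id, ": give keq0 or drg0")
    # DrG'0 refers to 1 M standard state; convert to mM-based quotient units
    dn <- sum(products$coef) - sum(substrates$coef)
    keq0 <- exp(-drg0 * 1000 / (.RGAS * 303.15)) * 1000^dn
  }
  if (keq0 <= 0) stop("flux ", id, ": keq0 must be > 0")
  for (pr in cofactor_pairs) {
    if (!(pr[1] %in% substrates$species && pr[2] %in% products$species))
      stop("flux ", id, ": cofactor pair (", pr[1], ", ", pr[2],
           ") must name a substrate and a product")
  }
  structure(list(id = id, kind = kind, substrates = substrates,
                 products = products, vmax = vmax, keq0 = keq0,
                 proton_convention = proton_convention, ph_side = ph_side,
                 cofactor_pairs = cofactor_pairs, mechanism = mechanism,
                 n_charge = n_charge, n_h_in = n_h_in,
                 h_matrix = h_matrix, h_buffer = h_buffer,
                 o2_km = o2_km, o2_stoich = o2_stoich),
            class = "flux_spec")
}

#' @export
print.flux_spec <- function(x, ...) {
  lhs <- paste(sprintf("%s %s", ifelse(x$substrates$coef > 1, x$substrates$coef, ""),
                       x$substrates$species), collapse = " + ")
  rhs <- paste(sprintf("%s %s", ifelse(x$products$coef > 1, x$products$coef, ""),
                       x$products$species), collapse = " + ")
  cat(sprintf("<flux_spec %s (%s)> %s <-> %s | Vmaxf %.4g, Keq0 %.4g, pH %s (%s)\n",
              x$id, x$kind, lhs, rhs, x$vmax, x$keq0, x$proton_convention, x$ph_side))
  invisible(x)
}

paired_species <- function(spec) {
  list(sub = vapply(spec$cofactor_pairs, `[`, "", 1),
       prod = vapply(spec$cofactor_pairs, `[`, "", 2))
}

#' Generalized thermodynamically-constrained reaction/transport flux
#'
#' Evaluates the random-ordered rapid-equilibrium rate law with the Haldane
#' constraint:
#' \deqn{J = \frac{V_{maxf}}{\prod_i K_{Si}^{\alpha_i}}
#'   \frac{\prod_i [S_i]^{\alpha_i} - \prod_j [P_j]^{\beta_j} / K'_{eq}}
#'        {\prod_i (1 + [S_i]^{\alpha_i}/K_{Si}^{\alpha_i})
#'         \prod_j (1 + [P_j]^{\beta_j}/K_{Pj}^{\beta_j})}}
#' where the denominator factors of cofactor-pair members are omitted (the
#' pair shares one binding site). The flux is zero exactly when the reaction
#' quotient equals `keq_apparent`, and positive in the forward direction.
#'
#' @param spec A [flux_spec()].
#' @param conc Named numeric vector of concentrations (mM) covering every
#'   species the spec references.
#' @param keq_apparent Apparent equilibrium constant (already pH/membrane
#'   corrected), in the same mM-consistent units as `spec$keq0`.
#' @return Flux in nmol min-1 mg-1 (sign: forward positive).
#' @export
#' @examples
#' sp <- flux_spec("demo", "reaction",
#'   substrates = data.frame(species = "S", coef = 1, K = 0.5),
#'   products = data.frame(species = "P", coef = 1, K = 2),
#'   vmax = 10, keq0 = 4)
#' general_flux(sp, c(S = 1, P = 0.5), keq_apparent = 4)
general_flux <- function(spec, conc, keq_apparent) {
  if (keq_apparent <= 0) stop("keq_apparent must be > 0")
  need <- c(spec$substrates$species, spec$products$species)
  miss <- setdiff(need, names(conc))
  if (length(miss))
    stop("flux ", spec$id, ": unknown species id(s): ", paste(miss, collapse = ", "))
  cs <- pmax(conc[spec$substrates$species], 0)
  cp <- pmax(conc[spec$products$species], 0)
  a <- spec$substrates$coef; b <- spec$products$coef
  Ks <- spec$substrates$K; Kp <- spec$products$K
  pair <- paired_species(spec)
  s_in_denom <- !(spec$substrates$species %in% pair$sub)
  p_in_denom <- !(spec$products$species %in% pair$prod)
  num <- prod(cs^a) - prod(cp^b) / keq_apparent
  denom <- prod(1 + (cs[s_in_denom] / Ks[s_in_denom])^a[s_in_denom]) *
    prod(1 + (cp[p_in_denom] / Kp[p_in_denom])^b[p_in_denom])
  J <- spec$vmax / prod(Ks^a) * num / denom
  if (!is.na(spec$o2_km)) {
    o2 <- pmax(conc[["O2.e"]], 0)
    J <- J * o2 / (spec$o2_km + o2)
  }
  unname(J)
}

#' Proton-leak specification
#'
#' The passive proton leak across the inner membrane, modeled with a modified
#' Goldman-Hodgkin-Katz electrodiffusion law. `Tmaxf_leak` is the maximal leak
#' rate (nmol min-1 mg-1 at reference temperature and reference proton
#' concentration `h_ref`); `leak_scale` is a dimensionless multiplier
#' (1 by default; 0.40 reproduces the more tightly coupled in-house
#' preparation; 7 emulates FCCP uncoupling).
#'
#' @param Tmaxf_leak Maximal leak rate, nmol min-1 mg-1.
#' @param leak_scale Dimensionless multiplier (> 0).
#' @param h_ref Reference proton concentration (M) normalizing the GHK term
#'   so that `Tmaxf_leak` carries the rate units.
#' @return An object of class `leak_spec`.
#' @export
leak_spec <- function(Tmaxf_leak = 36, leak_scale = 1, h_ref = 4.0e-8) {
  stopifnot(Tmaxf_leak >= 0, leak_scale > 0, h_ref > 0)
  structure(list(Tmaxf_leak = Tmaxf_leak, leak_scale = leak_scale,
                 h_ref = h_ref), class = "leak_spec")
}

#' Proton leak flux (modified GHK)
#'
#' @param leak A [leak_spec()].
#' @param deltaPsi Membrane potential, mV (positive: matrix negative).
#' @param H_ims,H_matrix Proton concentrations (M) in the IMS/buffer pool and
#'   the matrix.
#' @param ctx A [thermo_ctx()].
#' @return Leak flux in nmol min-1 mg-1, positive for IMS -> matrix proton
#'   flow; monotonically increasing in `deltaPsi`.
#' @export
proton_leak_flux <- function(leak, deltaPsi, H_ims, H_matrix, ctx = thermo_ctx()) {
  stopifnot(H_ims > 0, H_matrix > 0)
  scale <- leak$Tmaxf_leak * leak$leak_scale / leak$h_ref
  ghk_cation_flux(deltaPsi, C_out = H_ims, C_in = H_matrix, p = scale,
                  z = 1, ctx = ctx)
}
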