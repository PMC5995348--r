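# Three-compartment lung-mitochondrion network: species, parameters, wiring.
#
# State naming convention: "<SPECIES>.<compartment>" with m = matrix,
# i = inter-membrane space, e = extra-mitochondrial buffer. Cytochrome c is
# confined to the IMS; species marked permeable share a single buffer/IMS
# state (outer-membrane porins).

#' Convert a matrix content to a concentration
#'
#' Matrix metabolite contents (nmol per mg mitochondrial protein) convert to
#' matrix concentrations (mM) through the 1 ul/mg mitochondrial water volume,
#' so the numeric value is unchanged.
#'
#' @param content Content in nmol per mg protein (>= 0).
#' @return Concentration in mM.
#' @export
#' @examples
#' content_to_concentration(1.73)  # pyridine-nucleotide pool -> 1.73 mM
content_to_concentration <- function(content) {
  if (any(content < 0)) stop("content must be nonnegative")
  content  # 1 nmol/mg divided by 1 ul/mg water volume = 1 mM
}

#' Default parameter registry of the lung-mitochondrion model
#'
#' Named defaults for every tunable quantity: the 25 extrinsic maximal rates
#' (`Vmaxf_*` for reactions, `Tmaxf_*` for transporters, nmol min-1 mg-1 at
#' 30 degrees C), intrinsic binding constants (`K_<flux>_<state>`, mM),
#' apparent pH-7 equilibrium constants (`Keq0_<flux>`, mM-consistent units),
#' membrane and proton-buffering constants, and the initial redox /
#' phosphorylation poise. Every name can be overridden through
#' [build_lung_model()].
#'
#' @return Named list of parameter defaults.
#' @export
lung_model_params <- function() {
  list(
    # --- extrinsic maximal rates (nmol/min/mg at 30 C) ---
    Vmaxf_PDH = 307, Vmaxf_CITS = 4631, Vmaxf_CITDH = 531, Vmaxf_AKGDH = 780,
    Vmaxf_SCAS = 5816, Vmaxf_NDK = 4.33e6, Vmaxf_SUCDH = 1.08e4,
    Vmaxf_FH = 6.4e3, Vmaxf_MDH = 3.3e3, Vmaxf_GOT = 975,
    Vmaxf_CI = 11, Vmaxf_CII = 220, Vmaxf_CIII = 2.23e4, Vmaxf_CIV = 0.27,
    Vmaxf_CV = 589,
    Tmaxf_DCC_SUC = 1699, Tmaxf_DCC_MAL = 22, Tmaxf_OME = 1, Tmaxf_TCC = 81.3,
    Tmaxf_PYRH = 96.6, Tmaxf_PIC = 2.4e4, Tmaxf_ANT = 523.9, Tmaxf_GLUH = 5,
    Tmaxf_GAE = 646, Tmaxf_LEAK = 36,
    # --- membrane / leak / buffering ---
    Cimm = 6.75e-3,        # nmol charge per mg per mV
    leak_scale = 1.0,      # dimensionless multiplier on Tmaxf_LEAK
    leak_h_ref = 3.6e-8,   # M; proton concentration normalizing the GHK leak
    K_O2 = 1.0e-3,         # mM; complex-IV oxygen Michaelis constant
    beta_matrix = 300,     # mM per pH unit; effective slope lumping intrinsic
                           # buffering with K+/H+ exchange homeostasis
    beta_buffer = 12,      # mM per pH unit; MOPS-buffered medium
    pH_matrix0 = 7.35,     # initial matrix pH
    init_psi = 100,        # mV; resting membrane potential at mito addition
    # --- conserved-pool totals (mM after the 1 ul/mg conversion) ---
    pool_NAD = 1.73, pool_FAD = 0.7, pool_ADN = 6.4, pool_CoA = 0.93,
    pool_CytC = 0.33, pool_UQ = 0.52, pool_ASPGLU = 12, pool_GDN = 0.5,
    # --- initial poise (resting, substrate-free) ---
    init_NADH = 0.16, init_FADH2 = 0.05, init_ATP = 0.02, init_UQH2 = 0.06,
    init_CytCred_frac = 0.09, init_GTP = 0.1,
    init_PYR = 0.01, init_ACoA = 0.04, init_OXA = 5e-4, init_CIT = 0.05,
    init_AKG = 0.05, init_SCoA = 0.01, init_SUC = 0.1, init_FUM = 0.02,
    init_MAL = 0.3, init_GLU = 10, init_Pi = 2.0,
    # --- intrinsic constants: Keq0 (pH 7, mM-consistent) ---
    Keq0_PDH = 1e6, Keq0_CITS = 2.2e6, Keq0_CITDH = 150, Keq0_AKGDH = 2400,
    Keq0_SCAS = 3.7, Keq0_NDK = 1, Keq0_SUCDH = 1, Keq0_FH = 4.4,
    Keq0_MDH = 1e-5, Keq0_GOT = 0.15,
    Keq0_CI = 8e7, Keq0_CII = 450, Keq0_CIII = 3e4, Keq0_CIV = 5e17,
    Keq0_CV = 6e-9,
    Keq0_DCC_SUC = 1, Keq0_DCC_MAL = 1, Keq0_OME = 1, Keq0_TCC = 1,
    Keq0_PYRH = 1, Keq0_PIC = 1, Keq0_ANT = 1, Keq0_GLUH = 1, Keq0_GAE = 1,
    # --- intrinsic constants: binding constants (mM) ---
    K_PDH_PYR.m = 0.08, K_PDH_CoA.m = 1.4, K_PDH_NAD.m = 0.03,
    K_PDH_ACoA.m = 1, K_PDH_NADH.m = 50,
    K_CITS_OXA.m = 0.004, K_CITS_ACoA.m = 0.03, K_CITS_CIT.m = 1.6,
    K_CITS_CoA.m = 0.9,
    K_CITDH_CIT.m = 0.1, K_CITDH_NAD.m = 0.002, K_CITDH_AKG.m = 2,
    K_CITDH_NADH.m = 4.7e-3,
    K_AKGDH_AKG.m = 0.5, K_AKGDH_CoA.m = 0.9, K_AKGDH_NAD.m = 1.6,
    K_AKGDH_SCoA.m = 0.05, K_AKGDH_NADH.m = 0.15,
    K_SCAS_SCoA.m = 0.05, K_SCAS_GDP.m = 0.5, K_SCAS_Pi.m = 2.5,
    K_SCAS_SUC.m = 1.5, K_SCAS_GTP.m = 0.5, K_SCAS_CoA.m = 0.9,
    K_NDK_GTP.m = 1, K_NDK_ADP.m = 1, K_NDK_GDP.m = 1, K_NDK_ATP.m = 1,
    K_SUCDH_SUC.m = 1.6, K_SUCDH_FAD.m = 0.6, K_SUCDH_FUM.m = 1.2,
    K_SUCDH_FADH2.m = 0.06,
    K_FH_FUM.m = 0.14, K_FH_MAL.m = 0.6,
    K_MDH_MAL.m = 1.3, K_MDH_NAD.m = 0.03, K_MDH_OXA.m = 0.04,
    K_MDH_NADH.m = 50,
    K_GOT_ASP.m = 3.9, K_GOT_AKG.m = 0.43, K_GOT_OXA.m = 0.09,
    K_GOT_GLU.m = 8.6,
    K_CI_NADH.m = 0.1, K_CI_UQ.m = 0.4, K_CI_NAD.m = 1.0, K_CI_UQH2.m = 0.4,
    K_CII_FADH2.m = 0.04, K_CII_UQ.m = 0.5, K_CII_FAD.m = 0.6,
    K_CII_UQH2.m = 0.5,
    K_CIII_UQH2.m = 40, K_CIII_CytCox.i = 3, K_CIII_UQ.m = 4,
    K_CIII_CytCred.i = 3,
    K_CIV_CytCred.i = 0.042, K_CIV_CytCox.i = 0.042,
    K_CV_ADP.m = 0.05, K_CV_Pi.m = 1.0, K_CV_ATP.m = 0.5,
    K_DCC_SUC_SUC.e = 1.2, K_DCC_SUC_Pi.m = 5, K_DCC_SUC_SUC.m = 2,
    K_DCC_SUC_Pi.e = 5,
    K_DCC_MAL_MAL.e = 0.5, K_DCC_MAL_Pi.m = 5, K_DCC_MAL_MAL.m = 8,
    K_DCC_MAL_Pi.e = 5,
    K_OME_AKG.m = 0.5, K_OME_MAL.e = 1, K_OME_AKG.e = 0.5, K_OME_MAL.m = 1,
    K_TCC_CIT.m = 0.5, K_TCC_MAL.e = 1.5, K_TCC_CIT.e = 1.5, K_TCC_MAL.m = 1.5,
    K_PYRH_PYR.e = 15, K_PYRH_PYR.m = 15,
    K_PIC_Pi.e = 1.5, K_PIC_Pi.m = 1.5,
    K_ANT_ATP.m = 0.01, K_ANT_ADP.e = 0.005, K_ANT_ATP.e = 5, K_ANT_ADP.m = 10,
    K_GLUH_GLU.e = 10, K_GLUH_GLU.m = 10,
    K_GAE_GLU.e = 2, K_GAE_ASP.m = 2, K_GAE_GLU.m = 2, K_GAE_ASP.e = 2
  )
}

# Assemble the 25 flux specifications from the parameter registry.
lung_model_fluxes <- function(p) {
  sp <- function(flux, species, coef = rep(1, length(species))) {
    data.frame(species = species, coef = coef,
               K = vapply(species, function(s)
                 p[[paste0("K_", flux, "_", s)]], 0), row.names = NULL)
  }
  fl <- list(
    # ---- TCA cycle ----
    flux_spec("PDH", "reaction",
              sp("PDH", c("PYR.m", "CoA.m", "NAD.m")),
              sp("PDH", c("ACoA.m", "NADH.m")),
              vmax = p$Vmaxf_PDH, keq0 = p$Keq0_PDH,
              proton_convention = "releasing",
              cofactor_pairs = list(c("CoA.m", "ACoA.m")),
              h_matrix = 1),
    flux_spec("CITS", "reaction",
              sp("CITS", c("OXA.m", "ACoA.m")),
              sp("CITS", c("CIT.m", "CoA.m")),
              vmax = p$Vmaxf_CITS, keq0 = p$Keq0_CITS,
              proton_convention = "releasing",
              cofactor_pairs = list(c("ACoA.m", "CoA.m"))),
    # Lumped aconitase + NAD-isocitrate dehydrogenase. NAD/NADH deliberately
    # NOT treated as a shared-site pair here: the strong NADH product
    # inhibition (K ~ 4.7 uM) is a load-bearing feature of the incomplete
    # TCA-cycle phenotype and lives in the denominator saturation term.
    flux_spec("CITDH", "reaction",
              sp("CITDH", c("CIT.m", "NAD.m")),
              sp("CITDH", c("AKG.m", "NADH.m")),
              vmax = p$Vmaxf_CITDH, keq0 = p$Keq0_CITDH,
              proton_convention = "releasing", h_matrix = 1),
    flux_spec("AKGDH", "reaction",
              sp("AKGDH", c("AKG.m", "CoA.m", "NAD.m")),
              sp("AKGDH", c("SCoA.m", "NADH.m")),
              vmax = p$Vmaxf_AKGDH, keq0 = p$Keq0_AKGDH,
              proton_convention = "releasing",
              cofactor_pairs = list(c("CoA.m", "SCoA.m"), c("NAD.m", "NADH.m")),
              h_matrix = 1),
    flux_spec("SCAS", "reaction",
              sp("SCAS", c("SCoA.m", "GDP.m", "Pi.m")),
              sp("SCAS", c("SUC.m", "GTP.m", "CoA.m")),
              vmax = p$Vmaxf_SCAS, keq0 = p$Keq0_SCAS,
              cofactor_pairs = list(c("SCoA.m", "CoA.m"), c("GDP.m", "GTP.m"))),
    flux_spec("NDK", "reaction",
              sp("NDK", c("GTP.m", "ADP.m")),
              sp("NDK", c("GDP.m", "ATP.m")),
              vmax = p$Vmaxf_NDK, keq0 = p$Keq0_NDK,
              cofactor_pairs = list(c("GTP.m", "GDP.m"), c("ADP.m", "ATP.m"))),
    flux_spec("SUCDH", "reaction",
              sp("SUCDH", c("SUC.m", "FAD.m")),
              sp("SUCDH", c("FUM.m", "FADH2.m")),
              vmax = p$Vmaxf_SUCDH, keq0 = p$Keq0_SUCDH,
              cofactor_pairs = list(c("FAD.m", "FADH2.m"))),
    flux_spec("FH", "reaction",
              sp("FH", "FUM.m"), sp("FH", "MAL.m"),
              vmax = p$Vmaxf_FH, keq0 = p$Keq0_FH),
    flux_spec("MDH", "reaction",
              sp("MDH", c("MAL.m", "NAD.m")),
              sp("MDH", c("OXA.m", "NADH.m")),
              vmax = p$Vmaxf_MDH, keq0 = p$Keq0_MDH,
              proton_convention = "releasing",
              h_matrix = 1),
    flux_spec("GOT", "reaction",
              sp("GOT", c("ASP.m", "AKG.m")),
              sp("GOT", c("OXA.m", "GLU.m")),
              vmax = p$Vmaxf_GOT, keq0 = p$Keq0_GOT),
    # ---- electron transport chain / oxidative phosphorylation ----
    flux_spec("CI", "reaction",
              sp("CI", c("NADH.m", "UQ.m")),
              sp("CI", c("NAD.m", "UQH2.m")),
              vmax = p$Vmaxf_CI, keq0 = p$Keq0_CI,
              proton_convention = "consuming",
              cofactor_pairs = list(c("NADH.m", "NAD.m"), c("UQ.m", "UQH2.m")),
              n_charge = 4, n_h_in = -4, h_matrix = -5, h_buffer = 4),
    flux_spec("CII", "reaction",
              sp("CII", c("FADH2.m", "UQ.m")),
              sp("CII", c("FAD.m", "UQH2.m")),
              vmax = p$Vmaxf_CII, keq0 = p$Keq0_CII,
              cofactor_pairs = list(c("FADH2.m", "FAD.m"), c("UQ.m", "UQH2.m"))),
    flux_spec("CIII", "reaction",
              sp("CIII", c("UQH2.m", "CytCox.i"), coef = c(1, 2)),
              sp("CIII", c("UQ.m", "CytCred.i"), coef = c(1, 2)),
              vmax = p$Vmaxf_CIII, keq0 = p$Keq0_CIII,
              cofactor_pairs = list(c("UQH2.m", "UQ.m"),
                                    c("CytCox.i", "CytCred.i")),
              n_charge = 2, n_h_in = -2, h_matrix = -2, h_buffer = 2),
    flux_spec("CIV", "reaction",
              sp("CIV", "CytCred.i", coef = 2),
              sp("CIV", "CytCox.i", coef = 2),
              vmax = p$Vmaxf_CIV, keq0 = p$Keq0_CIV,
              proton_convention = "consuming",
              cofactor_pairs = list(c("CytCred.i", "CytCox.i")),
              n_charge = 4, n_h_in = -4, h_matrix = -4, h_buffer = 4,
              o2_km = p$K_O2, o2_stoich = 0.5),
    flux_spec("CV", "reaction",
              sp("CV", c("ADP.m", "Pi.m")),
              sp("CV", "ATP.m"),
              vmax = p$Vmaxf_CV, keq0 = p$Keq0_CV,
              cofactor_pairs = list(c("ADP.m", "ATP.m")),
              n_charge = -3, n_h_in = 3, h_matrix = 3, h_buffer = -3),
    # ---- carriers ----
    flux_spec("DCC_SUC", "transporter",
              sp("DCC_SUC", c("SUC.e", "Pi.m")),
              sp("DCC_SUC", c("SUC.m", "Pi.e")),
              vmax = p$Tmaxf_DCC_SUC, keq0 = p$Keq0_DCC_SUC),
    flux_spec("DCC_MAL", "transporter",
              sp("DCC_MAL", c("MAL.e", "Pi.m")),
              sp("DCC_MAL", c("MAL.m", "Pi.e")),
              vmax = p$Tmaxf_DCC_MAL, keq0 = p$Keq0_DCC_MAL),
    flux_spec("OME", "transporter",
              sp("OME", c("AKG.m", "MAL.e")),
              sp("OME", c("AKG.e", "MAL.m")),
              vmax = p$Tmaxf_OME, keq0 = p$Keq0_OME),
    # forward = citrate efflux (the dominant direction in lung mitochondria)
    flux_spec("TCC", "transporter",
              sp("TCC", c("CIT.m", "MAL.e")),
              sp("TCC", c("CIT.e", "MAL.m")),
              vmax = p$Tmaxf_TCC, keq0 = p$Keq0_TCC),
    flux_spec("PYRH", "transporter",
              sp("PYRH", "PYR.e"), sp("PYRH", "PYR.m"),
              vmax = p$Tmaxf_PYRH, keq0 = p$Keq0_PYRH, n_h_in = 1),
    flux_spec("PIC", "transporter",
              sp("PIC", "Pi.e"), sp("PIC", "Pi.m"),
              vmax = p$Tmaxf_PIC, keq0 = p$Keq0_PIC,
              n_h_in = 1, h_matrix = 1, h_buffer = -1),
    flux_spec("ANT", "transporter",
              sp("ANT", c("ATP.m", "ADP.e")),
              sp("ANT", c("ATP.e", "ADP.m")),
              vmax = p$Tmaxf_ANT, keq0 = p$Keq0_ANT,
              n_charge = -1),
    flux_spec("GLUH", "transporter",
              sp("GLUH", "GLU.e"), sp("GLUH", "GLU.m"),
              vmax = p$Tmaxf_GLUH, keq0 = p$Keq0_GLUH, n_h_in = 1),
    flux_spec("GAE", "transporter",
              sp("GAE", c("GLU.e", "ASP.m")),
              sp("GAE", c("GLU.m", "ASP.e")),
              vmax = p$Tmaxf_GAE, keq0 = p$Keq0_GAE)
  )
  names(fl) <- vapply(fl, `[[`, "", "id")
  fl
}

#' Build the integrated lung-mitochondrion bioenergetics model
#'
#' Assembles the default three-compartment network: 10 TCA-cycle reactions,
#' respiratory complexes I-V, 9 carriers plus the GHK proton leak, the seven
#' conserved pools and the membrane-potential balance. All parameters come
#' from [lung_model_params()] and can be overridden by name.
#'
#' @param param_overrides Named list of parameter values applied last (e.g.
#'   `list(Tmaxf_LEAK = 14.4)`). Unknown names are an error.
#' @return An object of class `lung_model`.
#' @export
#' @examples
#' m <- build_lung_model()
#' m$params$Tmaxf_LEAK
#' m2 <- build_lung_model(list(Tmaxf_LEAK = 36 * 0.40))
build_lung_model <- function(param_overrides = list()) {
  p <- lung_model_params()
  if (length(param_overrides)) {
    bad <- setdiff(names(param_overrides), names(p))
    if (length(bad))
      stop("unknown parameter override(s): ", paste(bad, collapse = ", "))
    p[names(param_overrides)] <- param_overrides
  }
  init <- c(
    PYR.m = p$init_PYR, CoA.m = p$pool_CoA - p$init_ACoA - p$init_SCoA,
    ACoA.m = p$init_ACoA, OXA.m = p$init_OXA, CIT.m = p$init_CIT,
    AKG.m = p$init_AKG, SCoA.m = p$init_SCoA, SUC.m = p$init_SUC,
    FUM.m = p$init_FUM, MAL.m = p$init_MAL, GLU.m = p$init_GLU,
    ASP.m = p$pool_ASPGLU - p$init_GLU, NAD.m = p$pool_NAD - p$init_NADH,
    NADH.m = p$init_NADH, FAD.m = p$pool_FAD - p$init_FADH2,
    FADH2.m = p$init_FADH2, ADP.m = p$pool_ADN - p$init_ATP,
    ATP.m = p$init_ATP, GDP.m = p$pool_GDN - p$init_GTP, GTP.m = p$init_GTP,
    UQ.m = p$pool_UQ - p$init_UQH2, UQH2.m = p$init_UQH2, Pi.m = p$init_Pi,
    # IMS concentration = content / (0.1 ul/mg)
    CytCox.i = 10 * p$pool_CytC * (1 - p$init_CytCred_frac),
    CytCred.i = 10 * p$pool_CytC * p$init_CytCred_frac,
    PYR.e = 0, CIT.e = 0, AKG.e = 0, SUC.e = 0, FUM.e = 0, MAL.e = 0,
    GLU.e = 0, ASP.e = 0, ADP.e = 0, ATP.e = 0, Pi.e = 2, O2.e = 0.25
  )
  species <- tibble::tibble(
    state = names(init),
    species = sub("\\.[mie]$", "", names(init)),
    compartment = c(m = "matrix", i = "ims", e = "buffer")[
      sub("^.*\\.", "", names(init))],
    initial = unname(init))
  pools <- list(
    pyridine = c("NAD.m", "NADH.m"),
    flavin = c("FAD.m", "FADH2.m"),
    adenine = c("ADP.m", "ATP.m", "ADP.e", "ATP.e"),
    coenzymeA = c("CoA.m", "ACoA.m", "SCoA.m"),
    cytochrome_c = c("CytCox.i", "CytCred.i"),
    ubiquinone = c("UQ.m", "UQH2.m"),
    asp_glu = c("ASP.m", "GLU.m", "ASP.e", "GLU.e"),
    guanine = c("GDP.m", "GTP.m"))
  structure(list(
    species = species,
    fluxes = lung_model_fluxes(p),
    leak = leak_spec(p$Tmaxf_LEAK, p$leak_scale, p$leak_h_ref),
    membrane = list(Cimm = p$Cimm,
                    proton_stoichiometry = c(CI = 4, CIII = 2, CIV = 4,
                                             CV = -3, ANT = -1, LEAK = -1)),
    pools = pools,
    params = p), class = "lung_model")
}

#' @export
print.lung_model <- function(x, ...) {
  cat(sprintf(paste0("<lung_model> %d states (%d metabolites + 2 H+ pools + deltaPsi), ",
                     "%d reaction/transport fluxes + proton leak\n"),
              nrow(x$species) + 3, nrow(x$species), length(x$fluxes)))
  invisible(x)
}

#' Stoichiometric matrix of the network
#'
#' Species-by-flux stoichiometry (substrates negative, products positive), in
#' flux units (nmol min-1 mg-1), without compartment volume conversion.
#' Useful for inspecting pool closure: pool rows sum to zero for every
#' column.
#'
#' @param model A [build_lung_model()] result.
#' @return A tibble with a `state` column and one column per flux.
#' @export
stoichiometric_matrix <- function(model) {
  states <- model$species$state
  S <- matrix(0, nrow = length(states), ncol = length(model$fluxes),
              dimnames = list(states, names(model$fluxes)))
  for (f in model$fluxes) {
    for (k in seq_len(nrow(f$substrates)))
      S[f$substrates$species[k], f$id] <-
        S[f$substrates$species[k], f$id] - f$substrates$coef[k]
    for (k in seq_len(nrow(f$products)))
      S[f$products$species[k], f$id] <-
        S[f$products$species[k], f$id] + f$products$coef[k]
    if (f$o2_stoich != 0) S["O2.e", f$id] <- S["O2.e", f$id] - f$o2_stoich
  }
  dplyr::bind_cols(tibble::tibble(state = states),
                   tibble::as_tibble(as.data.frame(S)))
}

#' Audit the conserved pools of a model state
#'
#' Totals each conserved moiety pool in content units (nmol per mg protein):
#' matrix and IMS concentrations convert through their volumes (1 and
#' 0.1 ul/mg), buffer concentrations through the protocol buffer volume and
#' protein mass. Pools span compartments where carriers move their members
#' (adenine nucleotides, aspartate/glutamate), so totals are invariant along
#' trajectories between addition events.
#'
#' @param state Named state vector (mM; as in simulation trajectories).
#' @param model A `lung_model`.
#' @param buffer_volume_l Buffer volume in liters.
#' @param protein_mg Mitochondrial protein mass in mg.
#' @return Named numeric vector of pool totals (nmol/mg).
#' @export
check_conservation_pools <- function(state, model, buffer_volume_l = 0.55e-3,
                                     protein_mg = 0.55) {
  fac <- c(matrix = 1, ims = 0.1,
           buffer = buffer_volume_l * 1e6 / protein_mg)
  w <- fac[model$species$compartment]
  names(w) <- model$species$state
  vapply(model$pools, function(members) {
    sum(state[members] * w[members])
  }, 0)
}
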