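#' @import methods
NULL

.IONIZABLE_KINDS <- c("acid", "base")

.emptyGroups <- function() data.frame(pka = numeric(0), kind = character(0))

.checkGroups <- function(groups) {
    msgs <- character(0)
    if (!is.data.frame(groups) || !all(c("pka", "kind") %in% names(groups)))
        return("'groups' must be a data.frame with columns 'pka' and 'kind'")
    if (nrow(groups)) {
        if (!all(groups$kind %in% .IONIZABLE_KINDS))
            msgs <- c(msgs, "group kind must be 'acid' or 'base'")
        if (!all(is.finite(groups$pka) & groups$pka > 0 & groups$pka < 14))
            msgs <- c(msgs, "all pKa values must lie in (0, 14)")
    }
    msgs
}

#' Capped Henderson-Hasselbalch pH-solubility model
#'
#' Holds the intrinsic (neutral-species) solubility \code{s0} (mg/mL), the
#' ionizable groups, and one solubility factor per ionization state: the
#' maximal ratio of that state's solubility to \code{s0}. The evaluated
#' solubility is \code{s0 * (1 + sum over states of min(ratio(pH),
#' factor - 1))}, where \code{ratio(pH)} is the Henderson-Hasselbalch
#' ionized/neutral concentration ratio of the state.
#'
#' @slot s0 intrinsic solubility of the neutral species, mg/mL.
#' @slot groups data.frame with columns \code{pka}, \code{kind}.
#' @slot factors numeric, one cap (>= 1) per ionization state, states ordered
#'   as cumulative base protonations (descending pKa) then cumulative acid
#'   deprotonations (ascending pKa).
#' @slot fitted logical, whether the model has been fitted.
#' @slot fit list of fit diagnostics (residuals, convergence).
#' @exportClass SolubilityModel
setClass("SolubilityModel",
    slots = c(s0 = "numeric", groups = "data.frame", factors = "numeric",
              fitted = "logical", fit = "list"),
    prototype = list(s0 = NA_real_, groups = data.frame(pka = numeric(0),
        kind = character(0)), factors = numeric(0), fitted = FALSE,
        fit = list()))

setValidity("SolubilityModel", function(object) {
    msgs <- .checkGroups(object@groups)
    if (object@fitted) {
        if (!isTRUE(is.finite(object@s0) && object@s0 > 0))
            msgs <- c(msgs, "fitted model requires s0 > 0")
        if (length(object@factors) != nrow(object@groups))
            msgs <- c(msgs, "one solubility factor per ionizable group required")
        if (length(object@factors) && any(object@factors < 1))
            msgs <- c(msgs, "solubility factors must be >= 1")
    }
    if (length(msgs)) msgs else TRUE
})

setClassUnion("SolubilityModelOrNULL", c("SolubilityModel", "NULL"))

#' Systemic disposition parameters (mammillary compartment model)
#'
#' Micro-constant parameterization of a linear 1-3 compartment model.
#' \code{vc} is the central-compartment volume; elimination is from the
#' central compartment with k10 = cl/vc.
#'
#' @slot cl clearance, L/h/kg.
#' @slot vc central volume of distribution, L/kg.
#' @slot k12,k21,k13,k31 inter-compartment rate constants, 1/h (zero drops
#'   the corresponding peripheral compartment).
#' @slot fpePercent hepatic first-pass extraction of orally absorbed drug, %.
#' @slot bodyWeight kg.
#' @slot bloodPlasmaRatio dimensionless (metadata; plasma is the model
#'   currency).
#' @slot fractionUnboundPercent plasma fraction unbound, % (metadata).
#' @slot fit list of fitting diagnostics when estimated from data.
#' @exportClass DispositionParams
setClass("DispositionParams",
    slots = c(cl = "numeric", vc = "numeric", k12 = "numeric",
              k21 = "numeric", k13 = "numeric", k31 = "numeric",
              fpePercent = "numeric", bodyWeight = "numeric",
              bloodPlasmaRatio = "numeric",
              fractionUnboundPercent = "numeric", fit = "list"),
    prototype = list(fpePercent = 0, bodyWeight = 70,
        bloodPlasmaRatio = NA_real_, fractionUnboundPercent = NA_real_,
        fit = list()))

setValidity("DispositionParams", function(object) {
    msgs <- character(0)
    for (nm in c("cl", "vc"))
        if (!isTRUE(is.finite(slot(object, nm)) && slot(object, nm) > 0))
            msgs <- c(msgs, paste0("'", nm, "' must be a positive number"))
    for (nm in c("k12", "k21", "k13", "k31"))
        if (!isTRUE(is.finite(slot(object, nm)) && slot(object, nm) >= 0))
            msgs <- c(msgs, paste0("'", nm, "' must be >= 0"))
    if (!isTRUE(object@fpePercent >= 0 && object@fpePercent <= 100))
        msgs <- c(msgs, "fpePercent must lie in [0, 100]")
    if (!isTRUE(is.finite(object@bodyWeight) && object@bodyWeight > 0))
        msgs <- c(msgs, "bodyWeight must be positive")
    if ((object@k12 > 0) != (object@k21 > 0))
        msgs <- c(msgs, "k12 and k21 must be both zero or both positive")
    if ((object@k13 > 0) != (object@k31 > 0))
        msgs <- c(msgs, "k13 and k31 must be both zero or both positive")
    if (length(msgs)) msgs else TRUE
})

#' Drug-specific model input parameters
#'
#' Physicochemical, biopharmaceutic and disposition inputs for one compound,
#' mirroring the layout of a mechanistic oral-absorption model input table.
#' Units are kept as conventionally printed (molecular weight g/mol, Peff
#' cm/s, particle diameter um, precipitation time s); computations convert
#' to canonical internal units (mg, mL, h, cm) at the point of use.
#'
#' @slot name compound name.
#' @slot mw molecular weight, g/mol.
#' @slot logP octanol-water partition coefficient (log10).
#' @slot groups ionizable groups, data.frame(pka, kind).
#' @slot solubility measured pH-solubility points, data.frame(ph, solubility)
#'   with solubility in mg/mL at 37 C.
#' @slot solubilityModel fitted \linkS4class{SolubilityModel} or NULL.
#' @slot peff human effective jejunal permeability, cm/s.
#' @slot particleDiameter initial particle diameter, um.
#' @slot particleDensity true density, g/mL.
#' @slot precipitationTime mean precipitation time, s.
#' @slot diffusionCoeff aqueous diffusion coefficient, cm^2/s (NA = derive
#'   from molecular weight).
#' @slot disposition \linkS4class{DispositionParams}.
#' @exportClass DrugSpec
setClass("DrugSpec",
    slots = c(name = "character", mw = "numeric", logP = "numeric",
              groups = "data.frame", solubility = "data.frame",
              solubilityModel = "SolubilityModelOrNULL",
              peff = "numeric", particleDiameter = "numeric",
              particleDensity = "numeric", precipitationTime = "numeric",
              diffusionCoeff = "numeric", disposition = "DispositionParams"),
    prototype = list(particleDensity = 1.2, diffusionCoeff = NA_real_,
        solubilityModel = NULL))

setValidity("DrugSpec", function(object) {
    msgs <- .checkGroups(object@groups)
    if (!isTRUE(is.finite(object@mw) && object@mw > 0))
        msgs <- c(msgs, "molecular weight must be positive")
    if (!isTRUE(is.finite(object@peff) && object@peff > 0))
        msgs <- c(msgs, "Peff must be positive")
    if (!isTRUE(is.finite(object@particleDiameter) && object@particleDiameter > 0))
        msgs <- c(msgs, "particle diameter must be positive")
    if (!isTRUE(is.finite(object@particleDensity) && object@particleDensity > 0))
        msgs <- c(msgs, "particle density must be positive")
    if (!isTRUE(is.finite(object@precipitationTime) && object@precipitationTime > 0))
        msgs <- c(msgs, "precipitation time must be positive")
    sol <- object@solubility
    if (!is.data.frame(sol) || !all(c("ph", "solubility") %in% names(sol)))
        msgs <- c(msgs, "'solubility' must have columns 'ph' and 'solubility'")
    else if (nrow(sol) && !all(is.finite(sol$solubility) & sol$solubility > 0))
        msgs <- c(msgs, "measured solubilities must be positive")
    if (length(msgs)) msgs else TRUE
})

#' Gastrointestinal tract physiology
#'
#' Ordered gut compartments (stomach followed by small-intestinal and
#' colonic segments) with fluid volumes, pH, transit times, absorption
#' geometry and bile-salt concentrations, plus the set of surgically
#' bypassed segments and the volume of water taken with the dose.
#'
#' @slot compartments data.frame, one row per segment in luminal order, with
#'   columns name, volume (resting fluid mL), percentFluid, ph, transit (h),
#'   radius (cm), length (cm), asf (absorption scale factor), bile (mM),
#'   absorptive (logical).
#' @slot bypassed character, names of segments excluded from luminal flow.
#' @slot doseWaterVolume mL of water ingested with the dose.
#' @slot subject physiology label: healthy, post_sg or post_oagb.
#' @exportClass GITract
setClass("GITract",
    slots = c(compartments = "data.frame", bypassed = "character",
              doseWaterVolume = "numeric", subject = "character"))

setValidity("GITract", function(object) {
    cmp <- object@compartments
    need <- c("name", "volume", "percentFluid", "ph", "transit", "radius",
              "length", "asf", "bile", "absorptive")
    msgs <- character(0)
    if (!all(need %in% names(cmp)))
        return(paste("compartments must have columns:",
                     paste(need, collapse = ", ")))
    if (cmp$name[1] != "stomach")
        msgs <- c(msgs, "the first compartment must be the stomach")
    if (isTRUE(cmp$absorptive[1]))
        msgs <- c(msgs, "the stomach must be non-absorptive")
    if (!all(cmp$transit > 0))
        msgs <- c(msgs, "all transit times must be positive")
    if (!all(cmp$volume >= 0))
        msgs <- c(msgs, "fluid volumes must be non-negative")
    if (anyDuplicated(cmp$name))
        msgs <- c(msgs, "compartment names must be unique")
    if (!all(object@bypassed %in% cmp$name))
        msgs <- c(msgs, "bypassed names must match compartment names")
    if ("stomach" %in% object@bypassed)
        msgs <- c(msgs, "the stomach cannot be bypassed")
    if (!isTRUE(object@doseWaterVolume >= 0))
        msgs <- c(msgs, "doseWaterVolume must be non-negative")
    if (length(msgs)) msgs else TRUE
})

#' Result of an oral absorption-disposition simulation
#'
#' Time series of per-compartment undissolved and dissolved drug, cumulative
#' absorbed drug per segment, drug excreted from the gut, plasma
#' concentration and hepatic portal inlet flux.
#'
#' @slot drug compound name.
#' @slot scenario physiology label.
#' @slot dose mg.
#' @slot times h.
#' @slot plasma plasma concentration, ng/mL.
#' @slot hepaticInletFlux absorbed drug flux entering the liver, mg/h
#'   (before first-pass extraction).
#' @slot solid,dissolved matrices [time x compartment] of luminal mass, mg.
#' @slot absorbed matrix [time x compartment] of cumulative absorbed mass, mg.
#' @slot exitSolid,exitDissolved cumulative mass excreted from the gut, mg.
#' @slot central amounts in the three disposition compartments, mg
#'   (matrix [time x 3]).
#' @exportClass SimulationResult
setClass("SimulationResult",
    slots = c(drug = "character", scenario = "character", dose = "numeric",
              times = "numeric", plasma = "numeric",
              hepaticInletFlux = "numeric", solid = "matrix",
              dissolved = "matrix", absorbed = "matrix",
              exitSolid = "numeric", exitDissolved = "numeric",
              central = "matrix"))

setValidity("SimulationResult", function(object) {
    n <- length(object@times)
    ok <- length(object@plasma) == n && nrow(object@solid) == n &&
        nrow(object@dissolved) == n && nrow(object@absorbed) == n
    if (!ok) "time series lengths are inconsistent" else TRUE
})

#' In vitro dissolution vessel
#'
#' @slot volume medium volume, mL.
#' @slot ph medium pH.
#' @slot temperature C (reported only; kinetics assume 37 C).
#' @slot rpm paddle rotation speed.
#' @slot apparatus "usp2_paddle" or "mini_paddle".
#' @exportClass DissolutionVessel
setClass("DissolutionVessel",
    slots = c(volume = "numeric", ph = "numeric", temperature = "numeric",
              rpm = "numeric", apparatus = "character"),
    prototype = list(temperature = 37, rpm = 100, apparatus = "usp2_paddle"))

setValidity("DissolutionVessel", function(object) {
    msgs <- character(0)
    if (!isTRUE(is.finite(object@volume) && object@volume > 0))
        msgs <- c(msgs, "vessel volume must be positive")
    if (!object@apparatus %in% c("usp2_paddle", "mini_paddle"))
        msgs <- c(msgs, "apparatus must be 'usp2_paddle' or 'mini_paddle'")
    if (length(msgs)) msgs else TRUE
})

#' Model validation report
#'
#' Paired observed/predicted pharmacokinetic parameters with fold errors,
#' verdicts against a fold-error criterion, and the coefficient of
#' determination across all pairs.
#'
#' @slot table data.frame with columns parameter, dose, observed, predicted,
#'   foldError (rounded to 2 decimals), within (logical).
#' @slot rSquared squared Pearson correlation of observed vs predicted.
#' @slot criterion fold-error acceptance bound (e.g. 1.25).
#' @exportClass ValidationReport
setClass("ValidationReport",
    slots = c(table = "data.frame", rSquared = "numeric",
              criterion = "numeric"))

setValidity("ValidationReport", function(object) {
    msgs <- character(0)
    if (nrow(object@table) && any(object@table$foldError <= 0))
        msgs <- c(msgs, "fold errors must be positive")
    if (isTRUE(is.finite(object@rSquared)) &&
        (object@rSquared < 0 || object@rSquared > 1))
        msgs <- c(msgs, "rSquared must lie in [0, 1]")
    if (length(msgs)) msgs else TRUE
})
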