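#' Construct a DispositionParams object
#'
#' @param cl clearance, L/h/kg.
#' @param vc central volume, L/kg.
#' @param k12,k21,k13,k31 inter-compartment rate constants, 1/h.
#' @param fpePercent hepatic first-pass extraction, percent.
#' @param bodyWeight kg.
#' @param bloodPlasmaRatio blood/plasma concentration ratio (metadata).
#' @param fractionUnboundPercent plasma fraction unbound, percent (metadata).
#' @return A \linkS4class{DispositionParams} object.
#' @examples
#' dispositionParams(cl = 0.925, vc = 0.8, k12 = 3.09, k21 = 2.1,
#'                   k13 = 0.448, k31 = 0.25, fpePercent = 83)
#' @export
dispositionParams <- function(cl, vc, k12 = 0, k21 = 0, k13 = 0, k31 = 0,
                              fpePercent = 0, bodyWeight = 70,
                              bloodPlasmaRatio = NA_real_,
                              fractionUnboundPercent = NA_real_) {
    new("DispositionParams", cl = cl, vc = vc, k12 = k12, k21 = k21,
        k13 = k13, k31 = k31, fpePercent = fpePercent,
        bodyWeight = bodyWeight, bloodPlasmaRatio = bloodPlasmaRatio,
        fractionUnboundPercent = fractionUnboundPercent)
}

#' Construct a DrugSpec object
#'
#' @param name compound name.
#' @param mw molecular weight, g/mol.
#' @param logP log10 octanol-water partition coefficient.
#' @param groups data.frame with columns \code{pka} and \code{kind}
#'   ("acid"/"base").
#' @param solubility data.frame with columns \code{ph} and \code{solubility}
#'   (mg/mL at 37 C).
#' @param peff effective intestinal permeability, cm/s.
#' @param particleDiameter um.
#' @param particleDensity g/mL.
#' @param precipitationTime s.
#' @param diffusionCoeff cm^2/s; \code{NA} derives it from \code{mw} via
#'   \code{\link{diffusionCoefficientFromMW}}.
#' @param disposition a \linkS4class{DispositionParams} object.
#' @param fitSolubility fit the pH-solubility model on construction?
#' @return A \linkS4class{DrugSpec} object.
#' @export
drugSpec <- function(name, mw, logP, groups = .emptyGroups(),
                     solubility, peff, particleDiameter = 100,
                     particleDensity = 1.2, precipitationTime = 900,
                     diffusionCoeff = NA_real_, disposition,
                     fitSolubility = TRUE) {
    obj <- new("DrugSpec", name = name, mw = mw, logP = logP,
               groups = groups, solubility = solubility,
               peff = peff, particleDiameter = particleDiameter,
               particleDensity = particleDensity,
               precipitationTime = precipitationTime,
               diffusionCoeff = diffusionCoeff, disposition = disposition)
    if (fitSolubility && nrow(solubility) >= 2)
        obj@solubilityModel <- fitSolubilityModel(solubility, groups)
    obj
}

#' Construct an in vitro dissolution vessel
#'
#' @param volume medium volume, mL.
#' @param ph medium pH.
#' @param temperature C.
#' @param rpm paddle speed.
#' @param apparatus "usp2_paddle" or "mini_paddle".
#' @return A \linkS4class{DissolutionVessel} object.
#' @export
dissolutionVessel <- function(volume, ph, temperature = 37, rpm = 100,
                              apparatus = c("usp2_paddle", "mini_paddle")) {
    new("DissolutionVessel", volume = volume, ph = ph,
        temperature = temperature, rpm = rpm,
        apparatus = match.arg(apparatus))
}

setMethod("show", "SolubilityModel", function(object) {
    cat("Capped Henderson-Hasselbalch solubility model\n")
    if (!object@fitted) {
        cat("  <unfitted>\n")
        return(invisible(NULL))
    }
    cat(sprintf("  intrinsic solubility S0: %.4g mg/mL\n", object@s0))
    if (nrow(object@groups)) {
        st <- .ionizationStates(object@groups)
        cat(sprintf("  %-26s factor\n", "state"))
        for (i in seq_along(object@factors))
            cat(sprintf("  %-26s %.4g\n", st$label[i], object@factors[i]))
    }
    invisible(NULL)
})

setMethod("show", "DispositionParams", function(object) {
    nc <- 1 + (object@k12 > 0) + (object@k13 > 0)
    cat(sprintf("%d-compartment disposition: CL %.4g L/h/kg, Vc %.4g L/kg\n",
                nc, object@cl, object@vc))
    cat(sprintf("  k12 %.4g  k21 %.4g  k13 %.4g  k31 %.4g (1/h)\n",
                object@k12, object@k21, object@k13, object@k31))
    cat(sprintf("  FPE %.3g%%, body weight %.3g kg, t1/2 %.3g h\n",
                object@fpePercent, object@bodyWeight,
                terminalHalfLife(object)))
    invisible(NULL)
})

setMethod("show", "DrugSpec", function(object) {
    cat(sprintf("DrugSpec: %s (MW %.2f g/mol, logP %.2f)\n",
                object@name, object@mw, object@logP))
    if (nrow(object@groups))
        cat(sprintf("  pKa: %s\n",
            paste(sprintf("%.2f (%s)", object@groups$pka,
                          object@groups$kind), collapse = "; ")))
    cat(sprintf("  measured solubility points: %d; model %s\n",
                nrow(object@solubility),
                if (is.null(object@solubilityModel)) "unfitted" else "fitted"))
    cat(sprintf("  Peff %.3g cm/s, particle %.3g um, precipitation %.3g s\n",
                object@peff, object@particleDiameter,
                object@precipitationTime))
    invisible(NULL)
})

setMethod("show", "GITract", function(object) {
    cat(sprintf("GITract (%s): %d compartments, %.0f mL dose water\n",
                object@subject, nrow(object@compartments),
                object@doseWaterVolume))
    st <- object@compartments[1, ]
    cat(sprintf("  stomach: %.0f mL, pH %.1f, transit %.2f h\n",
                st$volume, st$ph, st$transit))
    if (length(object@bypassed))
        cat("  bypassed:", paste(object@bypassed, collapse = ", "), "\n")
    invisible(NULL)
})

setMethod("show", "SimulationResult", function(object) {
    fa <- 100 * absorbedFraction(object)
    cat(sprintf("SimulationResult: %s %.4g mg, %s, %.3g h\n", object@drug,
                object@dose, object@scenario, max(object@times)))
    cat(sprintf("  Cmax %.4g ng/mL at %.3g h; fraction absorbed %.1f%%\n",
                max(object@plasma), object@times[which.max(object@plasma)],
                fa))
    invisible(NULL)
})

setMethod("show", "ValidationReport", function(object) {
    cat(sprintf("ValidationReport (criterion %.4g-fold, R^2 %.4f)\n",
                object@criterion, object@rSquared))
    print(object@table, row.names = FALSE)
    invisible(NULL)
})

#' @rdname plasmaProfile
#' @export
setGeneric("plasmaProfile", function(object) standardGeneric("plasmaProfile"))

#' Extract the plasma concentration-time profile
#'
#' @param object a \linkS4class{SimulationResult}.
#' @return data.frame with columns \code{t_h} and \code{conc_ng_mL}.
#' @export
setMethod("plasmaProfile", "SimulationResult", function(object)
    data.frame(t_h = object@times, conc_ng_mL = object@plasma))

#' @rdname absorbedFraction
#' @export
setGeneric("absorbedFraction", function(object, cumulative = FALSE)
    standardGeneric("absorbedFraction"))

#' Fraction of the dose absorbed
#'
#' @param object a \linkS4class{SimulationResult}.
#' @param cumulative return the full time course instead of the final value?
#' @return Final absorbed fraction (0-1), or a data.frame \code{t_h},
#'   \code{fraction_absorbed} when \code{cumulative = TRUE}.
#' @export
setMethod("absorbedFraction", "SimulationResult",
    function(object, cumulative = FALSE) {
        if (object@dose == 0) {
            fa <- rep(0, length(object@times))
        } else {
            fa <- rowSums(object@absorbed) / object@dose
        }
        if (cumulative)
            data.frame(t_h = object@times, fraction_absorbed = fa)
        else fa[length(fa)]
    })

#' @rdname dissolvedFraction
#' @export
setGeneric("dissolvedFraction", function(object, cumulative = FALSE)
    standardGeneric("dissolvedFraction"))

#' Cumulative in vivo dissolved fraction of the dose
#'
#' Fraction of the dose no longer in the solid state anywhere in (or
#' excreted from) the gut, i.e. the in vivo dissolution profile.
#'
#' @param object a \linkS4class{SimulationResult}.
#' @param cumulative return the full time course instead of the final value?
#' @return Final dissolved fraction (0-1), or a data.frame \code{t_h},
#'   \code{fraction_dissolved}.
#' @export
setMethod("dissolvedFraction", "SimulationResult",
    function(object, cumulative = FALSE) {
        if (object@dose == 0) {
            fd <- rep(0, length(object@times))
        } else {
            fd <- 1 - (rowSums(object@solid) + object@exitSolid) / object@dose
        }
        if (cumulative)
            data.frame(t_h = object@times, fraction_dissolved = fd)
        else fd[length(fd)]
    })

#' Accessors for DrugSpec components
#'
#' @param object a \linkS4class{DrugSpec}.
#' @return \code{solubilityModel} returns the fitted
#'   \linkS4class{SolubilityModel} (or NULL); \code{disposition} the
#'   \linkS4class{DispositionParams}.
#' @rdname drugSpec-accessors
#' @export
setGeneric("solubilityModel", function(object)
    standardGeneric("solubilityModel"))

#' @rdname drugSpec-accessors
#' @export
setMethod("solubilityModel", "DrugSpec", function(object)
    object@solubilityModel)

#' @rdname drugSpec-accessors
#' @export
setGeneric("disposition", function(object) standardGeneric("disposition"))

#' @rdname drugSpec-accessors
#' @export
setMethod("disposition", "DrugSpec", function(object) object@disposition)
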