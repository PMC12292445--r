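# Particle dissolution / precipitation kinetics and the in vitro vessel
# simulator. Canonical internal units: mg, mL, h, cm.

.DIFFUSION_LAYER_CAP_CM <- 30e-4  # 30 um, standard Johnson-model default

#' Johnson-type particle dissolution rate
#'
#' Nernst-Brunner flux for a monodisperse particle population:
#' dM/dt = 3 D M (Cs - C) / (rho h r), with diffusion-layer thickness
#' h = min(r, 30 um). The rate is clamped at zero when the medium is at or
#' above saturation (precipitation is handled separately by
#' \code{\link{precipitationFlux}}).
#'
#' @param undissolvedMass mg of solid drug.
#' @param radius current particle radius, um.
#' @param density particle true density, g/mL.
#' @param solubility local saturation solubility Cs, mg/mL.
#' @param concentration dissolved concentration C, mg/mL.
#' @param volume fluid volume, mL (must be positive).
#' @param diffusionCoeff cm^2/s.
#' @return Dissolution flux, mg/h (non-negative).
#' @export
dissolutionRate <- function(undissolvedMass, radius, density, solubility,
                            concentration, volume, diffusionCoeff) {
    stopifnot(undissolvedMass >= 0, radius >= 0, density > 0,
              solubility >= 0, concentration >= 0, diffusionCoeff >= 0)
    if (volume <= 0) stop("fluid volume must be positive")
    if (undissolvedMass == 0 || radius == 0) return(0)
    rCm <- radius * 1e-4
    h <- min(rCm, .DIFFUSION_LAYER_CAP_CM)
    dCmH <- diffusionCoeff * 3600
    rho <- density * 1000  # mg/cm^3
    3 * dCmH * undissolvedMass * max(solubility - concentration, 0) /
        (rho * h * rCm)
}

#' Precipitation flux of supersaturated dissolved drug
#'
#' First-order removal of the supersaturated excess with rate constant
#' 1/precipitationTime: flux = (C - Cs) * V / tau for C > Cs, else zero.
#'
#' @param concentration dissolved concentration, mg/mL.
#' @param solubility local saturation solubility, mg/mL.
#' @param precipitationTime mean precipitation time, s (positive).
#' @param volume fluid volume, mL.
#' @return Flux of drug returning to the solid state, mg/h.
#' @export
precipitationFlux <- function(concentration, solubility, precipitationTime,
                              volume) {
    stopifnot(precipitationTime > 0, volume >= 0)
    tauH <- precipitationTime / 3600
    max(concentration - solubility, 0) * volume / tauH
}

#' Simulate dissolution of a dose in a closed stirred vessel
#'
#' Closed-vessel mass balance between a monodisperse solid phase (cube-root
#' radius shrinkage) and the dissolved phase, at the vessel pH. Solubility
#' comes from the drug's fitted pH-solubility model; no bile salts are
#' present in vitro. Hydrodynamics enter only through the vessel volume (the
#' paddle-speed scaling of \code{\link{scaledPaddleRpm}} is a standalone
#' calculator).
#'
#' @param dose mg of drug in the vessel.
#' @param drug a \linkS4class{DrugSpec} with a fitted solubility model.
#' @param vessel a \linkS4class{DissolutionVessel}.
#' @param duration minutes.
#' @param by output step, minutes.
#' @return data.frame with columns \code{time_min}, \code{percent_dissolved},
#'   \code{conc_mg_mL}.
#' @examples
#' \donttest{
#' drug <- vardenafilFixture()
#' v <- dissolutionVessel(volume = 250, ph = 1, rpm = 100)
#' prof <- simulateInvitroDissolution(20, drug, v, duration = 90)
#' tail(prof, 1)
#' }
#' @export
simulateInvitroDissolution <- function(dose, drug, vessel, duration = 90,
                                       by = 0.5) {
    stopifnot(is(drug, "DrugSpec"), is(vessel, "DissolutionVessel"),
              dose > 0, duration > 0)
    cs <- solubilityAtPh(drug, vessel@ph)
    dCoef <- .drugDiffusionCoeff(drug)
    r0 <- drug@particleDiameter / 2          # um
    v <- vessel@volume
    rhs <- function(t, y, p) {
        solid <- max(y[1], 0); dis <- max(y[2], 0)
        conc <- dis / v
        r <- r0 * (solid / dose)^(1/3)
        dflux <- if (solid > 0)
            dissolutionRate(solid, r, drug@particleDensity, cs, conc, v,
                            dCoef) else 0
        pflux <- precipitationFlux(conc, cs, drug@precipitationTime, v)
        list(c(-dflux + pflux, dflux - pflux))
    }
    timesH <- seq(0, duration, by = by) / 60
    out <- deSolve::lsoda(c(solid = dose, dissolved = 0), timesH, rhs,
                          parms = NULL, rtol = 1e-8, atol = 1e-10)
    data.frame(time_min = timesH * 60,
               percent_dissolved = 100 * out[, "dissolved"] / dose,
               conc_mg_mL = out[, "dissolved"] / v)
}

#' Paddle speed matching agitation strength across vessels
#'
#' Equates the agitation strength epsilon ~ RPM^3 * D^5 / V between a
#' reference paddle vessel and a new geometry and solves for the new
#' rotation speed: RPM_new = RPM_ref * (D_ref^5 / D_new^5 * V_new /
#' V_ref)^(1/3).
#'
#' @param rpmRef reference paddle speed.
#' @param dRef,dNew paddle diameters (any common length unit).
#' @param vRef,vNew fluid volumes (any common volume unit).
#' @return Matched rotation speed, rpm.
#' @examples
#' scaledPaddleRpm(100, dRef = 75, vRef = 250, dNew = 42, vNew = 50)
#' @export
scaledPaddleRpm <- function(rpmRef, dRef, vRef, dNew, vNew) {
    if (any(c(rpmRef, dRef, vRef, dNew, vNew) <= 0))
        stop("all paddle dimensions, volumes and speeds must be positive")
    rpmRef * ((dRef / dNew)^5 * vNew / vRef)^(1/3)
}
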