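# Built-in parameter fixtures and synthetic concentration-profile
# generation, so every pipeline stage is testable without external data.

#' Vardenafil model input parameters
#'
#' The complete input set of the vardenafil oral-absorption model: MW 488.61
#' g/mol, logP 1.97, measured 37 C solubilities 30 (pH 1), 30 (pH 3), 27.4
#' (pH 5) and 0.05 (pH 7) mg/mL, pKa 4.24/7.76 (base) and 8.68 (acid), Peff
#' 5.00e-4 cm/s, 100 um particles, 900 s precipitation time, diffusion
#' coefficient 0.5913e-5 cm^2/s, and the three-compartment disposition
#' (CL 0.925 L/h/kg, Vc 0.800 L/kg, k12 3.090, k21 2.100, k13 0.448,
#' k31 0.250 1/h, FPE 83%, blood/plasma ratio 0.83, fu 5%) at 70 kg body
#' weight.
#'
#' @param fitSolubility fit the pH-solubility model on construction?
#' @return A \linkS4class{DrugSpec}.
#' @examples
#' vardenafilFixture()
#' @export
vardenafilFixture <- function(fitSolubility = TRUE) {
    drugSpec(
        name = "vardenafil",
        mw = 488.61,
        logP = 1.97,
        groups = data.frame(pka = c(4.24, 7.76, 8.68),
                            kind = c("base", "base", "acid")),
        solubility = data.frame(ph = c(1, 3, 5, 7),
                                solubility = c(30, 30, 27.4, 0.05)),
        peff = 5.00e-4,
        particleDiameter = 100,
        particleDensity = 1.2,
        precipitationTime = 900,
        diffusionCoeff = 0.5913e-5,
        disposition = dispositionParams(
            cl = 0.925, vc = 0.800, k12 = 3.090, k21 = 2.100,
            k13 = 0.448, k31 = 0.250, fpePercent = 83, bodyWeight = 70,
            bloodPlasmaRatio = 0.83, fractionUnboundPercent = 5),
        fitSolubility = fitSolubility)
}

#' Observed vardenafil pharmacokinetic parameters
#'
#' Mean observed single-dose fasted PK parameters used to validate the
#' model: 10 mg (Cmax 7.20 ng/mL, Tmax 0.95 h, AUC0-inf 27.29 ng h/mL) and
#' 20 mg (Cmax 16.30 ng/mL, Tmax 0.78 h, AUC0-inf 41.86 ng h/mL).
#'
#' @return data.frame with columns \code{parameter} (cmax/tmax/auc0inf),
#'   \code{dose} (mg) and \code{value}.
#' @export
observedPkFixture <- function() {
    data.frame(
        parameter = rep(c("cmax", "tmax", "auc0inf"), 2),
        dose = rep(c(10, 20), each = 3),
        value = c(7.20, 0.95, 27.29, 16.30, 0.78, 41.86))
}

# Evaluate a function with a locally seeded RNG, restoring global state.
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

#' Generate noisy synthetic concentration-time profiles
#'
#' Forward-simulates the compartmental model (IV bolus or first-order oral
#' absorption), multiplies log-normal measurement noise exp(N(0, sigma))
#' with sigma = cv/100, and censors values below the lower limit of
#' quantification. Identical seeds give identical profiles.
#'
#' @param params a \linkS4class{DispositionParams}.
#' @param dose mg.
#' @param route "iv" or "oral_first_order".
#' @param times sampling times, h.
#' @param cv coefficient of variation of the multiplicative noise, percent.
#' @param lloq lower limit of quantification, ng/mL; censored samples are
#'   dropped (rows listed in the "censored" attribute).
#' @param seed integer RNG seed.
#' @param ka first-order absorption rate constant, 1/h (oral route).
#' @param fApparent apparent oral bioavailability (oral route); defaults to
#'   1 - FPE.
#' @return data.frame(t_h, conc_ng_mL) with attribute "censored".
#' @export
generateNoisyProfiles <- function(params, dose,
                                  route = c("iv", "oral_first_order"),
                                  times, cv = 0, lloq = 0.1, seed = 1,
                                  ka = 1, fApparent = NULL) {
    route <- match.arg(route)
    stopifnot(is(params, "DispositionParams"), dose > 0, cv >= 0,
              all(times >= 0), all(diff(times) > 0))
    truth <- if (route == "iv") .bolusConc(params, dose, times)
    else {
        if (is.null(fApparent)) fApparent <- 1 - params@fpePercent / 100
        .oralFirstOrderConc(params, fApparent * dose, ka, times)
    }
    conc <- if (cv > 0)
        .withSeed(seed, truth * exp(stats::rnorm(length(times),
                                                 sd = cv / 100)))
    else truth
    censored <- which(conc < lloq)
    out <- data.frame(t_h = times, conc_ng_mL = conc)
    if (length(censored)) out <- out[-censored, , drop = FALSE]
    attr(out, "censored") <- censored
    out
}
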