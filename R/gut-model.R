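# Nine-compartment gastrointestinal transit-dissolution-absorption model
# coupled to linear mammillary disposition. Compartment geometry and transit
# defaults are standard fasted-human compartmental-absorption values; the
# physiology object only departs from them where the modeled scenario says
# so (reduced luminal percent-fluid, bariatric stomach changes, bypass).

.giDefaultTable <- function() {
    cmp <- data.frame(
        name = c("stomach", "duodenum", "jejunum1", "jejunum2",
                 "ileum1", "ileum2", "ileum3", "caecum", "asc_colon"),
        transit = c(0.25, 0.26, 0.95, 0.76, 0.59, 0.43, 0.31, 4.50, 13.50),
        radius  = c(9.67, 1.60, 1.50, 1.34, 1.18, 1.01, 0.85, 3.50, 2.50),
        length  = c(28.3, 15, 62, 62, 62, 62, 62, 13.75, 29.02),
        percentFluid = c(NA, 23, 23, 23, 23, 23, 23, 0.5, 0.5),
        ph   = c(1.3, 6.0, 6.2, 6.4, 6.6, 6.9, 7.4, 6.4, 6.8),
        bile = c(0, 3, 3, 3, 3, 3, 3, 0, 0),
        asf  = c(0, 1, 1, 1, 1, 1, 1, 1, 1),
        absorptive = c(FALSE, rep(TRUE, 8)),
        stringsAsFactors = FALSE)
    geo <- pi * cmp$radius^2 * cmp$length
    cmp$volume <- ifelse(is.na(cmp$percentFluid), NA,
                         geo * cmp$percentFluid / 100)
    cmp$volume[1] <- 50          # resting gastric fluid
    cmp
}

#' Default fasted-human gastrointestinal physiology
#'
#' Nine serial compartments (stomach, duodenum, two jejunal, three ileal,
#' caecum, ascending colon) with fasted-state transit times (small-intestinal
#' total 3.30 h), segment radii/lengths, pH ladder, fasted bile-salt levels
#' (3 mM in the bile-rich small intestine, none in stomach/colon) and
#' reduced luminal percent-fluid volumes (23% small intestine, 0.5% colon).
#' Stomach: 50 mL resting fluid, pH 1.3, 0.25 h fasted transit,
#' non-absorptive. The dose is taken with 250 mL of water.
#'
#' @param subject physiology label; only \code{"healthy"} is constructed
#'   directly (surgical states derive from it via
#'   \code{\link{applyBariatricModifications}}).
#' @return A \linkS4class{GITract}.
#' @export
defaultPhysiology <- function(subject = "healthy") {
    subject <- match.arg(subject, "healthy")
    new("GITract", compartments = .giDefaultTable(),
        bypassed = character(0), doseWaterVolume = 250, subject = subject)
}

#' Apply bariatric-surgery modifications to a healthy gut
#'
#' Sleeve gastrectomy (SG): stomach reduced to 10 mL resting fluid, gastric
#' pH 5.0, gastric transit 0.12 h, 50 mL dose water. One-anastomosis gastric
#' bypass (OAGB): as SG but gastric pH 7.0 and the duodenum and jejunum
#' excluded from luminal flow (gastric outflow routed directly to the
#' proximal ileum). All other compartments keep their fasted defaults.
#'
#' @param tract a healthy \linkS4class{GITract}.
#' @param surgery \code{"SG"} or \code{"OAGB"}.
#' @return The modified \linkS4class{GITract}.
#' @export
applyBariatricModifications <- function(tract, surgery = c("SG", "OAGB")) {
    stopifnot(is(tract, "GITract"))
    surgery <- match.arg(toupper(surgery), c("SG", "OAGB"))
    if (tract@subject != "healthy")
        stop("bariatric modifications must start from the healthy baseline, ",
             "got '", tract@subject, "'")
    cmp <- tract@compartments
    i <- match("stomach", cmp$name)
    cmp$volume[i] <- 10
    cmp$transit[i] <- 0.12
    cmp$ph[i] <- if (surgery == "SG") 5.0 else 7.0
    tract@compartments <- cmp
    tract@doseWaterVolume <- 50
    if (surgery == "OAGB") {
        tract@bypassed <- c("duodenum", "jejunum1", "jejunum2")
        tract@subject <- "post_oagb"
    } else {
        tract@subject <- "post_sg"
    }
    validObject(tract)
    tract
}

# Right-hand side of the coupled gut + disposition ODE system.
# State layout (n gut compartments):
#   y[1:n]          solid mass per compartment, mg
#   y[n+1:n]        dissolved mass per compartment, mg
#   y[2n+1:n]       cumulative absorbed per compartment, mg
#   y[3n+1], y[3n+2] cumulative solid / dissolved mass excreted, mg
#   y[3n+3:3]       amounts in central + peripheral compartments, mg
.oralRHS <- function(t, y, p) {
    n <- p$n
    solid <- pmax(y[seq_len(n)], 0)
    dis <- pmax(y[n + seq_len(n)], 0)
    exitS <- y[3 * n + 1]
    a <- y[3 * n + 2 + 1:3]

    vol <- p$vol
    vol[1] <- p$stomachRest + p$doseWater * exp(-t / p$transit[1])
    conc <- dis / vol

    totalSolid <- sum(solid) + max(exitS, 0)
    r <- p$r0 * max(totalSolid / p$dose, 0)^(1/3)   # um
    rCm <- max(r, 1e-4) * 1e-4
    h <- min(rCm, .DIFFUSION_LAYER_CAP_CM)

    under <- pmax(p$cs - conc, 0)
    dissFlux <- 3 * p$dCmH * solid * under / (p$rho * h * rCm)
    precFlux <- pmax(conc - p$cs, 0) * vol / p$tauH

    outS <- solid * p$kt
    outD <- dis * p$kt
    inS <- as.numeric(p$flow %*% outS)
    inD <- as.numeric(p$flow %*% outD)
    exitSFlux <- sum(outS[p$last])
    exitDFlux <- sum(outD[p$last])

    absFlux <- p$ka * dis
    hep <- sum(absFlux)

    dSolid <- -dissFlux + precFlux - outS + inS
    dDis <- dissFlux - precFlux - outD + inD - absFlux

    k <- p$k
    dA1 <- hep * (1 - p$fpe) - (k$k10 + k$k12 + k$k13) * a[1] +
        k$k21 * a[2] + k$k31 * a[3]
    dA2 <- k$k12 * a[1] - k$k21 * a[2]
    dA3 <- k$k13 * a[1] - k$k31 * a[3]

    list(c(dSolid, dDis, absFlux, exitSFlux, exitDFlux, dA1, dA2, dA3))
}

#' Simulate oral dosing through the gut and systemic disposition
#'
#' Per-compartment Johnson dissolution (bile-salt-enhanced, pH-dependent
#' solubility), first-order luminal transit skipping bypassed segments,
#' absorption of dissolved drug with rate constant ka_n = 2 Peff ASF_n /
#' R_n, precipitation of supersaturated drug, and hepatic first-pass
#' extraction of all absorbed drug before it reaches the central
#' compartment of the linear mammillary disposition model. Gastric fluid
#' volume starts at resting + dose water and decays first-order to resting
#' with the gastric transit rate; intestinal fluid volumes are static.
#'
#' @param drug a \linkS4class{DrugSpec} with a fitted solubility model.
#' @param tract a \linkS4class{GITract}.
#' @param dose mg (zero returns an all-zero result).
#' @param duration h.
#' @param dt output grid step, h.
#' @param disposition optional \linkS4class{DispositionParams} overriding
#'   \code{drug@disposition}.
#' @return A \linkS4class{SimulationResult}.
#' @examples
#' \donttest{
#' drug <- vardenafilFixture()
#' res <- simulateOralPBPK(drug, defaultPhysiology(), dose = 20)
#' res
#' }
#' @export
simulateOralPBPK <- function(drug, tract, dose, duration = 24, dt = 0.01,
                             disposition = NULL) {
    stopifnot(is(drug, "DrugSpec"), is(tract, "GITract"), dose >= 0,
              duration > 0)
    if (is.null(disposition)) disposition <- drug@disposition
    if (is.null(drug@solubilityModel) || !drug@solubilityModel@fitted)
        stop("drug has no fitted solubility model")
    cmp <- tract@compartments
    n <- nrow(cmp)
    times <- seq(0, duration, by = dt)
    cmpNames <- cmp$name

    if (dose == 0) {
        z <- matrix(0, length(times), n, dimnames = list(NULL, cmpNames))
        return(new("SimulationResult", drug = drug@name,
                   scenario = tract@subject, dose = 0, times = times,
                   plasma = numeric(length(times)),
                   hepaticInletFlux = numeric(length(times)),
                   solid = z, dissolved = z, absorbed = z,
                   exitSolid = numeric(length(times)),
                   exitDissolved = numeric(length(times)),
                   central = matrix(0, length(times), 3)))
    }

    active <- !(cmpNames %in% tract@bypassed)
    activeIdx <- which(active)
    # luminal flow: each active compartment feeds the next active one
    flow <- matrix(0, n, n)
    for (j in seq_along(activeIdx)[-length(activeIdx)])
        flow[activeIdx[j + 1], activeIdx[j]] <- 1
    last <- activeIdx[length(activeIdx)]

    kt <- ifelse(active, 1 / cmp$transit, 0)
    csAq <- solubilityAtPh(drug@solubilityModel, cmp$ph)
    cs <- bileSaltEnhancement(drug@logP, cmp$bile, csAq)
    peffCmH <- drug@peff * 3600
    ka <- ifelse(cmp$absorptive & active, 2 * peffCmH * cmp$asf / cmp$radius,
                 0)

    p <- list(n = n, dose = dose, vol = cmp$volume,
              stomachRest = cmp$volume[1],
              doseWater = tract@doseWaterVolume,
              transit = cmp$transit, kt = kt, flow = flow, last = last,
              cs = cs, ka = ka, r0 = drug@particleDiameter / 2,
              rho = drug@particleDensity * 1000,
              dCmH = .drugDiffusionCoeff(drug) * 3600,
              tauH = drug@precipitationTime / 3600,
              fpe = disposition@fpePercent / 100,
              k = list(k10 = disposition@cl / disposition@vc,
                       k12 = disposition@k12, k21 = disposition@k21,
                       k13 = disposition@k13, k31 = disposition@k31))

    y0 <- c(rep(0, 3 * n + 5))
    y0[1] <- dose
    out <- deSolve::lsoda(y0, times, .oralRHS, parms = p,
                          rtol = 1e-8, atol = 1e-10, maxsteps = 50000)
    if (attr(out, "istate")[1] < 0 || any(!is.finite(out)))
        stop("gut-disposition ODE integration failed (scenario ",
             tract@subject, ", dose ", dose, " mg); check drug and ",
             "physiology parameters")
    sol <- out[, 1 + seq_len(n), drop = FALSE]
    dis <- out[, 1 + n + seq_len(n), drop = FALSE]
    abs <- out[, 1 + 2 * n + seq_len(n), drop = FALSE]
    colnames(sol) <- colnames(dis) <- colnames(abs) <- cmpNames
    central <- out[, 1 + 3 * n + 2 + 1:3, drop = FALSE]
    plasma <- central[, 1] / (disposition@vc * disposition@bodyWeight) * 1000
    hep <- as.numeric(pmax(dis, 0) %*% ka)

    new("SimulationResult", drug = drug@name, scenario = tract@subject,
        dose = dose, times = times, plasma = plasma,
        hepaticInletFlux = hep, solid = sol, dissolved = dis,
        absorbed = abs, exitSolid = out[, 1 + 3 * n + 1],
        exitDissolved = out[, 1 + 3 * n + 2], central = central)
}

#' Regional absorption summary
#'
#' Percent of the dose absorbed from each gut segment at the end of the
#' simulation; the segments sum to the total fraction absorbed.
#'
#' @param result a \linkS4class{SimulationResult}.
#' @return data.frame with columns \code{segment} and \code{percent_of_dose}.
#' @export
regionalAbsorption <- function(result) {
    stopifnot(is(result, "SimulationResult"))
    final <- result@absorbed[nrow(result@absorbed), ]
    pct <- if (result@dose > 0) 100 * final / result@dose else final * 0
    data.frame(segment = colnames(result@absorbed),
               percent_of_dose = as.numeric(pct))
}

.SENSITIVITY_PARAMS <- c("precipitation_time", "particle_diameter", "peff",
                         "diffusion_coeff", "particle_density", "dose")

#' One-at-a-time parameter sensitivity analysis
#'
#' Reruns the oral simulation with one input scaled by each multiplier and
#' reports the relative change in Cmax and AUC0-inf against the unscaled
#' run.
#'
#' @param drug a \linkS4class{DrugSpec}.
#' @param tract a \linkS4class{GITract}.
#' @param parameter one of \code{"precipitation_time"},
#'   \code{"particle_diameter"}, \code{"peff"}, \code{"diffusion_coeff"},
#'   \code{"particle_density"}, \code{"dose"}.
#' @param multipliers numeric vector of scale factors.
#' @param dose mg.
#' @param duration h.
#' @return data.frame with columns multiplier, cmax, auc0inf,
#'   pct_change_cmax, pct_change_auc.
#' @export
sensitivityAnalysis <- function(drug, tract, parameter, multipliers,
                                dose = 20, duration = 24) {
    if (!parameter %in% .SENSITIVITY_PARAMS)
        stop("unknown parameter '", parameter, "'; available: ",
             paste(.SENSITIVITY_PARAMS, collapse = ", "))
    runOne <- function(m) {
        d <- drug; ds <- dose
        switch(parameter,
               precipitation_time = { d@precipitationTime <-
                   d@precipitationTime * m },
               particle_diameter = { d@particleDiameter <-
                   d@particleDiameter * m },
               peff = { d@peff <- d@peff * m },
               diffusion_coeff = { d@diffusionCoeff <-
                   .drugDiffusionCoeff(d) * m },
               particle_density = { d@particleDensity <-
                   d@particleDensity * m },
               dose = { ds <- ds * m })
        res <- simulateOralPBPK(d, tract, dose = ds, duration = duration)
        m <- pkMetrics(plasmaProfile(res))
        c(cmax = m$cmax, auc = m$auc0inf)
    }
    base <- runOne(1)
    rows <- t(vapply(multipliers, runOne, numeric(2)))
    data.frame(multiplier = multipliers,
               cmax = rows[, "cmax"], auc0inf = rows[, "auc"],
               pct_change_cmax = 100 * (rows[, "cmax"] / base["cmax"] - 1),
               pct_change_auc = 100 * (rows[, "auc"] / base["auc"] - 1))
}
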