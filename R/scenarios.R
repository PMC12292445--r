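# End-to-end study pipeline: build the drug model, validate the healthy
# scenario against observed PK, simulate the bariatric scenarios, and
# compute cross-scenario percent changes.

.SCENARIOS <- c("pre_surgery", "post_sg", "post_oagb")

.tractForScenario <- function(scenario) {
    base <- defaultPhysiology()
    switch(scenario,
           pre_surgery = base,
           post_sg = applyBariatricModifications(base, "SG"),
           post_oagb = applyBariatricModifications(base, "OAGB"),
           stop("unknown scenario '", scenario, "'"))
}

#' Run the full pre- vs post-bariatric simulation study
#'
#' For each requested scenario, simulates the main oral dose, extracts
#' plasma PK metrics, regional absorption and the in vivo dissolution
#' profile; validates the pre-surgery model against observed PK parameters
#' at the validation doses; and computes the percent change of Cmax, Tmax
#' and AUC0-inf in each surgical scenario relative to pre-surgery.
#'
#' @param drug a \linkS4class{DrugSpec}; defaults to the built-in
#'   vardenafil parameter set.
#' @param scenarios subset of \code{c("pre_surgery", "post_sg",
#'   "post_oagb")}. An empty vector yields a validation-only report.
#' @param mainDose mg, the dose compared across scenarios.
#' @param validationDoses mg, simulated pre-surgery and compared with
#'   \code{observed}.
#' @param observed observed PK fixture (data.frame parameter/dose/value) or
#'   NULL to skip validation.
#' @param duration simulated horizon, h.
#' @param dt output grid, h.
#' @param outDir optional directory; per-run profiles, the delta table, the
#'   validation report and a run manifest are written there.
#' @return list with elements \code{runs} (named list of
#'   \linkS4class{SimulationResult}), \code{metrics} (data.frame),
#'   \code{regional}, \code{deltas}, \code{validation}
#'   (\linkS4class{ValidationReport} or NULL) and \code{earlyExposure}
#'   (plasma concentration 0.5 h post-dose per scenario).
#' @export
runStudy <- function(drug = vardenafilFixture(), scenarios = .SCENARIOS,
                     mainDose = 20, validationDoses = c(10, 20),
                     observed = observedPkFixture(), duration = 24,
                     dt = 0.01, outDir = NULL) {
    stopifnot(all(scenarios %in% .SCENARIOS))
    if (is.null(drug@solubilityModel) || !drug@solubilityModel@fitted)
        drug@solubilityModel <- fitSolubilityModel(drug@solubility,
                                                   drug@groups)
    runs <- list()
    # validation runs (pre-surgery physiology)
    predicted <- NULL
    if (!is.null(observed)) {
        pre <- .tractForScenario("pre_surgery")
        predRows <- lapply(validationDoses, function(d) {
            key <- sprintf("pre_surgery_%gmg", d)
            res <- simulateOralPBPK(drug, pre, dose = d,
                                    duration = duration, dt = dt)
            runs[[key]] <<- res
            m <- pkMetrics(res)
            data.frame(parameter = c("cmax", "tmax", "auc0inf"), dose = d,
                       value = c(m$cmax, m$tmax, m$auc0inf))
        })
        predicted <- do.call(rbind, predRows)
    }
    validation <- if (!is.null(observed) && !is.null(predicted))
        validationReport(observed, predicted) else NULL

    for (sc in scenarios) {
        key <- sprintf("%s_%gmg", sc, mainDose)
        if (is.null(runs[[key]]))
            runs[[key]] <- simulateOralPBPK(drug, .tractForScenario(sc),
                                            dose = mainDose,
                                            duration = duration, dt = dt)
    }

    metrics <- do.call(rbind, lapply(names(runs), function(key) {
        m <- pkMetrics(runs[[key]])
        data.frame(run = key, scenario = runs[[key]]@scenario,
                   dose = runs[[key]]@dose, cmax = m$cmax, tmax = m$tmax,
                   auc0inf = m$auc0inf,
                   fractionAbsorbed = absorbedFraction(runs[[key]]),
                   peakHepaticFlux = max(runs[[key]]@hepaticInletFlux))
    }))

    regional <- lapply(runs, regionalAbsorption)

    deltas <- NULL
    surgical <- intersect(scenarios, c("post_sg", "post_oagb"))
    if ("pre_surgery" %in% scenarios && length(surgical)) {
        preKey <- sprintf("pre_surgery_%gmg", mainDose)
        mPre <- pkMetrics(runs[[preKey]])
        deltas <- do.call(rbind, lapply(surgical, function(sc) {
            mPost <- pkMetrics(runs[[sprintf("%s_%gmg", sc, mainDose)]])
            data.frame(scenario = sc,
                       parameter = c("cmax", "tmax", "auc0inf"),
                       pre = c(mPre$cmax, mPre$tmax, mPre$auc0inf),
                       post = c(mPost$cmax, mPost$tmax, mPost$auc0inf),
                       percent_change = percentChange(
                           c(mPre$cmax, mPre$tmax, mPre$auc0inf),
                           c(mPost$cmax, mPost$tmax, mPost$auc0inf)))
        }))
    }

    early <- vapply(scenarios, function(sc) {
        key <- sprintf("%s_%gmg", sc, mainDose)
        earlyExposure(plasmaProfile(runs[[key]]), 0.5)
    }, numeric(1))

    report <- list(runs = runs, metrics = metrics, regional = regional,
                   deltas = deltas, validation = validation,
                   earlyExposure = early)
    if (!is.null(outDir)) .writeStudyReport(report, drug, outDir)
    report
}

#' Interpolated plasma concentration at an early time point
#'
#' Linear interpolation of the profile at time \code{t}; refuses to
#' extrapolate outside the sampled span.
#'
#' @param profile data.frame(t_h, conc_ng_mL).
#' @param t h.
#' @return Concentration, ng/mL.
#' @export
earlyExposure <- function(profile, t) {
    stopifnot(length(t) == 1, is.finite(t))
    if (t < min(profile$t_h) || t > max(profile$t_h))
        stop("t = ", t, " h lies outside the profile span [",
             min(profile$t_h), ", ", max(profile$t_h), "]")
    stats::approx(profile$t_h, profile$conc_ng_mL, xout = t)$y
}

.writeStudyReport <- function(report, drug, outDir) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (key in names(report$runs))
        writeProfiles(report$runs[[key]], file.path(outDir, key))
    utils::write.csv(report$metrics, file.path(outDir, "metrics.csv"),
                     row.names = FALSE)
    if (!is.null(report$deltas))
        utils::write.csv(report$deltas, file.path(outDir, "deltas.csv"),
                         row.names = FALSE)
    if (!is.null(report$validation)) {
        v <- report$validation
        jsonlite::write_json(
            list(criterion = v@criterion, r_squared = v@rSquared,
                 table = v@table),
            file.path(outDir, "validation.json"), auto_unbox = TRUE,
            digits = NA)
    }
    writeRunManifest(outDir, config = list(
        drug = drug@name, doses = unique(report$metrics$dose),
        scenarios = unique(report$metrics$scenario)))
    invisible(outDir)
}
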