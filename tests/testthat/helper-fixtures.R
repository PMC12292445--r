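# Shared fixtures. Oral simulations are the expensive step; memoise them so
# the scenario runs are computed once per test session.

.cache <- new.env(parent = emptyenv())

cachedDrug <- function() {
    if (is.null(.cache$drug)) .cache$drug <- vardenafilFixture()
    .cache$drug
}

cachedRun <- function(scenario = c("pre_surgery", "post_sg", "post_oagb"),
                      dose = 20, duration = 24) {
    scenario <- match.arg(scenario)
    key <- sprintf("%s_%g_%g", scenario, dose, duration)
    if (is.null(.cache[[key]])) {
        tract <- switch(scenario,
            pre_surgery = defaultPhysiology(),
            post_sg = applyBariatricModifications(defaultPhysiology(), "SG"),
            post_oagb = applyBariatricModifications(defaultPhysiology(),
                                                    "OAGB"))
        .cache[[key]] <- simulateOralPBPK(cachedDrug(), tract, dose = dose,
                                          duration = duration)
    }
    .cache[[key]]
}

cachedStudy <- function() {
    if (is.null(.cache$study)) .cache$study <- runStudy(cachedDrug())
    .cache$study
}

# simple monoprotic base model used in solubility round-trip tests
monoproticBaseModel <- function(s0 = 0.01, factor = 1000, pka = 5) {
    groups <- data.frame(pka = pka, kind = "base")
    new("SolubilityModel", s0 = s0, groups = groups, factors = factor,
        fitted = TRUE, fit = list())
}
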