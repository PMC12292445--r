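test_that("healthy physiology carries the fasted defaults", {
    tr <- defaultPhysiology()
    cmp <- tr@compartments
    expect_identical(nrow(cmp), 9L)
    st <- cmp[cmp$name == "stomach", ]
    expect_equal(st$ph, 1.3)
    expect_equal(st$volume, 50)
    expect_equal(st$transit, 0.25)
    expect_false(st$absorptive)
    expect_equal(tr@doseWaterVolume, 250)
    expect_true(all(cmp$percentFluid[2:7] == 23))
    expect_true(all(cmp$percentFluid[8:9] == 0.5))
    # fasted small-intestinal transit sums to 3.30 h
    expect_equal(sum(cmp$transit[2:7]), 3.30, tolerance = 1e-9)
})

test_that("bariatric modifications rewire the tract as specified", {
    sg <- applyBariatricModifications(defaultPhysiology(), "SG")
    expect_equal(sg@compartments$ph[1], 5.0)
    expect_equal(sg@compartments$volume[1], 10)
    expect_equal(sg@compartments$transit[1], 0.12)
    expect_equal(sg@doseWaterVolume, 50)
    expect_length(sg@bypassed, 0)

    og <- applyBariatricModifications(defaultPhysiology(), "OAGB")
    expect_equal(og@compartments$ph[1], 7.0)
    expect_setequal(og@bypassed, c("duodenum", "jejunum1", "jejunum2"))
    # everything distal untouched
    expect_identical(og@compartments[5:9, c("ph", "transit", "volume")],
                     defaultPhysiology()@compartments[5:9,
                         c("ph", "transit", "volume")])

    expect_error(applyBariatricModifications(sg, "OAGB"), "healthy")
    expect_error(applyBariatricModifications(defaultPhysiology(), "RYGB"))
})

test_that("zero dose produces identically zero profiles", {
    r <- simulateOralPBPK(cachedDrug(), defaultPhysiology(), dose = 0,
                          duration = 2)
    expect_true(all(r@plasma == 0))
    expect_true(all(r@solid == 0))
    expect_identical(absorbedFraction(r), 0)
})

test_that("gut mass balance holds to 1e-6 relative at every step", {
    for (sc in c("pre_surgery", "post_oagb")) {
        r <- cachedRun(sc)
        total <- rowSums(r@solid) + rowSums(r@dissolved) +
            rowSums(r@absorbed) + r@exitSolid + r@exitDissolved
        expect_lt(max(abs(total - r@dose)) / r@dose, 1e-6)
        expect_true(all(r@solid >= -1e-9) && all(r@dissolved >= -1e-9))
    }
})

test_that("absorption is complete pre-surgery and the stomach absorbs nothing", {
    r <- cachedRun("pre_surgery")
    expect_gte(absorbedFraction(r), 0.95)
    reg <- regionalAbsorption(r)
    expect_equal(reg$percent_of_dose[reg$segment == "stomach"], 0)
    # segment percentages sum to the total fraction absorbed
    expect_equal(sum(reg$percent_of_dose), 100 * absorbedFraction(r),
                 tolerance = 1e-3)
})

test_that("AUC matches the closed-form mass-balance identity", {
    r <- cachedRun("pre_surgery")
    d <- disposition(cachedDrug())
    m <- pkMetrics(plasmaProfile(r))
    fa <- absorbedFraction(r)
    aucClosed <- 1000 * fa * (1 - d@fpePercent / 100) * r@dose /
        (d@cl * d@bodyWeight)
    expect_equal(m$auc0inf, aucClosed, tolerance = 0.02)
})

test_that("bypassed segments receive and absorb nothing after OAGB", {
    r <- cachedRun("post_oagb")
    bypass <- c("duodenum", "jejunum1", "jejunum2")
    expect_true(all(r@solid[, bypass] == 0))
    expect_true(all(r@dissolved[, bypass] == 0))
    reg <- regionalAbsorption(r)
    expect_true(all(reg$percent_of_dose[reg$segment %in% bypass] == 0))
    # distal segments dominate, and the healthy proximal share is larger
    regPre <- regionalAbsorption(cachedRun("pre_surgery"))
    proximal <- c("duodenum", "jejunum1", "jejunum2")
    expect_gt(sum(regPre$percent_of_dose[regPre$segment %in% proximal]),
              sum(reg$percent_of_dose[reg$segment %in% proximal]))
    distal <- c("ileum1", "ileum2", "ileum3", "caecum", "asc_colon")
    expect_gt(sum(reg$percent_of_dose[reg$segment %in% distal]),
              50)
})

test_that("removing a bypass never decreases the fraction absorbed", {
    og <- applyBariatricModifications(defaultPhysiology(), "OAGB")
    faFull <- absorbedFraction(cachedRun("post_oagb"))
    og@bypassed <- c("duodenum", "jejunum1")   # restore jejunum2
    faPartial <- absorbedFraction(
        simulateOralPBPK(cachedDrug(), og, dose = 20))
    expect_gte(faPartial, faFull - 1e-6)
})

test_that("dose scaling is linear while solubility is non-binding", {
    m10 <- pkMetrics(plasmaProfile(cachedRun("pre_surgery", dose = 10)))
    m20 <- pkMetrics(plasmaProfile(cachedRun("pre_surgery", dose = 20)))
    expect_equal(m20$auc0inf / m10$auc0inf, 2, tolerance = 0.02)
    expect_equal(m20$cmax / m10$cmax, 2, tolerance = 0.02)
})

test_that("sensitivity analysis reports relative metric changes", {
    expect_error(sensitivityAnalysis(cachedDrug(), defaultPhysiology(),
                                     "no_such_param", 1), "unknown")
    sens <- sensitivityAnalysis(cachedDrug(), defaultPhysiology(),
                                "precipitation_time", c(0.1, 1, 10),
                                dose = 20, duration = 12)
    expect_equal(sens$pct_change_cmax[sens$multiplier == 1], 0,
                 tolerance = 1e-9)
    expect_true(all(abs(sens$pct_change_cmax) < 10))
    expect_true(all(abs(sens$pct_change_auc) < 10))
})
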