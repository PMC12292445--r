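test_that("species fractions follow Henderson-Hasselbalch and sum to one", {
    base <- data.frame(pka = 4.24, kind = "base")
    # at pH = pKa a single base is half ionized
    fr <- fractionIonized(4.24, base)
    expect_equal(unname(fr["neutral"]), 0.5, tolerance = 1e-12)
    expect_equal(unname(fr["cation+1"]), 0.5, tolerance = 1e-12)
    # pH 1: ionized fraction 10^3.24 / (1 + 10^3.24)
    fr1 <- fractionIonized(1, base)
    expect_gt(fr1["cation+1"], 0.999)
    expect_equal(unname(fr1["cation+1"]),
                 10^3.24 / (1 + 10^3.24), tolerance = 1e-12)
    # no groups: single neutral species
    expect_identical(fractionIonized(7), c(neutral = 1))
    # sums to 1 across a pH sweep for the full triprotic set
    groups <- cachedDrug()@groups
    for (ph in seq(0, 14, by = 0.5))
        expect_equal(sum(fractionIonized(ph, groups)), 1, tolerance = 1e-12)
})

test_that("fitted vardenafil solubility model reproduces the endpoints", {
    m <- solubilityModel(cachedDrug())
    expect_s4_class(m, "SolubilityModel")
    expect_equal(solubilityAtPh(m, 1), 30, tolerance = 0.1)
    expect_equal(solubilityAtPh(m, 7), 0.05, tolerance = 0.2)
    expect_gte(solubilityAtPh(m, 1) / solubilityAtPh(m, 7), 600 * 0.999)
    # nonincreasing on [1, 7] for this base-dominated group set
    s <- solubilityAtPh(m, seq(1, 7, by = 0.1))
    expect_true(all(diff(s) <= 1e-6 * s[-1]))
    # bounded between S0 and S0 * (1 + sum of caps) everywhere
    sAll <- solubilityAtPh(m, seq(0, 14, by = 0.25))
    expect_true(all(sAll >= m@s0 - 1e-12))
    expect_true(all(sAll <= m@s0 * (1 + sum(m@factors - 1)) + 1e-9))
})

test_that("solubility evaluation demands a fitted model", {
    expect_error(solubilityAtPh(new("SolubilityModel"), 7), "fitted")
    d <- vardenafilFixture(fitSolubility = FALSE)
    expect_error(solubilityAtPh(d, 7), "fitted")
})

test_that("solubility fitting recovers a known forward model", {
    truth <- monoproticBaseModel(s0 = 0.01, factor = 1000, pka = 5)
    ph <- 1:7
    meas <- data.frame(ph = ph, solubility = solubilityAtPh(truth, ph))
    fit <- fitSolubilityModel(meas, truth@groups)
    expect_equal(fit@s0, truth@s0, tolerance = 0.1)
    expect_equal(fit@factors, truth@factors, tolerance = 0.1)
    # refit reproduces the profile itself
    expect_equal(solubilityAtPh(fit, ph), meas$solubility,
                 tolerance = 0.02)
})

test_that("flat profile without groups recovers the mean solubility", {
    meas <- data.frame(ph = c(2, 6), solubility = c(0.4, 0.4))
    fit <- fitSolubilityModel(meas)
    expect_equal(fit@s0, 0.4, tolerance = 1e-9)
    expect_equal(solubilityAtPh(fit, 4), 0.4, tolerance = 1e-9)
})

test_that("degenerate solubility input is rejected", {
    expect_error(fitSolubilityModel(
        data.frame(ph = c(3, 3), solubility = c(1, 2))), "degenerate")
    expect_error(fitSolubilityModel(
        data.frame(ph = 3, solubility = 1)), "two")
})

test_that("bile-salt solubilization is conservative and monotone", {
    expect_identical(bileSaltEnhancement(1.97, 0, 0.05), 0.05)
    expect_gt(bileSaltEnhancement(1.97, 3, 0.05), 0.05)
    conc <- seq(0, 10, by = 0.5)
    enh <- bileSaltEnhancement(1.97, conc, 0.05)
    expect_true(all(diff(enh) > 0))
    # more lipophilic drugs are solubilized more
    expect_gt(bileSaltEnhancement(3, 3, 0.05),
              bileSaltEnhancement(1, 3, 0.05))
})

test_that("diffusion coefficient correlation matches the printed value", {
    expect_equal(diffusionCoefficientFromMW(488.61), 0.5913e-5,
                 tolerance = 0.05)
    expect_equal(diffusionCoefficientFromMW(488.61),
                 9.9e-5 * 488.61^(-0.453), tolerance = 1e-12)
    expect_gt(diffusionCoefficientFromMW(488.61 / 2),
              diffusionCoefficientFromMW(488.61))
})
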