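vardenafilDisposition <- function()
    dispositionParams(cl = 0.925, vc = 0.800, k12 = 3.090, k21 = 2.100,
                      k13 = 0.448, k31 = 0.250, fpePercent = 83)

test_that("terminal half-life comes from the smallest eigenvalue", {
    p <- vardenafilDisposition()
    expect_equal(terminalHalfLife(p), 4.43, tolerance = 0.05 / 4.43)
    # root of the characteristic cubic located independently
    cubic <- function(s) s^3 + 7.04425 * s^2 + 4.9554875 * s + 0.60703125
    root <- uniroot(cubic, c(-0.2, -0.1), tol = 1e-12)$root
    expect_equal(terminalHalfLife(p), log(2) / abs(root), tolerance = 1e-6)
    # one-compartment limit: t1/2 = ln2 Vc / CL
    p1 <- dispositionParams(cl = 0.925, vc = 0.8)
    expect_equal(terminalHalfLife(p1), log(2) * 0.8 / 0.925,
                 tolerance = 1e-12)
})

test_that("disposition simulation matches the eigen solution", {
    p <- vardenafilDisposition()
    prof <- simulateDisposition(p, bolus = 10, duration = 24)
    # C(0+) = D / (Vc BW), in ng/mL
    expect_equal(prof$conc_ng_mL[1], 10 / (0.8 * 70) * 1000,
                 tolerance = 1e-9)
    # late log-slope equals the terminal eigenvalue
    tail <- prof[prof$t_h >= 16, ]
    slope <- -coef(lm(log(conc_ng_mL) ~ t_h, tail))[[2]]
    expect_equal(slope, log(2) / terminalHalfLife(p), tolerance = 0.01)
    # zero input is identically zero
    z <- simulateDisposition(p, bolus = 0, duration = 2)
    expect_true(all(z$conc_ng_mL == 0))
})

test_that("the system is linear: doubled input doubles concentrations", {
    p <- vardenafilDisposition()
    u1 <- function(t) ifelse(t < 2, 5, 0)
    u2 <- function(t) ifelse(t < 2, 10, 0)
    c1 <- simulateDisposition(p, input = u1, duration = 12, dt = 0.05)
    c2 <- simulateDisposition(p, input = u2, duration = 12, dt = 0.05)
    nz <- c1$conc_ng_mL > 1e-8
    expect_equal(c2$conc_ng_mL[nz] / c1$conc_ng_mL[nz],
                 rep(2, sum(nz)), tolerance = 1e-7)
})

test_that("fitting recovers noise-free three-compartment parameters", {
    p <- vardenafilDisposition()
    tms <- c(0.033, 0.083, 0.167, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8,
             12, 16, 24)
    prof <- generateNoisyProfiles(p, 10, "iv", times = tms, cv = 0)
    fit <- fitDisposition(prof, dose = 10)
    expect_equal(fit@cl, p@cl, tolerance = 0.01)
    expect_equal(fit@vc, p@vc, tolerance = 0.01)
    expect_equal(fit@k12, p@k12, tolerance = 0.02)
    expect_equal(fit@k21, p@k21, tolerance = 0.02)
    expect_true(fit@fit$converged)
})

test_that("fitting needs more observations than parameters", {
    p <- vardenafilDisposition()
    prof <- generateNoisyProfiles(p, 10, "iv", times = c(0.5, 1, 2, 4, 8),
                                  cv = 0)
    expect_error(fitDisposition(prof, dose = 10, nCompartments = 3),
                 "at least 7")
})

test_that("clearance is recovered within 10% under 10% noise", {
    p <- vardenafilDisposition()
    tms <- c(0.033, 0.083, 0.167, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8,
             12, 16, 24)
    cls <- vapply(1:20, function(seed) {
        prof <- generateNoisyProfiles(p, 10, "iv", times = tms, cv = 10,
                                      seed = seed)
        fitDisposition(prof, dose = 10)@cl
    }, numeric(1))
    expect_lt(abs(median(cls) / p@cl - 1), 0.10)
})

test_that("oral stage recovers absorption rate and bioavailability", {
    p <- vardenafilDisposition()
    tms <- c(0.033, 0.083, 0.167, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8,
             12, 16, 24)
    iv <- generateNoisyProfiles(p, 10, "iv", times = tms, cv = 0)
    oral <- generateNoisyProfiles(p, 20, "oral_first_order", times = tms,
                                  cv = 0, ka = 2)
    fit <- fitDisposition(iv, dose = 10, oralProfile = oral,
                          oralDose = 20)
    expect_equal(fit@fit$ka, 2, tolerance = 0.01)
    expect_equal(fit@fit$fApparent, 1 - 0.83, tolerance = 0.01)
})

test_that("NCA metrics agree with single-exponential closed forms", {
    t <- seq(0, 24, by = 0.01)
    prof <- data.frame(t_h = t, conc_ng_mL = 100 * exp(-0.5 * t))
    m <- pkMetrics(prof)
    expect_equal(m$auc0inf, 200, tolerance = 0.005)
    expect_equal(m$lambdaZ, 0.5, tolerance = 0.005)
    expect_identical(m$tmax, 0)      # monotone decreasing: first point
    expect_gte(m$auc0inf, m$auc0t)
    # linear interpolation of a triangle profile
    tri <- data.frame(t_h = c(0, 1, 2), conc_ng_mL = c(0, 10, 0))
    expect_equal(pkMetrics(tri)$auc0t, 10, tolerance = 1e-12)
})
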