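test_that("the full study report is internally consistent", {
    study <- cachedStudy()
    expect_named(study, c("runs", "metrics", "regional", "deltas",
                          "validation", "earlyExposure"))
    # four runs: two validation doses pre-surgery plus the two surgeries
    expect_setequal(names(study$runs),
                    c("pre_surgery_10mg", "pre_surgery_20mg",
                      "post_sg_20mg", "post_oagb_20mg"))
    # validation doses scale linearly pre-surgery
    m <- study$metrics
    a10 <- m$auc0inf[m$run == "pre_surgery_10mg"]
    a20 <- m$auc0inf[m$run == "pre_surgery_20mg"]
    expect_equal(a20 / a10, 2, tolerance = 0.02)
    # deltas carry both surgical scenarios and the sign convention
    expect_setequal(unique(study$deltas$scenario),
                    c("post_sg", "post_oagb"))
    cmaxRow <- study$deltas[study$deltas$scenario == "post_oagb" &
                            study$deltas$parameter == "cmax", ]
    expect_equal(cmaxRow$percent_change,
                 percentChange(cmaxRow$pre, cmaxRow$post))
})

test_that("pre-surgery validation passes the 1.25-fold criterion", {
    v <- cachedStudy()$validation
    expect_s4_class(v, "ValidationReport")
    expect_identical(nrow(v@table), 6L)
    expect_true(all(v@table$within))
})

test_that("post-bypass early exposure is markedly reduced", {
    study <- cachedStudy()
    expect_lt(study$earlyExposure[["post_oagb"]],
              study$earlyExposure[["pre_surgery"]])
    # and peak hepatic inlet flux is lower after bypass
    m <- study$metrics
    expect_lt(m$peakHepaticFlux[m$run == "post_oagb_20mg"],
              m$peakHepaticFlux[m$run == "pre_surgery_20mg"])
    # T_max is delayed after bypass
    expect_gt(m$tmax[m$run == "post_oagb_20mg"],
              m$tmax[m$run == "pre_surgery_20mg"])
})

test_that("an empty scenario list yields a validation-only report", {
    report <- runStudy(cachedDrug(), scenarios = character(0),
                       validationDoses = 10, duration = 12)
    expect_s4_class(report$validation, "ValidationReport")
    expect_null(report$deltas)
    expect_identical(names(report$runs), "pre_surgery_10mg")
})

test_that("early exposure interpolates linearly and refuses to extrapolate", {
    prof <- data.frame(t_h = c(0, 1, 2), conc_ng_mL = c(0, 10, 4))
    expect_equal(earlyExposure(prof, 0.5), 5)
    expect_equal(earlyExposure(prof, 1.5), 7)
    expect_equal(earlyExposure(prof, 1), 10)
    expect_error(earlyExposure(prof, 3), "outside")
    # at the grid maximum it returns Cmax itself
    r <- cachedStudy()$runs$pre_surgery_20mg
    m <- pkMetrics(plasmaProfile(r))
    expect_equal(earlyExposure(plasmaProfile(r), m$tmax), m$cmax)
})

test_that("study output directory holds profiles, deltas and a manifest", {
    dir <- withr::local_tempdir()
    report <- runStudy(cachedDrug(), scenarios = "pre_surgery",
                       validationDoses = 20, duration = 12, outDir = dir)
    expect_true(file.exists(file.path(dir, "metrics.csv")))
    expect_true(file.exists(file.path(dir, "validation.json")))
    expect_true(file.exists(file.path(dir, "run_manifest.json")))
    expect_true(file.exists(file.path(dir, "pre_surgery_20mg",
                                      "plasma.csv")))
})
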