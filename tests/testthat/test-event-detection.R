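test_that("onset detection is exact on clean baseline-then-ramp series", {
    t <- seq(0, 40, by = 0.2)
    y_down <- c(rep(0.6, 100), seq(0.6, 0.2, length.out = 20),
                rep(0.2, length(t) - 120))
    o <- detectOnset(t, y_down, detectionParams(), "decrease")
    expect_true(o$found)
    expect_equal(o$onset, t[101])

    y_up <- c(rep(0.35, 80), seq(0.35, 0.9, length.out = 10),
              seq(0.9, 0.15, length.out = 10), rep(0.15, length(t) - 100))
    o2 <- detectOnset(t, y_up, detectionParams(), "increase")
    expect_true(o2$found)
    expect_equal(o2$onset, t[81])
})

test_that("onset error under Gaussian noise stays within a few frames", {
    t <- seq(0, 40, by = 0.2)
    y <- c(rep(0.6, 100), seq(0.6, 0.2, length.out = 20),
           rep(0.2, length(t) - 120))
    set.seed(71)
    errs <- replicate(200, {
        o <- detectOnset(t, y + rnorm(length(y), sd = 0.05),
                         detectionParams(), "decrease")
        if (o$found) (o$onset - t[101]) / 0.2 else NA_real_
    })
    expect_true(all(!is.na(errs)))
    expect_lte(median(abs(errs)), 2)
    expect_lte(unname(stats::quantile(abs(errs), 0.95)), 5)
})

test_that("flat, short and invalid series yield no onset, with a reason", {
    t <- seq(0, 30, by = 0.2)
    set.seed(5)
    o <- detectOnset(t[1:120], rnorm(120, 0.5, 0.05), detectionParams(),
                     "decrease")
    expect_false(o$found)
    o2 <- detectOnset(t[1:4], c(0.5, 0.5, NA, 0.5), detectionParams(), "any")
    expect_false(o2$found)
    expect_match(o2$reason, "min_segment")
})

test_that("bleach steps are dated exactly on clean traces", {
    dt <- 0.1
    frame <- 0:299
    y638_cy5 <- ifelse(frame < 150, 1000, 0)
    df <- data.frame(molecule_id = 0L, frame = frame, time_s = frame * dt,
                     excitation = ifelse(frame %% 2L == 0L, 532L, 638L),
                     I_cy3 = 500, I_cy5 = y638_cy5, I_a750 = 0)
    bl <- detectBleachSteps(traceSet(df))
    ## first 638 frame at/after frame 150 is frame 151
    expect_equal(bl$bleach_cy5_s, 151 * dt)
    expect_true(bl$single_step)

    ## constant trace: no steps, vacuously single-step
    df2 <- df; df2$I_cy5 <- 800
    bl2 <- detectBleachSteps(traceSet(df2))
    expect_equal(bl2$bleach_cy5_s, Inf)
    expect_true(bl2$single_step)

    ## two equal steps (doubly labelled): not single-step
    df3 <- df
    df3$I_cy5 <- ifelse(frame < 100, 1000, ifelse(frame < 200, 500, 0))
    bl3 <- detectBleachSteps(traceSet(df3))
    expect_false(bl3$single_step)

    ## short trace: flagged only
    bl4 <- detectBleachSteps(traceSet(df[1:10, ]))
    expect_true(bl4$too_short)
    expect_true(is.na(bl4$single_step))
})

test_that("noise-free events are recovered within one ALEX cycle", {
    cfg <- kineticConfig(n_molecules = 20L, duration = 80, seed = 23L,
                         k_init = 0.2,
                         bleach_rate_cy3 = 0, bleach_rate_cy5 = 0,
                         bleach_rate_a750 = 0)
    tls <- sampleKinetics(cfg)
    ts <- renderTraces(tls, noiseless_photo())
    res <- analyzeTraces(ts, correctionParamsFromPhoto(noiseless_photo()))
    ev <- traceData(res$events)
    truth <- traceData(tls)
    cyc <- 0.2
    done <- truth$t_exit_onset + cfg@d_exit < cfg@duration
    for (i in which(done)) {
        row <- ev[ev$molecule_id == truth$molecule_id[i], ]
        expect_equal(row$flag, "complete")
        expect_lte(abs(row$t_lag_s - truth$t_lag[i]), cyc)
    }
})

test_that("bleach-censored molecules are flagged, and lags are never negative", {
    ## no transitions, early Cy5 bleach: no event observable
    tls <- make_static_timelines(bleach_cy5 = 2, n = 1L, duration = 40,
                                 seed = 3L)
    res <- analyzeTraces(renderTraces(tls, photoConfig(), seed = 8L),
                         default_inverse_params())
    expect_equal(traceData(res$events)$flag, "no_event")

    ## entry transition, then Cy5 bleach before the exit transition
    cfg <- kineticConfig(n_molecules = 1L, duration = 60, seed = 4L)
    tlc <- sampleKinetics(cfg)
    tlc@data$t_exit_onset <- 1e6
    tlc@data$t_entry_onset <- 10
    tlc@data$t_exit_onset <- 55
    tlc@data$t_lag <- 45
    tlc@data$bleach_cy3 <- Inf; tlc@data$bleach_a750 <- Inf
    tlc@data$bleach_cy5 <- 30
    res2 <- analyzeTraces(renderTraces(tlc, photoConfig(), seed = 9L),
                          default_inverse_params())
    ev2 <- traceData(res2$events)
    expect_match(ev2$flag, "entry_only")
    expect_match(ev2$flag, "censored_by_bleach")
    expect_true(is.na(ev2$t_exit_s))
    expect_gt(ev2$t_censor_s, 0)

    ## negative lags are structurally impossible
    cfg3 <- kineticConfig(n_molecules = 30L, duration = 80, seed = 29L,
                          k_init = 0.2)
    res3 <- analyzeTraces(renderTraces(sampleKinetics(cfg3), photoConfig(),
                                       seed = 30L),
                          default_inverse_params())
    lags <- traceData(res3$events)$t_lag_s
    expect_true(all(lags[!is.na(lags)] >= 0))
    diag <- attr(traceData(res3$events), "unconstrained_exit_before_entry")
    expect_true(is.numeric(diag) && diag >= 0 && diag <= 1)
})

test_that("multi-step molecules are excluded from event detection", {
    frame <- 0:399
    dt <- 0.1
    I_cy5 <- ifelse(frame < 100, 1000, ifelse(frame < 250, 500, 0))
    df <- data.frame(molecule_id = 0L, frame = frame, time_s = frame * dt,
                     excitation = ifelse(frame %% 2L == 0L, 532L, 638L),
                     I_cy3 = 500, I_cy5 = I_cy5, I_a750 = 100)
    ts <- traceSet(df)
    res <- analyzeTraces(ts, correctionParams())
    expect_equal(traceData(res$events)$flag, "multi_step_bleach")
})
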