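test_that("sampled lag times follow the configured exponential mean", {
    cfg <- kineticConfig(atp_uM = 100, n_molecules = 100000L, seed = 11L)
    tau <- meanLag(cfg)
    lags <- traceData(sampleKinetics(cfg))$t_lag
    expect_lt(abs(mean(lags) - tau) / tau, 0.01)
})

test_that("the lag rate saturates at k_max and rejects zero ATP", {
    cfg <- kineticConfig(atp_uM = 1e9, k_max = 0.25)
    expect_equal(1 / meanLag(cfg), 0.25, tolerance = 1e-6)
    expect_error(kineticConfig(atp_uM = 0), "atp_uM must be > 0")
})

test_that("timeline sampling is deterministic under a fixed seed", {
    a <- traceData(sampleKinetics(kineticConfig(n_molecules = 50L, seed = 3L)))
    b <- traceData(sampleKinetics(kineticConfig(n_molecules = 50L, seed = 3L)))
    expect_identical(a, b)
})

test_that("entry onset precedes exit onset for every generated molecule", {
    d <- traceData(sampleKinetics(kineticConfig(n_molecules = 1000L,
                                                seed = 13L)))
    expect_true(all(d$t_exit_onset >= d$t_entry_onset))
    gt <- timelineFret(sampleKinetics(kineticConfig(n_molecules = 2L,
                                                    seed = 5L)),
                       0L, seq(0, 200, by = 0.5))
    expect_true(all(gt$E1 >= 0 & gt$E1 <= 1))
    expect_true(all(gt$E2 >= 0 & gt$E2 <= 1))
})

test_that("lag samples pass a KS test against the exponential in >= 98/100 runs", {
    cfg0 <- kineticConfig(atp_uM = 100, n_molecules = 5000L)
    tau <- meanLag(cfg0)
    pass <- vapply(seq_len(100L), function(i) {
        lags <- traceData(sampleKinetics(cfg0, seed = 1000L + i))$t_lag
        stats::ks.test(lags, stats::pexp, rate = 1 / tau)$p.value > 0.01
    }, logical(1))
    expect_gte(sum(pass), 98L)
})

test_that("the ground-truth table mirrors the sampled timelines", {
    tls <- make_static_timelines(n = 1L)
    tls@data$t_entry_onset <- 3; tls@data$t_lag <- 5
    tls@data$t_exit_onset <- 8
    gt <- traceData(groundTruthTable(tls))
    expect_equal(unname(unlist(gt[1L, c("t_entry_s", "t_exit_s", "t_lag_s")])),
                 c(3, 8, 5))

    tl10 <- sampleKinetics(kineticConfig(n_molecules = 10L, seed = 21L))
    expect_identical(traceData(groundTruthTable(tl10))$t_lag_s,
                     traceData(tl10)$t_lag)
})

test_that("noiseless rendering splits photons by the cascade rule", {
    ## crosstalk-free, unit-gain photophysics; constant E1 = 0.7, E2 = 0
    photo <- noiseless_photo(g_cy3 = 1, g_a750 = 1, d_cy5_532 = 0,
                             d_a750_638 = 0, b_cy3_cy5 = 0, b_cy5_a750 = 0)
    cfg <- kineticConfig(n_molecules = 1L, duration = 10, seed = 2L,
                         E_exit0 = 0.7, E_entry0 = 0, E_entry_peak = 0.5,
                         E_entry1 = 0.1,
                         bleach_rate_cy3 = 0, bleach_rate_cy5 = 0,
                         bleach_rate_a750 = 0)
    tls <- sampleKinetics(cfg)
    tls@data$t_exit_onset <- 1e6 + 1
    tls@data$t_entry_onset <- 1e6
    tls@data$t_lag <- 1
    ts <- renderTraces(tls, photo)
    d <- traceData(ts)
    s532 <- d[d$excitation == 532L, ]
    N <- photo@photon_budget
    expect_equal(s532$I_cy3, rep(0.3 * N, nrow(s532)), tolerance = 1e-12)
    expect_equal(s532$I_cy5, rep(0.7 * N, nrow(s532)), tolerance = 1e-12)
    expect_equal(s532$I_a750, rep(0, nrow(s532)), tolerance = 1e-12)
    fr <- computeFret(applyCorrections(pairAlexFrames(ts),
                                       correctionParams()))
    expect_equal(traceData(fr)$E_exit,
                 rep(0.7, nrow(traceData(fr))), tolerance = 1e-12)

    ## E2 = 1: every Cy5-destined photon arrives in the A750 channel
    cfg2 <- kineticConfig(n_molecules = 1L, duration = 10, seed = 2L,
                          E_entry0 = 0.9, E_entry_peak = 1, E_entry1 = 0.1,
                          d_rise = 1e-3, d_fall = 1e9,  # hold E2 at the peak
                          bleach_rate_cy3 = 0, bleach_rate_cy5 = 0,
                          bleach_rate_a750 = 0)
    tls2 <- sampleKinetics(cfg2)
    tls2@data$t_exit_onset <- 1e6
    tls2@data$t_entry_onset <- -1   # peak reached before the trace starts
    tls2@data$t_lag <- 1e6 + 1
    ts2 <- renderTraces(tls2, photo)
    d2 <- traceData(ts2)
    s638 <- d2[d2$excitation == 638L & d2$time_s > 1, ]
    expect_equal(s638$I_cy5, rep(0, nrow(s638)), tolerance = 1e-5)
    expect_equal(s638$I_a750, rep(N, nrow(s638)), tolerance = 1e-5)
})

test_that("expected 532 nm totals conserve the photon budget", {
    ## equal g factors, no crosstalk: the three-way split sums to the budget
    ## regardless of E1(t), E2(t)
    photo <- noiseless_photo(g_cy3 = 1, g_a750 = 1, d_cy5_532 = 0,
                             d_a750_638 = 0, b_cy3_cy5 = 0, b_cy5_a750 = 0)
    cfg <- kineticConfig(n_molecules = 4L, duration = 40, seed = 8L,
                         k_init = 0.5,
                         bleach_rate_cy3 = 0, bleach_rate_cy5 = 0,
                         bleach_rate_a750 = 0)
    d <- traceData(renderTraces(sampleKinetics(cfg), photo))
    s532 <- d[d$excitation == 532L, ]
    total <- s532$I_cy3 + s532$I_cy5 + s532$I_a750
    expect_equal(total, rep(photo@photon_budget, length(total)),
                 tolerance = 1e-9)
})
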