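test_that("the exponential MLE is the sample mean and recovers the rate", {
    expect_equal(fitExponential(c(1, 2, 3), min_events = 3L)@mean_lag, 2.0)
    set.seed(61)
    x <- rexp(5000, rate = 1 / 4.9)
    f <- fitExponential(x)
    expect_lt(abs(f@mean_lag - 4.9), 2 * f@sem)
    expect_gt(f@ks_p, 1e-4)
    expect_error(fitExponential(c(1, 2, 3)), "at least 5")
})

test_that("the censored MLE matches brute-force likelihood maximisation", {
    f <- fitExponential(c(1, 2), censored = 10, method = "mle_censored",
                        min_events = 2L)
    expect_equal(f@mean_lag, 6.5)
    ## independent oracle: dense grid over the censored log-likelihood
    loglik <- function(tau, x, cens)
        -length(x) * log(tau) - (sum(x) + sum(cens)) / tau
    grid <- exp(seq(log(0.1), log(100), length.out = 200000L))
    tau_grid <- grid[which.max(loglik(grid, c(1, 2), 10))]
    expect_equal(f@mean_lag, tau_grid, tolerance = 1e-4)

    ## censoring adds observation time: censored MLE >= uncensored MLE
    set.seed(62)
    x <- rexp(50, 1 / 5); cens <- rexp(20, 1 / 3)
    fu <- fitExponential(x)
    fc <- fitExponential(x, censored = cens, method = "mle_censored")
    expect_gte(fc@mean_lag, fu@mean_lag)
})

test_that("the MLE is order-invariant and scales with the time unit", {
    set.seed(63)
    x <- rexp(200, 1 / 7)
    f1 <- fitExponential(x)
    f2 <- fitExponential(sample(x))
    expect_equal(f1@mean_lag, f2@mean_lag)
    f_ms <- fitExponential(1000 * x)
    expect_equal(f_ms@mean_lag, 1000 * f1@mean_lag)
})

test_that("bootstrap SEM approximates mean/sqrt(n) for exponential samples", {
    set.seed(64)
    x <- rexp(200, 1 / 4.9)
    f <- fitExponential(x)
    expect_lt(abs(f@sem - f@mean_lag / sqrt(200)) / (f@mean_lag / sqrt(200)),
              0.2)
})

test_that("binned least squares agrees with the MLE on large samples", {
    set.seed(65)
    x <- rexp(3000, 1 / 4.9)
    fb <- fitExponential(x, method = "binned_ls")
    expect_lt(abs(fb@mean_lag - 4.9) / 4.9, 0.1)
})

test_that("the hyperbolic ATP fit is exact on noiseless points", {
    S <- c(20, 50, 100, 200, 500)
    pts <- data.frame(atp_uM = S, mean_lag = (60 + S) / (0.5 * S),
                      sem = 1e-6)
    f <- fitAtpDependence(pts)
    expect_equal(f@k_max, 0.5, tolerance = 1e-6)
    expect_equal(f@K_app, 60, tolerance = 1e-6)
    ## hyperbola midpoint: v(K_app) = k_max / 2
    expect_equal(f@k_max * 60 / (f@K_app + 60), 0.25, tolerance = 1e-6)
    expect_error(fitAtpDependence(pts[1:2, ]), "at least 3")
})

test_that("population FRET histograms summarise before/after levels", {
    ## constant-FRET molecules pile into a single bin
    tls <- make_static_timelines(n = 5L, duration = 20, seed = 41L)
    ts <- renderTraces(tls, noiseless_photo())
    fr <- computeFret(applyCorrections(pairAlexFrames(ts),
                                       default_inverse_params(noiseless_photo())))
    ev <- eventTable(data.frame(molecule_id = 0:4, t_entry_s = NA_real_,
                                t_exit_s = NA_real_, t_lag_s = NA_real_,
                                flag = "no_event"))
    h <- buildFretHistograms(fr, "before_event", ev)
    expect_equal(h$entry$mean, 0.35, tolerance = 1e-9)
    expect_equal(sum(h$entry$counts > 0), 1L)
    expect_equal(h$exit$mean, 0.7, tolerance = 1e-9)
    expect_equal(h$entry$n, 5L)

    ## synthetic before/after populations at the generator levels
    cfg <- kineticConfig(n_molecules = 12L, duration = 80, seed = 42L,
                         k_init = 0.5,
                         bleach_rate_cy3 = 0, bleach_rate_cy5 = 0,
                         bleach_rate_a750 = 0)
    tl2 <- sampleKinetics(cfg)
    ts2 <- renderTraces(tl2, photoConfig())
    ## ground-truth bleach annotations and events isolate the histogram step
    truth <- groundTruthTable(tl2)
    fr2 <- computeFret(applyCorrections(pairAlexFrames(ts2),
                                        default_inverse_params()),
                       bleach = truth)
    before <- buildFretHistograms(fr2, "before_event", truth)
    after <- buildFretHistograms(fr2, "after_event", truth)
    expect_lt(abs(before$entry$mean - cfg@E_entry0), 0.05)
    expect_lt(abs(before$exit$mean - cfg@E_exit0), 0.05)
    expect_lt(abs(after$exit$mean - cfg@E_exit1), 0.07)
    expect_lt(abs(after$entry$mean - cfg@E_entry1), 0.1)

    ## no molecules: empty histogram with explicit n = 0
    ev0 <- eventTable(ev@data[0L, ])
    h0 <- buildFretHistograms(fr, "before_event", ev0)
    expect_equal(h0$entry$n, 0L)
    expect_true(all(h0$entry$counts == 0))
})
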