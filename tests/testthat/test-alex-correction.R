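## build an AlexSeries directly from channel values
make_alex <- function(I532_cy3, I532_cy5, I532_a750, I638_cy5, I638_a750) {
    n <- length(I532_cy3)
    d <- data.frame(molecule_id = 0L, time_s = seq_len(n) * 0.2 - 0.1,
                    t532_s = seq_len(n) * 0.2 - 0.2,
                    t638_s = seq_len(n) * 0.2 - 0.1,
                    I532_cy3 = I532_cy3, I532_cy5 = I532_cy5,
                    I532_a750 = I532_a750, I638_cy5 = I638_cy5,
                    I638_a750 = I638_a750)
    new("AlexSeries", data = d, dropped = c("0" = 0L), manifest = manifest())
}

test_that("the FRET observables are the stated intensity ratios", {
    al <- make_alex(c(30, 100, 1), c(50, 0, 2), c(20, 0, 1),
                    c(25, 40, 1), c(75, 10, 1))
    fr <- traceData(computeFret(applyCorrections(al, correctionParams()),
                                denominator_floor = 10))
    expect_equal(fr$E_exit[1L], 0.70)
    expect_equal(fr$E_entry[1L], 0.75)
    expect_equal(fr$E_exit[2L], 0)          # donor-only record
    ## records below the denominator floor are flagged, never dropped
    expect_false(fr$valid_exit[3L])
    expect_false(fr$valid_entry[3L])
    expect_equal(nrow(fr), 3L)
})

test_that("FRET values are invariant to a common intensity scale", {
    set.seed(42)
    base <- abs(matrix(rnorm(50, 100, 30), ncol = 5)) + 50
    al1 <- make_alex(base[, 1], base[, 2], base[, 3], base[, 4], base[, 5])
    al2 <- make_alex(3.7 * base[, 1], 3.7 * base[, 2], 3.7 * base[, 3],
                     3.7 * base[, 4], 3.7 * base[, 5])
    p <- correctionParams(d_cy5_532 = 0.05, d_a750_638 = 0.05,
                          b_cy3_cy5 = 0.1, b_cy5_a750 = 0.1,
                          s_cy3 = 0.8, s_a750 = 1.2)
    f1 <- traceData(computeFret(applyCorrections(al1, p)))
    f2 <- traceData(computeFret(applyCorrections(al2, p)))
    expect_equal(f2$E_exit, f1$E_exit, tolerance = 1e-12)
    expect_equal(f2$E_entry, f1$E_entry, tolerance = 1e-12)
})

test_that("zero-crosstalk corrections are the identity and zeros map to zeros", {
    al <- make_alex(c(10, 0), c(20, 0), c(30, 0), c(40, 0), c(50, 0))
    out <- traceData(applyCorrections(al, correctionParams()))
    for (col in c("I532_cy3", "I532_cy5", "I532_a750", "I638_cy5",
                  "I638_a750"))
        expect_equal(out[[col]], traceData(al)[[col]])
    p <- correctionParams(d_cy5_532 = 0.05, b_cy3_cy5 = 0.1,
                          b_cy5_a750 = 0.1, d_a750_638 = 0.05,
                          s_cy3 = 0.77, s_a750 = 1.25)
    out0 <- traceData(applyCorrections(al, p))[2L, ]
    expect_equal(unname(unlist(out0[c("I532_cy3", "I532_cy5", "I532_a750",
                                      "I638_cy5", "I638_a750")])),
                 rep(0, 5))
})

test_that("corrections invert the noiseless forward model exactly", {
    photo <- noiseless_photo()
    cfg <- kineticConfig(n_molecules = 4L, duration = 60, seed = 17L,
                         k_init = 0.2,
                         bleach_rate_cy3 = 0, bleach_rate_cy5 = 0,
                         bleach_rate_a750 = 0)
    tls <- sampleKinetics(cfg)
    ts <- renderTraces(tls, photo)
    al <- pairAlexFrames(ts)
    co <- applyCorrections(al, correctionParamsFromPhoto(photo))
    d <- traceData(co)
    N <- photo@photon_budget
    for (id in unique(d$molecule_id)) {
        m <- d[d$molecule_id == id, ]
        E1 <- timelineFret(tls, id, m$t532_s)$E1
        E2_532 <- timelineFret(tls, id, m$t532_s)$E2
        E2_638 <- timelineFret(tls, id, m$t638_s)$E2
        expect_equal(m$I532_cy3, N * (1 - E1), tolerance = 1e-9)
        expect_equal(m$I638_cy5, N * (1 - E2_638), tolerance = 1e-9)
        expect_equal(m$I638_a750, N * E2_638, tolerance = 1e-9)
        ## the direct-excitation correction references the paired 638 nm
        ## frame, so the split between the two 532 acceptor channels is exact
        ## wherever E2 does not move within the half cycle (it always cancels
        ## in the summed denominator of the exit-side observable)
        flat <- abs(E2_532 - E2_638) < 1e-12
        expect_gt(sum(flat), 0L)
        expect_equal(m$I532_cy5[flat], (N * E1 * (1 - E2_532))[flat],
                     tolerance = 1e-9)
        expect_equal(m$I532_a750[flat], (N * E1 * E2_532)[flat],
                     tolerance = 1e-9)
        expect_equal(m$I532_cy5 + m$I532_a750, N * E1, tolerance = 1e-9)
    }
    ## and Eqs. on the corrected records reproduce the ground truth
    fr <- traceData(computeFret(co))
    for (id in unique(fr$molecule_id)) {
        m <- fr[fr$molecule_id == id, ]
        expect_equal(m$E_exit, timelineFret(tls, id, m$t532_s)$E1,
                     tolerance = 1e-9)
        expect_equal(m$E_entry, timelineFret(tls, id, m$t638_s)$E2,
                     tolerance = 1e-9)
    }
})

test_that("bleach-segment estimation recovers the generator crosstalk", {
    ## molecules with staggered bleach patterns expose every coefficient
    tls <- make_static_timelines(
        bleach_cy3 = rep(c(Inf, Inf, 10, 10, Inf, Inf), each = 5L),
        bleach_cy5 = rep(c(20, Inf, Inf, 20, Inf, 30), each = 5L),
        bleach_a750 = rep(c(10, 10, Inf, Inf, 30, Inf), each = 5L),
        duration = 60, seed = 9L)
    photo <- photoConfig()
    ts <- renderTraces(tls, photo, seed = 33L)
    est <- estimateCorrections(ts, groundTruthTable(tls))
    expect_true(all(est@estimated))
    expect_lt(abs(est@b_cy3_cy5 - 0.10), 0.01)
    expect_lt(abs(est@b_cy5_a750 - 0.10), 0.01)
    expect_lt(abs(est@d_cy5_532 - 0.05), 0.01)
    expect_lt(abs(est@d_a750_638 - 0.05), 0.01)
    expect_lt(abs(est@s_cy3 - 1 / photo@g_cy3), 0.05)
    expect_lt(abs(est@s_a750 - 1 / photo@g_a750), 0.05)

    ## crosstalk-free render estimates all fractions at (essentially) zero
    photo0 <- photoConfig(d_cy5_532 = 0, d_a750_638 = 0, b_cy3_cy5 = 0,
                          b_cy5_a750 = 0)
    est0 <- estimateCorrections(renderTraces(tls, photo0, seed = 44L),
                                groundTruthTable(tls))
    expect_lt(abs(est0@b_cy3_cy5), 0.005)
    expect_lt(abs(est0@b_cy5_a750), 0.005)
    expect_lt(abs(est0@d_cy5_532), 0.005)
    expect_lt(abs(est0@d_a750_638), 0.005)

    ## no bleach events: everything stays at the prior, flagged
    tls_nb <- make_static_timelines(n = 10L, duration = 30, seed = 10L)
    est_nb <- estimateCorrections(renderTraces(tls_nb, photo, seed = 55L),
                                  groundTruthTable(tls_nb))
    expect_false(any(est_nb@estimated))
    expect_true(all(est_nb@n_segments == 0L))
})

test_that("estimation error shrinks with segment length", {
    photo <- photoConfig()
    errs <- vapply(c(20, 60, 180), function(dur) {
        tls <- make_static_timelines(
            bleach_cy3 = Inf, bleach_cy5 = rep(5 + dur, 8L),
            bleach_a750 = rep(5, 8L), duration = dur + 10, seed = 31L)
        est <- estimateCorrections(renderTraces(tls, photo, seed = 77L),
                                   groundTruthTable(tls))
        abs(est@b_cy5_a750 - photo@b_cy5_a750)
    }, numeric(1))
    expect_lt(errs[3L], 0.01)
    expect_lt(errs[3L], errs[1L] + 0.002)
})

test_that("correction parameters round-trip through key-value text", {
    p <- correctionParams(d_cy5_532 = 0.05, d_a750_638 = 0.04,
                          b_cy3_cy5 = 0.11, b_cy5_a750 = 0.09,
                          s_cy3 = 0.77, s_a750 = 1.25)
    f <- withr::local_tempfile(fileext = ".txt")
    writeCorrectionParams(p, f)
    q <- readCorrectionParams(f)
    expect_equal(q@d_cy5_532, 0.05)
    expect_equal(q@s_a750, 1.25)
})
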