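test_that("the gap rule reproduces the printed probe shifts", {
    s <- deterministicShifts(bufferModelConfig(gap_offset = 8))
    expect_identical(c(s@entry_shift, s@dyad_shift, s@exit_shift),
                     c(9L, 7L, 4L))
    expect_identical(c(s@absorbed_entry_dyad, s@absorbed_dyad_exit),
                     c(2L, 3L))

    ## zero buffering makes the movement continuous
    s0 <- deterministicShifts(bufferModelConfig(initial_defect = 0,
                                                capacity_entry_dyad = 0,
                                                capacity_dyad_exit = 0,
                                                gap_offset = 5))
    expect_identical(c(s0@entry_shift, s0@dyad_shift, s0@exit_shift),
                     c(5L, 5L, 5L))

    ## m = 0: only the initial defect, fully absorbed
    sm0 <- deterministicShifts(bufferModelConfig(gap_offset = 0))
    expect_identical(c(sm0@entry_shift, sm0@dyad_shift, sm0@exit_shift),
                     c(1L, 0L, 0L))

    expect_error(deterministicShifts(bufferModelConfig()),
                 "simulateCtmc")
})

test_that("deterministic shifts conserve base pairs and grow with m", {
    prev <- c(-1L, -1L, -1L)
    for (m in 0:15) {
        s <- deterministicShifts(bufferModelConfig(gap_offset = m))
        ## conservation (also enforced by the class validity)
        expect_identical(s@entry_shift,
                         s@exit_shift + s@absorbed_entry_dyad +
                             s@absorbed_dyad_exit)
        cur <- c(s@entry_shift, s@dyad_shift, s@exit_shift)
        expect_true(all(cur >= prev))
        prev <- cur
    }
})

test_that("stochastic trajectories respect ordering and converge to the gap rule", {
    cfg <- bufferModelConfig(gap_offset = 8, k_inj = 2, k_relax = 1,
                             seed = 51L)
    set.seed(51)
    for (i in 1:200) {
        tr <- slideFRET:::.simulate_ctmc_once(cfg, t_max = 100 / cfg@k_relax)
        expect_false(tr$censored)
        expect_lte(tr$t_entry, tr$t_exit)
        ## conservation at the end state
        expect_equal(tr$entry_shift, tr$exit_shift + sum(tr$buffers))
        ## agreement with the deterministic calculator at long times
        expect_equal(tr$entry_shift, 9L)
        expect_equal(tr$buffers, c(2L, 3L))
        expect_equal(tr$exit_shift, 4L)
    }
})

test_that("fast relaxation gives an Erlang lag over the injection stages", {
    ## with k_relax >> k_inj the lag is the wait for the injections that fill
    ## both buffers: Erlang(c1 + c2 - defect, k_inj), plus two fast transfers
    cfg <- bufferModelConfig(gap_offset = 8, k_inj = 1, k_relax = 1000,
                             seed = 52L)
    lags <- lagDistributionFromModel(cfg, 20000L)
    analytic <- (cfg@capacity_entry_dyad + cfg@capacity_dyad_exit -
                     cfg@initial_defect) / cfg@k_inj + 2 / cfg@k_relax
    expect_lt(abs(mean(lags) - analytic) / analytic, 0.02)
})

test_that("a single rate-limiting stage gives an exponential lag", {
    ## one buffer at capacity 1 preloaded by the initial defect: the first
    ## injection saturates it and the single relaxation step sets the lag
    cfg <- bufferModelConfig(initial_defect = 1, gap_offset = 10,
                             k_inj = 50, k_relax = 0.5, seed = 53L)
    lags <- lagDistributionFromModel(cfg, 500L, capacities = 1L)
    f <- fitExponential(lags)
    expect_lt(abs(f@mean_lag - 1 / cfg@k_relax), 2 * f@sem)

    ## same seed, same draw
    l2 <- lagDistributionFromModel(cfg, 500L, capacities = 1L)
    expect_identical(lags, l2)

    expect_error(lagDistributionFromModel(cfg, 0L), "n must be >= 1")
    expect_error(
        lagDistributionFromModel(bufferModelConfig(gap_offset = 3), 10L),
        "no exit movement")
})
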