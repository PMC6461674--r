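## Exponential lag-time fits and the ATP dependence of the lag rate ------------

#' Fit a single-exponential lag-time distribution
#'
#' Methods:
#' \describe{
#'   \item{\code{mle}}{closed-form exponential maximum likelihood, the sample
#'     mean of the uncensored lags;}
#'   \item{\code{mle_censored}}{right-censored exponential MLE,
#'     \code{(sum(lags) + sum(censored)) / n_uncensored};}
#'   \item{\code{binned_ls}}{least-squares fit of histogram counts (bin width
#'     by the Freedman-Diaconis rule) to an exponential density, the
#'     histogram-based procedure traditionally applied to dwell-time data.}
#' }
#' The SEM is a seeded nonparametric bootstrap; goodness of fit is a
#' Kolmogorov-Smirnov test of the uncensored lags against the fitted
#' exponential.
#'
#' @param lags numeric vector of observed (uncensored) lag times (s).
#' @param censored numeric vector of censoring times (s) for molecules whose
#'   exit onset was not observed; used by \code{mle_censored} only.
#' @param method one of \code{"mle"}, \code{"mle_censored"}, \code{"binned_ls"}.
#' @param n_boot bootstrap resamples for the SEM.
#' @param seed RNG seed of the bootstrap.
#' @param min_events minimum number of uncensored events (default 5); fewer
#'   events raise an error naming the minimum.
#' @return An \linkS4class{ExpFit}.
#' @examples
#' fitExponential(c(1, 2, 3), min_events = 3)@mean_lag     # 2.0
#' fitExponential(c(1, 2), censored = 10, method = "mle_censored",
#'                min_events = 2)@mean_lag                 # (1+2+10)/2 = 6.5
#' @export
fitExponential <- function(lags, censored = numeric(),
                           method = c("mle", "mle_censored", "binned_ls"),
                           n_boot = 1000L, seed = 1L, min_events = 5L) {
    method <- match.arg(method)
    lags <- lags[is.finite(lags) & lags > 0]
    censored <- censored[is.finite(censored) & censored > 0]
    if (length(lags) < min_events)
        stop("at least ", min_events, " uncensored events are required (got ",
             length(lags), ")")
    point <- function(x, cens) {
        switch(method,
               mle = mean(x),
               mle_censored = (sum(x) + sum(cens)) / length(x),
               binned_ls = .binned_ls_mean(x))
    }
    mean_lag <- point(lags, censored)
    set.seed(seed)
    boot <- vapply(seq_len(n_boot), function(i) {
        bx <- sample(lags, replace = TRUE)
        bc <- if (length(censored))
            sample(censored, replace = TRUE) else numeric()
        point(bx, bc)
    }, numeric(1))
    ks <- suppressWarnings(stats::ks.test(lags, stats::pexp,
                                          rate = 1 / mean_lag))
    new("ExpFit", mean_lag = mean_lag, sem = stats::sd(boot),
        n_events = length(lags),
        n_censored = if (method == "mle_censored") length(censored) else 0L,
        ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
        method = method)
}

## histogram least squares with Freedman-Diaconis bins
.binned_ls_mean <- function(x) {
    bw <- 2 * stats::IQR(x) / length(x)^(1 / 3)
    if (bw <= 0) bw <- diff(range(x)) / max(1, ceiling(sqrt(length(x))))
    breaks <- seq(0, max(x) + bw, by = bw)
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    counts <- h$counts
    mids <- h$mids
    obj <- function(tau)
        sum((counts - length(x) * bw * stats::dexp(mids, 1 / tau))^2)
    stats::optimize(obj, interval = c(bw / 10, 10 * max(x)))$minimum
}

#' Fit the Michaelis-Menten ATP dependence of the lag rate
#'
#' Weighted nonlinear least squares of \code{1/mean_lag} versus ATP
#' concentration on \code{v = k_max * S / (K_app + S)}, with weights
#' \code{1/SEM(v)^2} propagated from the per-concentration lag SEMs
#' (\code{SEM(1/m) = SEM(m)/m^2}).  Initialisation is a multi-start grid over
#' decades of \code{K_app} (and the plateau estimate of \code{k_max}); the
#' best converged start wins.
#'
#' @param points a data.frame with columns \code{atp_uM}, \code{mean_lag},
#'   \code{sem} -- or a list of \code{list(atp_uM =, fit = ExpFit)} pairs.
#' @return A \linkS4class{HyperbolicFit}.
#' @examples
#' pts <- data.frame(atp_uM = c(20, 50, 100, 200, 500),
#'                   mean_lag = (60 + c(20, 50, 100, 200, 500)) /
#'                       (0.5 * c(20, 50, 100, 200, 500)),
#'                   sem = 0.1)
#' fitAtpDependence(pts)
#' @export
fitAtpDependence <- function(points) {
    if (is.list(points) && !is.data.frame(points) &&
        all(vapply(points, function(p) is(p$fit, "ExpFit"), logical(1)))) {
        points <- data.frame(
            atp_uM = vapply(points, function(p) p$atp_uM, numeric(1)),
            mean_lag = vapply(points, function(p) p$fit@mean_lag, numeric(1)),
            sem = vapply(points, function(p) p$fit@sem, numeric(1)))
    }
    points <- as.data.frame(points)
    if (length(unique(points$atp_uM)) < 3L)
        stop("at least 3 distinct ATP concentrations are required")
    S <- points$atp_uM
    v <- 1 / points$mean_lag
    sem_v <- points$sem / points$mean_lag^2
    w <- ifelse(sem_v > 0, 1 / sem_v^2, 1)
    w <- w / mean(w)

    starts <- expand.grid(k_max = max(v) * c(1, 1.5, 3),
                          K_app = 10^seq(0, 3, by = 1))
    best <- NULL; best_rss <- Inf
    for (i in seq_len(nrow(starts))) {
        fit <- tryCatch(
            minpack.lm::nlsLM(v ~ k_max * S / (K_app + S),
                              start = as.list(starts[i, ]), weights = w,
                              lower = c(k_max = 1e-12, K_app = 1e-12),
                              control = minpack.lm::nls.lm.control(maxiter = 200)),
            error = function(e) NULL)
        if (!is.null(fit)) {
            rss <- sum(w * stats::residuals(fit)^2)
            if (rss < best_rss) { best <- fit; best_rss <- rss }
        }
    }
    if (is.null(best)) {
        ## report the best grid point rather than failing silently
        rss_grid <- apply(starts, 1L, function(p)
            sum(w * (v - p[1] * S / (p[2] + S))^2))
        j <- which.min(rss_grid)
        stop("ATP-dependence fit did not converge from any start; ",
             sprintf("best grid point k_max = %.3g, K_app = %.3g",
                     starts$k_max[j], starts$K_app[j]))
    }
    cf <- stats::coef(best)
    se <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                   error = function(e) c(k_max = NA_real_, K_app = NA_real_))
    res <- stats::setNames(v - cf[["k_max"]] * S / (cf[["K_app"]] + S),
                           as.character(S))
    new("HyperbolicFit", k_max = cf[["k_max"]], K_app = cf[["K_app"]],
        k_max_ci = cf[["k_max"]] + c(-1.96, 1.96) * se[["k_max"]],
        K_app_ci = cf[["K_app"]] + c(-1.96, 1.96) * se[["K_app"]],
        residuals = res, converged = TRUE)
}

#' Population FRET histograms before/after remodelling
#'
#' Per-molecule mean FRET over the requested window (before the entry onset or
#' after the end of the exit transition), aggregated into fixed-width
#' histograms (bin width 0.02 over [-0.1, 1.1]) for the entry-side and
#' exit-side observables, with a Gaussian summary per population.
#'
#' @param fret a \linkS4class{FretTraceSet}.
#' @param window \code{"before_event"} or \code{"after_event"}.
#' @param events an \linkS4class{EventTable} that dates the windows.
#' @return A list with elements \code{entry} and \code{exit}, each a list
#'   with \code{breaks}, \code{counts}, \code{mean}, \code{sd}, \code{n}
#'   (molecules contributing), and \code{n_skipped} (empty windows).
#' @export
buildFretHistograms <- function(fret, window = c("before_event", "after_event"),
                                events) {
    window <- match.arg(window)
    stopifnot(is(fret, "FretTraceSet"), is(events, "EventTable"))
    d <- fret@data
    ev <- events@data
    breaks <- seq(-0.1, 1.1, by = 0.02)
    one_side <- function(valid_col, value_col, time_col, onset_col) {
        vals <- numeric(); skipped <- 0L
        for (i in seq_len(nrow(ev))) {
            id <- ev$molecule_id[i]
            m <- d[d$molecule_id == id & d[[valid_col]], , drop = FALSE]
            lim <- ev[[onset_col]][i]
            sel <- if (window == "before_event") {
                if (is.na(lim)) rep(TRUE, nrow(m)) else m[[time_col]] < lim
            } else {
                if (is.na(lim)) rep(FALSE, nrow(m)) else m[[time_col]] > lim
            }
            x <- m[[value_col]][sel]
            if (!length(x)) { skipped <- skipped + 1L; next }
            vals <- c(vals, mean(x))
        }
        vals_in <- vals[vals >= -0.1 & vals <= 1.1]
        h <- if (length(vals_in))
            graphics::hist(vals_in, breaks = breaks, plot = FALSE)$counts
        else rep(0L, length(breaks) - 1L)
        list(breaks = breaks, counts = h,
             mean = if (length(vals)) mean(vals) else NA_real_,
             sd = if (length(vals) > 1L) stats::sd(vals) else NA_real_,
             n = length(vals), n_skipped = skipped)
    }
    ## before: everything up to the entry onset; after: everything past the
    ## exit onset (the entry-side rise/fall is complete shortly after it)
    onset_col <- if (window == "before_event") "t_entry_s" else "t_exit_s"
    list(entry = one_side("valid_entry", "E_entry", "t638_s", onset_col),
         exit = one_side("valid_exit", "E_exit", "t532_s", onset_col))
}

#' Collect lag and censoring times from an event table
#'
#' @param events an \linkS4class{EventTable}.
#' @return A list with numeric vectors \code{lags} (complete events) and
#'   \code{censored} (censoring times of entry-only molecules).
#' @export
lagTimes <- function(events) {
    stopifnot(is(events, "EventTable"))
    d <- events@data
    list(lags = d$t_lag_s[!is.na(d$t_lag_s)],
         censored = d$t_censor_s[!is.na(d$t_censor_s) & is.na(d$t_lag_s)])
}
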