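#' Classify trial outcomes
#'
#' A response at or before the change time is a false alarm; a response
#' within the `window` after the change is a hit (reaction time = response
#' time minus change time); no response, or a response after the window, is
#' a miss. Vectorized; `response_time` is NA for trials without a press.
#'
#' @param change_time change onset(s) in seconds from stimulus onset.
#' @param response_time press time(s) in seconds from stimulus onset, NA if
#'   no press.
#' @param window response window in seconds.
#' @return data.frame with `outcome` (factor hit/miss/false_alarm) and
#'   `reaction_time` (NA except for hits).
#' @export
classify_trial <- function(change_time, response_time = NA_real_,
                           window = 2) {
  n <- max(length(change_time), length(response_time))
  ct <- rep_len(as.numeric(change_time), n)
  rt <- rep_len(as.numeric(response_time), n)
  if (any(ct < 0)) stop("negative change_time")
  if (any(!is.na(rt) & rt < 0)) stop("negative response_time")
  outcome <- rep("miss", n)
  outcome[!is.na(rt) & rt <= ct] <- "false_alarm"
  outcome[!is.na(rt) & rt > ct & rt <= ct + window] <- "hit"
  reaction <- ifelse(outcome == "hit", rt - ct, NA_real_)
  data.frame(outcome = factor(outcome,
                              levels = c("hit", "miss", "false_alarm")),
             reaction_time = reaction)
}

#' Assemble response records from trials and responses
#'
#' @param trials a [generate_trials()] table (needs `trial`, `change_time`;
#'   other columns are carried through).
#' @param response_time per-trial press times (NA = no press).
#' @param window response window in seconds.
#' @return data.frame of response records: trial columns plus
#'   `response_time`, `outcome`, `reaction_time`.
#' @export
response_records <- function(trials, response_time, window = 2) {
  cls <- classify_trial(trials$change_time, response_time, window)
  cbind(trials, response_time = as.numeric(response_time), cls)
}

#' Screen a response set by total false-alarm rate
#'
#' Inattentive responders are screened out by their overall false-alarm
#' fraction (observers above 30% were excluded from the original analyses;
#' retained ones fell below 25%). Exposed as a flag only -- no further
#' exclusion logic is applied.
#'
#' @param records a [response_records()] table.
#' @param threshold maximum tolerated false-alarm fraction.
#' @return logical: `TRUE` if the set passes the screen; the observed
#'   fraction is attached as attribute `fa_rate`.
#' @export
passes_fa_screen <- function(records, threshold = 0.30) {
  fa <- mean(records$outcome == "false_alarm")
  structure(fa <= threshold, fa_rate = fa)
}

#' Bin change times into exponentially widening bins
#'
#' Bin edges are the empirical quantiles of the change times, which for the
#' exponential change-time law widen exponentially and equalize per-bin trial
#' counts.
#'
#' @param change_times numeric vector of change times in seconds.
#' @param n_bins number of bins.
#' @return list with `edges` (length `n_bins + 1`), `bin` (assignment per
#'   trial), `centers` (per-bin median change time).
#' @export
bin_change_times <- function(change_times, n_bins = 6) {
  if (n_bins < 1) stop("n_bins must be >= 1")
  if (length(change_times) < n_bins) stop("fewer trials than bins")
  edges <- unname(stats::quantile(change_times,
                                  probs = seq(0, 1, length.out = n_bins + 1)))
  edges[1] <- min(edges[1], 0)
  edges[n_bins + 1] <- edges[n_bins + 1] + 1e-9
  bin <- findInterval(change_times, edges, rightmost.closed = TRUE)
  bin[bin > n_bins] <- n_bins
  centers <- vapply(seq_len(n_bins), function(b)
    stats::median(change_times[bin == b]), numeric(1))
  list(edges = edges, bin = bin, centers = centers)
}

#' Per-condition performance table
#'
#' Performance is hits / (hits + misses): the fraction of detected changes
#' among trials in which the change occurred before any response. False
#' alarms are excluded (they end the trial before the change).
#'
#' @param records a [response_records()] table with `change_size`.
#' @param n_time_bins number of change-time bins.
#' @param localized_only restrict to localized-change trials when a
#'   `localized` column is present.
#' @return data.frame per (change_size, time bin): `change_size`, `bin`,
#'   `t` (median change time in bin), `n`, `hits`, `misses`, `false_alarms`,
#'   `performance`.
#' @export
performance_table <- function(records, n_time_bins = 6,
                              localized_only = TRUE) {
  if (localized_only && !is.null(records$localized))
    records <- records[records$localized, , drop = FALSE]
  btt <- bin_change_times(records$change_time, n_time_bins)
  records$time_bin <- btt$bin
  cells <- expand.grid(change_size = sort(unique(records$change_size)),
                       bin = seq_len(n_time_bins))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    r <- records[records$change_size == cells$change_size[i] &
                 records$time_bin == cells$bin[i], ]
    h <- sum(r$outcome == "hit"); m <- sum(r$outcome == "miss")
    fa <- sum(r$outcome == "false_alarm")
    data.frame(change_size = cells$change_size[i], bin = cells$bin[i],
               t = if (nrow(r)) stats::median(r$change_time) else NA_real_,
               n = nrow(r), hits = h, misses = m, false_alarms = fa,
               performance = if (h + m > 0) h / (h + m) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Instantaneous false-alarm rate
#'
#' False alarms per second in each time bin, as a fraction of the trials
#' still at risk at the bin start (change time beyond the bin start and no
#' earlier response). Bins with an empty risk set are NA, not zero.
#'
#' @param records a [response_records()] table.
#' @param dt bin width in seconds.
#' @param t_max last bin start (defaults to the change-time cap observed).
#' @return data.frame with `t` (bin start), `n_risk`, `fa`, `rate` (per s).
#' @export
instantaneous_fa_rate <- function(records, dt = 0.25, t_max = NULL) {
  if (!nrow(records)) stop("no records")
  if (is.null(t_max)) t_max <- max(records$change_time)
  starts <- seq(0, t_max, by = dt)
  ct <- records$change_time
  rt <- records$response_time
  is_fa <- records$outcome == "false_alarm"
  out <- lapply(starts, function(t0) {
    risk <- ct > t0 & (is.na(rt) | rt > t0)
    fa <- sum(is_fa & !is.na(rt) & rt > t0 & rt <= t0 + dt & ct > t0)
    data.frame(t = t0, n_risk = sum(risk), fa = fa,
               rate = if (sum(risk) > 0) fa / (sum(risk) * dt) else NA_real_)
  })
  do.call(rbind, out)
}

#' Time-dependent d-prime
#'
#' d'(t) = Z(HR(t)) - Z(FAR(t)) with Z the inverse Gaussian CDF. HR(t) is
#' the hit fraction among trials whose change falls in the bin starting at t.
#' FAR(t) is computed over all `window`-long windows starting at t in which
#' no change occurred and no earlier response ended the trial: the fraction
#' of those windows containing a press. Each such press also yields a pseudo
#' reaction time (press time - window start) for comparison with hit RTs.
#' Rates are clipped to [1/(2N), 1 - 1/(2N)] before Z to avoid infinities,
#' and grid points whose hit or false-alarm cell holds fewer than `min_n`
#' trials/windows are reported as missing (the inverse-normal of a rate
#' estimated from a handful of observations is dominated by sampling noise).
#'
#' @param records a [response_records()] table.
#' @param window response window in seconds.
#' @param dt analysis grid step in seconds.
#' @param n_boot bootstrap resamples for 95% confidence bounds (0 = none).
#' @param t_max last grid point (defaults to the largest change time).
#' @param min_n minimum cell count for a defined rate.
#' @return object of class `dprime_curve`: data.frame with `t`, `n_change`,
#'   `hr`, `n_windows`, `far`, `dprime`, and if bootstrapped `lo`, `hi`;
#'   attribute `fa_pseudo_rt` holds the pseudo reaction times.
#' @export
time_dependent_dprime <- function(records, window = 2, dt = 0.25,
                                  n_boot = 0, t_max = NULL, min_n = 10) {
  if (!nrow(records)) stop("no records")
  if (is.null(t_max)) t_max <- max(records$change_time)
  grid <- seq(0, t_max, by = dt)

  curve_of <- function(rec) {
    ct <- rec$change_time; rt <- rec$response_time
    hit <- rec$outcome == "hit"; miss <- rec$outcome == "miss"
    t(vapply(grid, function(t0) {
      in_bin <- ct >= t0 & ct < t0 + dt
      nh <- sum(in_bin & hit); nm <- sum(in_bin & miss)
      n_change <- nh + nm
      hr <- if (n_change >= min_n) nh / n_change else NA_real_
      # no-change windows: change beyond the window, trial not yet ended
      win <- ct >= t0 + window & (is.na(rt) | rt > t0)
      n_win <- sum(win)
      far <- if (n_win >= min_n)
        sum(win & !is.na(rt) & rt > t0 & rt <= t0 + window) / n_win
        else NA_real_
      c(n_change, hr, n_win, far)
    }, numeric(4)))
  }

  zclip <- function(p, n) {
    lim <- 1 / (2 * pmax(n, 1))
    stats::qnorm(pmin(pmax(p, lim), 1 - lim))
  }
  m <- curve_of(records)
  dp <- zclip(m[, 2], m[, 1]) - zclip(m[, 4], m[, 3])
  out <- data.frame(t = grid, n_change = m[, 1], hr = m[, 2],
                    n_windows = m[, 3], far = m[, 4], dprime = dp)

  if (n_boot > 0) {
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(records), replace = TRUE)
      mb <- curve_of(records[idx, ])
      zclip(mb[, 2], mb[, 1]) - zclip(mb[, 4], mb[, 3])
    }, numeric(length(grid)))
    out$lo <- apply(boots, 1, stats::quantile, 0.025, na.rm = TRUE)
    out$hi <- apply(boots, 1, stats::quantile, 0.975, na.rm = TRUE)
  }

  # artificial reaction times for false alarms (per no-change window)
  ct <- records$change_time; rt <- records$response_time
  pseudo <- unlist(lapply(grid, function(t0) {
    win <- ct >= t0 + window & !is.na(rt) & rt > t0 & rt <= t0 + window
    rt[win] - t0
  }))
  attr(out, "fa_pseudo_rt") <- pseudo
  class(out) <- c("dprime_curve", "data.frame")
  out
}

#' Erlang-CDF performance dynamics fit
#'
#' Fits P(size, tc) = P0 + Pmax * G(k, tc / tau) per change size, where
#' G(k, x) = gamma(k, x) / (k-1)! is the regularized lower incomplete gamma
#' function (`pgamma(x, shape = k)`), with an integer shape k shared across
#' change sizes. For each candidate k, tau is profiled by one-dimensional
#' minimization and (P0, Pmax) are solved by bounded linear least squares;
#' k minimizing the pooled residual wins.
#'
#' @param perf a [performance_table()] (needs `change_size`, `t`,
#'   `performance`, `n`); rows with NA performance are dropped.
#' @param k integer shape; `NULL` searches 1-6.
#' @param tau_range search interval for tau in seconds.
#' @param weighted weight squared residuals by per-cell trial counts.
#' @return object of class `erlang_fit`: list with `k`, `params`
#'   (data.frame: change_size, P0, Pmax, tau, sse), `sse` (total), and
#'   `fitted(tc, change_size)` via [predict.erlang_fit()].
#' @export
fit_erlang_cdf <- function(perf, k = NULL, tau_range = c(0.02, 20),
                           weighted = TRUE) {
  perf <- perf[!is.na(perf$performance) & !is.na(perf$t), , drop = FALSE]
  sizes <- sort(unique(perf$change_size))
  if (any(table(perf$change_size) < 4))
    stop("need at least 4 change-time bins per change size")
  ks <- if (is.null(k)) 1:6 else as.integer(k)

  fit_size_k <- function(tc, y, w, kk) {
    # conditional linear LS in (P0, Pmax) given tau, constrained to
    # 0 <= P0, 0 <= Pmax, P0 + Pmax <= 1
    sse_tau <- function(tau) {
      g <- stats::pgamma(tc / tau, shape = kk)
      fit <- stats::lm.wfit(cbind(1, g), y, w)
      p0 <- fit$coefficients[1]; pm <- fit$coefficients[2]
      if (is.na(pm)) pm <- 0
      p0 <- min(max(p0, 0), 1); pm <- min(max(pm, 0), 1 - p0)
      sum(w * (y - (p0 + pm * g))^2)
    }
    log_tau <- stats::optimize(function(l) sse_tau(exp(l)),
                               log(tau_range), tol = 1e-6)
    tau <- exp(log_tau$minimum)
    g <- stats::pgamma(tc / tau, shape = kk)
    fit <- stats::lm.wfit(cbind(1, g), y, w)
    p0 <- fit$coefficients[1]; pm <- fit$coefficients[2]
    if (is.na(pm)) pm <- 0
    p0 <- min(max(p0, 0), 1); pm <- min(max(pm, 0), 1 - p0)
    list(P0 = p0, Pmax = pm, tau = tau,
         sse = sum(w * (y - (p0 + pm * g))^2))
  }

  best <- NULL
  for (kk in ks) {
    fits <- lapply(sizes, function(s) {
      d <- perf[perf$change_size == s, ]
      w <- if (weighted && !is.null(d$n)) d$n else rep(1, nrow(d))
      fit_size_k(d$t, d$performance, w, kk)
    })
    tot <- sum(vapply(fits, `[[`, numeric(1), "sse"))
    if (is.null(best) || tot < best$sse)
      best <- list(k = kk, fits = fits, sse = tot)
  }
  params <- data.frame(
    change_size = sizes,
    P0 = vapply(best$fits, `[[`, numeric(1), "P0"),
    Pmax = vapply(best$fits, `[[`, numeric(1), "Pmax"),
    tau = vapply(best$fits, `[[`, numeric(1), "tau"),
    sse = vapply(best$fits, `[[`, numeric(1), "sse"))
  structure(list(k = best$k, params = params, sse = best$sse),
            class = "erlang_fit")
}

#' Evaluate an Erlang performance curve
#'
#' @param object an `erlang_fit`.
#' @param tc change times in seconds.
#' @param change_size one of the fitted sizes.
#' @param ... unused.
#' @return predicted performance at `tc`.
#' @export
predict.erlang_fit <- function(object, tc, change_size, ...) {
  p <- object$params[object$params$change_size == change_size, ]
  if (!nrow(p)) stop("change size not in fit")
  erlang_perf(tc, p$P0, p$Pmax, p$tau, object$k)
}

#' @rdname predict.erlang_fit
#' @param P0,Pmax,tau,k Erlang curve parameters.
#' @export
erlang_perf <- function(tc, P0, Pmax, tau, k) {
  P0 + Pmax * stats::pgamma(tc / tau, shape = k)
}

#' @export
print.erlang_fit <- function(x, ...) {
  cat("Erlang-CDF performance fit (k =", x$k, ", SSE =",
      format(x$sse, digits = 4), ")\n")
  print(x$params, row.names = FALSE)
  invisible(x)
}

#' AUROC from hit and false-alarm reaction-time distributions
#'
#' Cumulative hit and false-alarm probabilities are computed independently
#' from their reaction-time distributions at each grid time (default 0.2 to
#' 2 s in 0.2 s steps); the ROC-style curve of hit probability against FA
#' probability, anchored at (0,0) and (1,1), is integrated by the trapezoid
#' rule. 0.5 = indistinguishable distributions, 1 = all hit RTs precede all
#' FA pseudo-RTs.
#'
#' @param hit_rt hit reaction times in seconds.
#' @param fa_rt false-alarm pseudo reaction times (see
#'   [time_dependent_dprime()]).
#' @param t_grid evaluation grid in seconds.
#' @return list with `auroc`, and the `curve` data.frame (`t`, `p_hit`,
#'   `p_fa`).
#' @export
auroc_rt <- function(hit_rt, fa_rt, t_grid = seq(0.2, 2, by = 0.2)) {
  if (!length(hit_rt) || !length(fa_rt)) stop("empty RT sample")
  p_hit <- vapply(t_grid, function(tt) mean(hit_rt <= tt), numeric(1))
  p_fa <- vapply(t_grid, function(tt) mean(fa_rt <= tt), numeric(1))
  x <- c(0, p_fa, 1); y <- c(0, p_hit, 1)
  if (nrow(unique(round(cbind(x, y), 12))) <= 2)
    warning("degenerate single-point ROC curve")
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  area <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  list(auroc = area, curve = data.frame(t = t_grid, p_hit = p_hit,
                                        p_fa = p_fa))
}
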