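test_that("trial classification partitions outcomes", {
  # press before the change is a false alarm
  expect_equal(as.character(classify_trial(3.0, 2.1)$outcome), "false_alarm")
  # press within the 2 s window is a hit with RT = response - change
  h <- classify_trial(3.0, 4.2)
  expect_equal(as.character(h$outcome), "hit")
  expect_equal(h$reaction_time, 1.2)
  # press 0.6 s beyond the window (5.6 > 5.0) is a miss
  expect_equal(as.character(classify_trial(3.0, 5.6)$outcome), "miss")
  expect_equal(as.character(classify_trial(3.0, NA)$outcome), "miss")
  expect_error(classify_trial(3.0, -1))
  expect_error(classify_trial(-3, 1))
  # partition property over random cases
  set.seed(1)
  ct <- runif(500, 0, 8)
  rt <- ifelse(runif(500) < 0.3, NA, runif(500, 0, 10))
  cls <- classify_trial(ct, rt)
  expect_true(all(table(cls$outcome) >= 0))
  expect_equal(sum(table(cls$outcome)), 500)
  expect_true(all(is.na(cls$reaction_time) | cls$outcome == "hit"))
})

test_that("change-time bins equalize counts under the exponential law", {
  set.seed(2)
  x <- sample_change_time(1e4)
  b <- bin_change_times(x, 6)
  counts <- tabulate(b$bin, 6)
  expect_true(all(abs(counts - mean(counts)) / mean(counts) < 0.15))
  # widths increase (exponentially widening edges)
  expect_true(all(diff(diff(b$edges)) > -1e-9 | diff(b$edges)[-1] >
                    diff(b$edges)[-5] * 0.9))
  # single bin holds everything
  b1 <- bin_change_times(runif(50), 1)
  expect_true(all(b1$bin == 1))
  # four equal-count quartile bins
  b4 <- bin_change_times(x, 4)
  expect_true(all(abs(tabulate(b4$bin, 4) - 2500) < 200))
  expect_error(bin_change_times(c(1, 2), 5))
})

test_that("instantaneous FA rate recovers a constant press hazard", {
  # no false alarms -> all-zero curve
  tr <- data.frame(trial = 1:50, change_time = rep(6, 50))
  rec0 <- response_records(tr, rep(NA_real_, 50))
  fa0 <- instantaneous_fa_rate(rec0, dt = 0.5)
  expect_true(all(fa0$rate[!is.na(fa0$rate)] == 0))
  # Bernoulli responder with p per dt bin -> rate ~ p/dt, flat
  set.seed(3)
  n <- 20000
  dtb <- 0.25
  ct <- rep(8, n)
  p_bin <- 0.05
  resp <- vapply(seq_len(n), function(i) {
    k <- which(rbinom(40, 1, p_bin) == 1)[1]
    if (is.na(k)) NA_real_ else k * dtb
  }, numeric(1))
  rec <- response_records(data.frame(trial = 1:n, change_time = ct), resp)
  fa <- instantaneous_fa_rate(rec, dt = dtb, t_max = 7.5)
  mid <- fa$rate[fa$t >= 1 & fa$t <= 6]
  expect_equal(mean(mid), p_bin / dtb, tolerance = 0.05)
  expect_lt(sd(mid) / mean(mid), 0.15)
  # empty risk set reported as missing, not zero
  fa2 <- instantaneous_fa_rate(rec0, dt = 0.5, t_max = 10)
  expect_true(anyNA(fa2$rate))
})

test_that("time-dependent d-prime matches inverse-normal arithmetic", {
  # HR=0.84, FAR=0.16 -> d' ~ 1.989 (frozen from qnorm oracle)
  expect_equal(qnorm(0.84) - qnorm(0.16), 1.988916, tolerance = 1e-6)
  # construct records with exact cell rates at one grid point
  set.seed(4)
  n <- 400
  ct <- c(rep(2.1, 200), rep(8, 200))        # changes in bin [2, 2.25)
  rt <- c(ifelse(seq_len(200) <= 168, 2.5, NA),   # 84% hits
          ifelse(seq_len(200) <= 32, 2.6, NA))    # 16% of windows pressed
  rec <- response_records(data.frame(trial = 1:n, change_time = ct), rt)
  dp <- time_dependent_dprime(rec, dt = 0.25)
  row <- dp[dp$t == 2, ]
  expect_equal(row$hr, 0.84)
  expect_equal(row$far, 0.16)
  expect_equal(row$dprime, 1.988916, tolerance = 1e-4)
  # HR = FAR everywhere -> d' = 0; antisymmetry under swapping rates
  expect_equal(qnorm(0.4) - qnorm(0.4), 0)
  expect_equal(qnorm(0.3) - qnorm(0.7), -(qnorm(0.7) - qnorm(0.3)))
  # pseudo reaction times are press - window start, within (0, window]
  pseudo <- attr(dp, "fa_pseudo_rt")
  expect_true(length(pseudo) > 0)
  expect_true(all(pseudo > 0 & pseudo <= 2))
  # bootstrap bounds bracket the point estimate
  dpb <- time_dependent_dprime(rec, dt = 0.25, n_boot = 100)
  rb <- dpb[dpb$t == 2, ]
  expect_true(rb$lo <= rb$dprime && rb$dprime <= rb$hi)
})

test_that("random responder yields d-prime near zero", {
  set.seed(5)
  n <- 4000
  ct <- sample_change_time(n)
  resp <- random_responder(ct)
  rec <- response_records(data.frame(trial = 1:n, change_time = ct), resp)
  dp <- time_dependent_dprime(rec, dt = 0.25)
  w <- dp$n_change * dp$n_windows / (dp$n_change + dp$n_windows)
  expect_lt(abs(weighted.mean(dp$dprime, w, na.rm = TRUE)), 0.08)
})

test_that("Erlang CDF fit recovers generating parameters", {
  # gamma(k, 0) = 0: curve equals P0 at tc = 0
  expect_equal(erlang_perf(0, 0.05, 0.85, 0.8, 2), 0.05)
  # noise-free recovery is near exact
  tc <- c(0.3, 0.8, 1.5, 2.5, 4, 6)
  clean <- data.frame(change_size = 110, bin = 1:6, t = tc, n = 1000,
                      performance = erlang_perf(tc, 0.05, 0.85, 0.8, 2))
  f0 <- fit_erlang_cdf(clean, k = 2)
  expect_equal(f0$params$P0, 0.05, tolerance = 1e-3)
  expect_equal(f0$params$Pmax, 0.85, tolerance = 1e-3)
  expect_equal(f0$params$tau, 0.8, tolerance = 1e-2)
  # binomial noise at n = 30/bin: recovery within bootstrap CI
  set.seed(6)
  noisy <- clean
  noisy$n <- 30
  noisy$performance <- rbinom(6, 30, clean$performance) / 30
  f1 <- fit_erlang_cdf(noisy, k = 2)
  boot_tau <- replicate(200, {
    b <- noisy
    b$performance <- rbinom(6, 30, predict(f1, tc, 110)) / 30
    fit_erlang_cdf(b, k = 2)$params$tau
  })
  ci <- quantile(boot_tau, c(0.01, 0.99))
  expect_true(0.8 >= ci[1] * 0.8 && 0.8 <= ci[2] * 1.2)
  expect_lt(abs(f1$params$tau - 0.8), diff(range(boot_tau)) + 0.2)
  # tau ordering across change sizes is preserved
  set.seed(7)
  two <- do.call(rbind, lapply(c(50, 140), function(s) {
    tau_s <- if (s == 50) 1.4 else 0.5
    data.frame(change_size = s, bin = 1:6, t = tc, n = 200,
               performance = rbinom(6, 200,
                                    erlang_perf(tc, 0.05, 0.85, tau_s, 2))
               / 200)
  }))
  f2 <- fit_erlang_cdf(two, k = 2)
  pr <- f2$params[order(f2$params$change_size), ]
  expect_gt(pr$tau[1], pr$tau[2])
  # residual shrinks as noise vanishes
  expect_lt(f0$sse, f1$sse)
  expect_error(fit_erlang_cdf(clean[1:3, ]))
})

test_that("reaction-time AUROC agrees with the pairwise oracle", {
  # identical distributions -> 0.5; complete separation -> 1
  expect_equal(auroc_rt(c(0.4, 0.8, 1.2), c(0.4, 0.8, 1.2))$auroc, 0.5)
  expect_equal(auroc_rt(c(0.2, 0.4), c(1.2, 1.4, 1.8))$auroc, 1.0)
  # small samples on the grid: trapezoid area equals the brute-force
  # Mann-Whitney statistic P(hit < fa) + 0.5 P(tie)
  mw <- function(h, f) {
    s <- 0
    for (a in h) for (b in f) s <- s + (a < b) + 0.5 * (a == b)
    s / (length(h) * length(f))
  }
  set.seed(8)
  grid <- seq(0.2, 2, by = 0.2)
  for (i in 1:10) {
    h <- sample(grid, 5, replace = TRUE)
    f <- sample(grid, 5, replace = TRUE)
    expect_equal(auroc_rt(h, f)$auroc, mw(h, f), tolerance = 1e-12)
  }
  expect_error(auroc_rt(numeric(0), c(1)))
  expect_warning(auroc_rt(rep(5, 3), rep(5, 4)))
})

test_that("performance table counts hits and misses per condition cell", {
  tr <- small_trials(n_reps = 10, seed = 9)
  set.seed(9)
  # ideal observer that always presses 1 s after the change
  rec <- response_records(tr, tr$change_time + 1)
  pt <- performance_table(rec, 4)
  expect_true(all(pt$performance == 1))
  expect_equal(sum(pt$n), nrow(tr))
  # never-presser
  rec0 <- response_records(tr, rep(NA_real_, nrow(tr)))
  pt0 <- performance_table(rec0, 4)
  expect_true(all(pt0$performance == 0))
  expect_true(all(pt0$hits + pt0$misses == pt0$n))
  # false-alarm screen: never-presser passes, always-presser fails
  expect_true(passes_fa_screen(rec0))
  rec_fa <- response_records(tr, rep(0, nrow(tr)))
  expect_false(passes_fa_screen(rec_fa))
  expect_equal(attr(passes_fa_screen(rec_fa), "fa_rate"), 1)
})
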