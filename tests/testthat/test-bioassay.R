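test_that("Kaplan-Meier estimator matches hand calculation and handles ties", {
  rec <- data.frame(arm = "a", time = c(1, 2, 2, 5), event = c(1, 1, 0, 0))
  k <- km_curve(rec, "a")
  expect_equal(k$times, c(1, 2))
  expect_equal(k$S, c(0.75, 0.50))
  expect_equal(k$at_risk, c(4L, 3L))       # censored at 2 still at risk at 2
  expect_equal(km_surv_at(k, c(0.5, 1, 3, 10)), c(1, 0.75, 0.5, 0.5))

  allc <- data.frame(arm = "a", time = rep(14, 6), event = 0L)
  expect_length(km_curve(allc, "a")$times, 0L)
  expect_equal(km_surv_at(km_curve(allc, "a"), 14), 1)
  expect_error(km_curve(rec, "missing"), "no records")
})

test_that("without censoring KM equals one minus the empirical CDF", {
  withr::with_seed(101, {
    for (rep in 1:100) {
      n <- sample(5:40, 1)
      times <- sample(1:15, n, replace = TRUE)
      rec <- data.frame(arm = "a", time = times, event = 1L)
      k <- km_curve(rec, "a")
      at <- sort(unique(times))
      expect_equal(km_surv_at(k, at), 1 - ecdf(times)(at))
    }
  })
})

test_that("Cox fit agrees with the brute-force partial-likelihood maximizer", {
  withr::with_seed(211, {
    for (rep in 1:10) {
      # 20 subjects, two arms, distinct event times
      n <- 20L
      arm <- rep(c("ctl", "trt"), each = n / 2)
      time <- sample(seq(0.5, 40, by = 0.5), n)   # all distinct
      event <- rbinom(n, 1, 0.8)
      if (sum(event) < 2 || length(unique(arm[event == 1])) < 2) next
      rec <- data.frame(arm = arm, time = time, event = event)
      fit <- cox_fit(rec, "ctl")
      x <- as.integer(arm == "trt")
      brute <- oracle_cox_beta(x, time, event)
      expect_true(fit$converged)
      expect_equal(fit$beta, brute, tolerance = 1e-4,
                   ignore_attr = TRUE)
      # no ties: Efron and Breslow coincide
      fitb <- cox_fit(rec, "ctl", ties = "breslow")
      expect_equal(fit$beta, fitb$beta, tolerance = 1e-8, ignore_attr = TRUE)
      # likelihood identities
      expect_equal(fit$loglik_null,
                   oracle_cox_loglik(0, x, time, event))
      expect_gte(fit$lr_stat, 0)
      expect_equal(fit$lr_stat, 2 * (fit$loglik_fit - fit$loglik_null))
    }
  })
})

test_that("Cox fit agrees with the brute-force maximizer under Efron ties", {
  withr::with_seed(223, {
    arm <- rep(c("ctl", "trt"), each = 15)
    time <- sample(1:6, 30, replace = TRUE)     # heavy daily ties
    event <- rbinom(30, 1, 0.8)
  })
  rec <- data.frame(arm = arm, time = time, event = event)
  x <- as.integer(arm == "trt")
  for (ties in c("efron", "breslow")) {
    fit <- cox_fit(rec, "ctl", ties = ties)
    brute <- oracle_cox_beta(x, time, event, ties = ties)
    expect_equal(fit$beta, brute, tolerance = 1e-4, ignore_attr = TRUE)
  }
})

test_that("mirror-symmetric arms give beta = 0", {
  tpl <- data.frame(time = c(2, 3, 3, 7, 9, 14), event = c(1, 1, 0, 1, 1, 0))
  rec <- rbind(cbind(arm = "a", tpl), cbind(arm = "b", tpl))
  fit <- cox_fit(rec, "a")
  expect_true(fit$converged)
  expect_lt(abs(fit$beta), 1e-6)
  expect_equal(fit$hr, exp(fit$beta))
})

test_that("monotone likelihood is flagged, not thrown", {
  rec <- data.frame(arm = rep(c("doomed", "safe"), each = 10),
                    time = c(1:10, rep(14, 10)),
                    event = c(rep(1L, 10), rep(0L, 10)))
  fit <- cox_fit(rec, "safe")
  expect_false(fit$converged)
  expect_true(fit$monotone)
  expect_error(cox_fit(rec[rec$arm == "safe", ], "safe"), "two arms")
  rec0 <- transform(rec, event = 0L)
  expect_error(cox_fit(rec0, "safe"), "no events")
})

test_that("Cox fit matches the survival package on simulated trials", {
  skip_if_not_installed("survival")
  tr <- simulate_survival_trial(7, n_per_arm = 60,
                                arms = c(water = 0.05, dsEGFP = 0.06,
                                         dsMESH = 0.25))
  fit <- cox_fit(tr, "water")
  ref <- survival::coxph(
    survival::Surv(time, event) ~ stats::relevel(factor(arm), "water"),
    data = tr, ties = "efron")
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
  expect_equal(fit$loglik_fit, ref$loglik[2L], tolerance = 1e-8)
  expect_equal(fit$loglik_null, ref$loglik[1L], tolerance = 1e-8)
  # Breslow route too
  fb <- cox_fit(tr, "water", ties = "breslow")
  refb <- survival::coxph(
    survival::Surv(time, event) ~ stats::relevel(factor(arm), "water"),
    data = tr, ties = "breslow")
  expect_equal(unname(fb$beta), unname(coef(refb)), tolerance = 1e-6)
})

test_that("KM curves match the survival package", {
  skip_if_not_installed("survival")
  tr <- simulate_survival_trial(15, n_per_arm = 50)
  k <- km_curve(tr, "dsMESH")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          data = tr[tr$arm == "dsMESH", ])
  at <- k$times
  ref <- summary(sf, times = at)$surv
  expect_equal(k$S, ref, tolerance = 1e-12)
})

test_that("Henderson-Tilton reproduces worked examples and scale invariance", {
  expect_equal(henderson_tilton(20, 2, 20, 20), 90)
  expect_equal(henderson_tilton(30, 15, 20, 10), 0)
  expect_equal(henderson_tilton(10, 0, 20, 18), 100)
  expect_error(henderson_tilton(20, 2, 20, 0), "control collapsed")
  # invariant to rescaling both arms' counts by a common factor
  expect_equal(henderson_tilton(40, 4, 60, 30),
               henderson_tilton(4, 0.4, 6, 3))
  # may be negative, not clamped
  expect_lt(henderson_tilton(20, 20, 20, 10), 0)
})

test_that("field summary pairs treated plots with location control means", {
  fa <- simulate_field_trial(3)
  s <- ht_field_summary(fa, "dsMESH", "control", dpt = 7)
  expect_equal(nrow(s$per_location), 3L)
  expect_equal(nrow(s$per_plot), 12L)
  expect_equal(s$pooled, mean(s$per_location$ht))
  # manual recomputation for one location
  loc <- fa[fa$location == "loc1", ]
  ctrl <- loc[loc$arm == "control", ]
  trt <- loc[loc$arm == "dsMESH", ]
  manual <- henderson_tilton(trt$n_before, trt$n_after,
                             mean(ctrl$n_before), mean(ctrl$n_after))
  expect_equal(s$per_plot$ht[s$per_plot$location == "loc1"], manual)
})

test_that("leaf damage increase and emergence rate follow their definitions", {
  expect_equal(leaf_damage_increase(10, 35), 25)
  expect_equal(leaf_damage_increase(40, 40), 0)
  expect_equal(mean(leaf_damage_increase(c(10, 20, 5, 15), c(30, 45, 20, 35))),
               mean(c(20, 25, 15, 20)))
  expect_error(leaf_damage_increase(-1, 50), "0, 100")

  er <- emergence_rate(27, 3)
  expect_equal(er$rate, 100 * 3 / 27)
  expect_equal(er$n_treated, 27)
  expect_equal(emergence_rate(30, 0)$rate, 0)
  expect_equal(emergence_rate(30, 30)$rate, 100)
  expect_error(emergence_rate(10, 11), "more emerged")
})

test_that("survival and field CSV dialects round-trip", {
  tr <- simulate_survival_trial(5, n_per_arm = 10)
  f <- withr::local_tempfile(fileext = ".csv")
  write_survival_csv(tr, f)
  expect_equal(readLines(f)[1L], "subject_id,arm,trial,time_days,event")
  back <- read_survival_csv(f)
  expect_equal(back$time, tr$time)
  expect_equal(back$event, tr$event)
  expect_equal(back$arm, tr$arm)

  fa <- simulate_field_trial(5)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_field_csv(fa, f2)
  back2 <- read_field_csv(f2)
  expect_equal(back2$n_before, fa$n_before)
  expect_equal(back2$damage_after, fa$damage_after, tolerance = 1e-6)
})
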