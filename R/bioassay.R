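# Efficacy statistics for feeding and field trials: product-limit survival
# curves, Cox proportional-hazards regression for right-censored data with
# Efron/Breslow tie handling, Henderson-Tilton corrected field mortality,
# leaf-damage and adult-emergence metrics.
#
# Survival records are data frames with columns subject_id, arm, trial,
# time (days, > 0) and event (1 = death observed, 0 = right-censored).
# Feeding trials are observed daily, so tied event times are the rule, not
# the exception; the Efron correction is the default for that reason.

validate_survival <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("arm", "time", "event") %in% names(records)))
  if (nrow(records) == 0L) stop("no survival records")
  if (any(records$time <= 0)) stop("survival times must be positive")
  if (!all(records$event %in% c(0L, 1L))) stop("event must be 0 or 1")
  records
}

#' Kaplan-Meier survival curve for one arm
#'
#' Product-limit estimator `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over the
#' distinct observed death times of the arm. At tied times, deaths are
#' processed before censorings (a subject censored at `t` is still at risk
#' at `t`).
#'
#' @param records Survival data frame (`arm`, `time`, `event`).
#' @param arm Arm label to estimate.
#' @return Object of class `km_curve`: `arm`, `times` (death times), `S`,
#'   `at_risk`, `deaths`, and `n` (arm size).
#' @export
km_curve <- function(records, arm) {
  records <- validate_survival(records)
  r <- records[records$arm == arm, , drop = FALSE]
  if (nrow(r) == 0L) stop(sprintf("no records in arm '%s'", arm))
  dt <- sort(unique(r$time[r$event == 1L]))
  at_risk <- vapply(dt, function(t) sum(r$time >= t), integer(1))
  deaths <- vapply(dt, function(t) sum(r$time == t & r$event == 1L), integer(1))
  S <- cumprod(1 - deaths / at_risk)
  structure(list(arm = arm, times = dt, S = S, at_risk = at_risk,
                 deaths = deaths, n = nrow(r)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> arm '%s', n = %d, %d death time(s)\n",
              x$arm, x$n, length(x$times)))
  if (length(x$times)) {
    print(data.frame(time = x$times, at_risk = x$at_risk, deaths = x$deaths,
                     S = round(x$S, 4)), row.names = FALSE)
  }
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param curve A `km_curve`.
#' @param times Numeric vector of times.
#' @return `S(t)` at each time (step function, right-continuous).
#' @export
km_surv_at <- function(curve, times) {
  vapply(times, function(t) {
    i <- which(curve$times <= t)
    if (length(i) == 0L) 1 else curve$S[max(i)]
  }, numeric(1))
}

# ---- Cox proportional hazards ---------------------------------------------

# Partial log-likelihood, score and information for one stratum, given a
# model matrix X, times, events and coefficients. Efron or Breslow ties.
cox_stratum_quantities <- function(X, time, event, beta, ties) {
  eta <- drop(X %*% beta)
  w <- exp(eta)
  p <- ncol(X)
  ll <- 0
  U <- numeric(p)
  I <- matrix(0, p, p)
  for (t in sort(unique(time[event == 1L]))) {
    R <- time >= t
    D <- time == t & event == 1L
    d <- sum(D)
    S0 <- sum(w[R])
    S1 <- colSums(X[R, , drop = FALSE] * w[R])
    S2 <- crossprod(X[R, , drop = FALSE] * w[R], X[R, , drop = FALSE])
    ll <- ll + sum(eta[D])
    U <- U + colSums(X[D, , drop = FALSE])
    if (ties == "breslow") {
      ll <- ll - d * log(S0)
      U <- U - d * S1 / S0
      I <- I + d * (S2 / S0 - tcrossprod(S1 / S0))
    } else {                                   # efron
      S0D <- sum(w[D])
      S1D <- colSums(X[D, , drop = FALSE] * w[D])
      S2D <- crossprod(X[D, , drop = FALSE] * w[D], X[D, , drop = FALSE])
      for (l in seq_len(d) - 1L) {
        f <- l / d
        phi <- S0 - f * S0D
        s1 <- S1 - f * S1D
        s2 <- S2 - f * S2D
        ll <- ll - log(phi)
        U <- U - s1 / phi
        I <- I + s2 / phi - tcrossprod(s1 / phi)
      }
    }
  }
  list(loglik = ll, score = U, info = I)
}

#' Cox proportional-hazards regression on treatment arms
#'
#' Maximizes the partial likelihood of arm-indicator covariates (dummies
#' against `reference_arm`) by Newton-Raphson with step-halving; convergence
#' when the score norm falls below `tol` (default 1e-8), at most `max_iter`
#' iterations. Ties are handled by the Efron correction by default (daily
#' trial observation produces heavily tied event times); Breslow is
#' available for cross-checking. When any coefficient diverges beyond
#' `divergence_bound` the fit is flagged as monotone likelihood (e.g. one
#' arm with no events) and `converged` is `FALSE` rather than an error.
#'
#' @param records Survival data frame (`arm`, `time`, `event`, optionally
#'   the column named by `strata`).
#' @param reference_arm Baseline arm for the dummies.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param strata Optional column name; the partial likelihood is then
#'   stratified (separate risk sets per stratum, shared coefficients).
#' @param tol Convergence tolerance on the score norm.
#' @param max_iter Maximum Newton iterations.
#' @param divergence_bound Absolute coefficient bound signalling monotone
#'   likelihood (default 10).
#' @return Object of class `cox_fit` with `terms`, `beta`, `se`, `hr`,
#'   `wald_z`, `wald_p`, `loglik_null`, `loglik_fit`, `lr_stat`, `lr_df`,
#'   `lr_p`, `ties_method`, `converged`, `monotone`, `n`, `n_event`,
#'   `iterations`.
#' @export
cox_fit <- function(records, reference_arm, ties = c("efron", "breslow"),
                    strata = NULL, tol = 1e-8, max_iter = 25L,
                    divergence_bound = 10) {
  records <- validate_survival(records)
  ties <- match.arg(ties)
  arms <- unique(records$arm)
  if (!(reference_arm %in% arms)) stop("reference arm not present in data")
  if (length(arms) < 2L) stop("at least two arms are required")
  if (sum(records$event) == 0L) stop("no events observed")
  f <- stats::relevel(factor(records$arm), ref = reference_arm)
  X <- stats::model.matrix(~f)[, -1L, drop = FALSE]
  colnames(X) <- paste0("arm", levels(f)[-1L])
  if (is.null(strata)) {
    groups <- rep(1L, nrow(records))
  } else {
    stopifnot(strata %in% names(records))
    groups <- as.integer(factor(records[[strata]]))
  }
  idx <- split(seq_len(nrow(records)), groups)
  p <- ncol(X)
  total <- function(beta) {
    parts <- lapply(idx, function(i) {
      cox_stratum_quantities(X[i, , drop = FALSE], records$time[i],
                             records$event[i], beta, ties)
    })
    list(loglik = sum(vapply(parts, `[[`, numeric(1), "loglik")),
         score = Reduce(`+`, lapply(parts, `[[`, "score")),
         info = Reduce(`+`, lapply(parts, `[[`, "info")))
  }
  beta <- numeric(p)
  q0 <- total(beta)
  loglik_null <- q0$loglik
  q <- q0
  converged <- FALSE
  monotone <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (sqrt(sum(q$score^2)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(q$info, q$score), error = function(e) NULL)
    if (is.null(step)) { monotone <- TRUE; break }
    new_beta <- beta + step
    q_new <- total(new_beta)
    halvings <- 0L
    while (!is.finite(q_new$loglik) || q_new$loglik < q$loglik - 1e-12) {
      halvings <- halvings + 1L
      if (halvings > 20L) break
      new_beta <- beta + (new_beta - beta) / 2
      q_new <- total(new_beta)
    }
    beta <- new_beta
    q <- q_new
    if (any(abs(beta) > divergence_bound)) { monotone <- TRUE; break }
  }
  if (sqrt(sum(q$score^2)) < tol && !monotone) converged <- TRUE
  if (monotone) converged <- FALSE
  se <- tryCatch(sqrt(diag(solve(q$info))), error = function(e) rep(NA_real_, p))
  z <- beta / se
  lr_stat <- max(0, 2 * (q$loglik - loglik_null))
  structure(list(
    terms = colnames(X), beta = beta, se = se, hr = exp(beta),
    wald_z = z, wald_p = 2 * stats::pnorm(-abs(z)),
    loglik_null = loglik_null, loglik_fit = q$loglik,
    lr_stat = lr_stat, lr_df = p,
    lr_p = stats::pchisq(lr_stat, df = p, lower.tail = FALSE),
    ties_method = ties, converged = converged, monotone = monotone,
    n = nrow(records), n_event = sum(records$event), iterations = iter),
    class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d, ties = %s, %s\n",
              x$n, x$n_event, x$ties_method,
              if (x$converged) sprintf("converged in %d iteration(s)", x$iterations)
              else if (x$monotone) "NOT converged (monotone likelihood)"
              else "NOT converged"))
  print(data.frame(term = x$terms, beta = round(x$beta, 4),
                   se = round(x$se, 4), HR = round(x$hr, 4),
                   p = signif(x$wald_p, 3)), row.names = FALSE)
  cat(sprintf("Likelihood ratio = %.3f on %d df, p = %.3g\n",
              x$lr_stat, x$lr_df, x$lr_p))
  invisible(x)
}

# ---- field-trial metrics ---------------------------------------------------

#' Henderson-Tilton corrected mortality
#'
#' `100 * (1 - (treated_after * control_before) /
#' (treated_before * control_after))`: treatment kill corrected for the
#' natural population change observed in untreated control plots. The value
#' may be negative (population grew faster under treatment) and is not
#' clamped.
#'
#' @param treated_before,treated_after Larval counts on the treated plot at
#'   day 0 and at assessment.
#' @param control_before,control_after Counts on the paired control plot.
#' @return Corrected mortality in percent.
#' @examples
#' henderson_tilton(20, 2, 20, 20)  # 90
#' @export
henderson_tilton <- function(treated_before, treated_after,
                             control_before, control_after) {
  if (any(control_after == 0)) stop("control collapsed; Henderson-Tilton undefined")
  if (any(treated_before <= 0) || any(control_before <= 0)) {
    stop("before-treatment counts must be positive")
  }
  100 * (1 - (treated_after * control_before) /
           (treated_before * control_after))
}

#' Per-location and pooled Henderson-Tilton summary of a field trial
#'
#' For each treated replicate plot, corrected mortality is computed against
#' the mean before/after counts of the control plots at the same location;
#' per-location means and the pooled mean over locations are reported.
#'
#' @param assessments Field data frame with columns `location`, `plot`,
#'   `arm`, `n_before`, `n_after` (and optionally `dpt`, filtered when
#'   `dpt` is given).
#' @param treated_arm,control_arm Arm labels.
#' @param dpt Optional assessment day filter.
#' @return List with `per_plot`, `per_location` (data frames) and `pooled`
#'   (mean of location means, percent).
#' @export
ht_field_summary <- function(assessments, treated_arm, control_arm, dpt = NULL) {
  a <- assessments
  if (!is.null(dpt)) a <- a[a$dpt == dpt, , drop = FALSE]
  if (nrow(a) == 0L) stop("no assessments selected")
  per_plot <- do.call(rbind, lapply(split(a, a$location), function(loc) {
    ctrl <- loc[loc$arm == control_arm, , drop = FALSE]
    trt <- loc[loc$arm == treated_arm, , drop = FALSE]
    if (nrow(ctrl) == 0L || nrow(trt) == 0L) {
      stop(sprintf("location '%s' lacks treated or control plots",
                   loc$location[1L]))
    }
    cb <- mean(ctrl$n_before); ca <- mean(ctrl$n_after)
    data.frame(location = trt$location, plot = trt$plot,
               ht = henderson_tilton(trt$n_before, trt$n_after, cb, ca))
  }))
  rownames(per_plot) <- NULL
  per_location <- aggregate(ht ~ location, data = per_plot, FUN = mean)
  list(per_plot = per_plot, per_location = per_location,
       pooled = mean(per_location$ht))
}

#' Leaf damage increase
#'
#' Final minus initial percent defoliation over the observation window; may
#' be negative when foliage regrows.
#'
#' @param damage_before,damage_after Leaf damage percentages in `[0, 100]`.
#' @return Difference in percentage points.
#' @export
leaf_damage_increase <- function(damage_before, damage_after) {
  if (any(damage_before < 0 | damage_before > 100 |
          damage_after < 0 | damage_after > 100)) {
    stop("leaf damage must be in [0, 100]")
  }
  damage_after - damage_before
}

#' Adult emergence rate
#'
#' @param n_treated Number of larvae entering the assay (> 0).
#' @param n_emerged Number emerging as adults (≤ `n_treated`).
#' @return List with `rate` (percent), `n_treated`, `n_emerged`.
#' @examples
#' emergence_rate(27, 3)$rate  # 11.1...
#' @export
emergence_rate <- function(n_treated, n_emerged) {
  if (n_treated <= 0) stop("n_treated must be positive")
  if (n_emerged > n_treated) stop("more emerged than treated")
  if (n_emerged < 0) stop("n_emerged must be non-negative")
  list(rate = 100 * n_emerged / n_treated,
       n_treated = n_treated, n_emerged = n_emerged)
}

# ---- CSV dialects ----------------------------------------------------------

#' Read a survival CSV (`subject_id,arm,trial,time_days,event`)
#'
#' @param path CSV path.
#' @return Survival data frame with columns `subject_id`, `arm`, `trial`,
#'   `time`, `event`.
#' @export
read_survival_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "arm", "trial", "time_days", "event")
  if (!all(need %in% names(df))) {
    stop(sprintf("survival CSV must have columns: %s", paste(need, collapse = ",")))
  }
  out <- data.frame(subject_id = as.character(df$subject_id),
                    arm = as.character(df$arm),
                    trial = as.character(df$trial),
                    time = as.numeric(df$time_days),
                    event = as.integer(df$event))
  validate_survival(out)
}

#' Write a survival data frame in the package CSV dialect
#'
#' @param records Survival data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survival_csv <- function(records, path) {
  records <- validate_survival(records)
  if (is.null(records$subject_id)) {
    records$subject_id <- sprintf("s%04d", seq_len(nrow(records)))
  }
  if (is.null(records$trial)) records$trial <- "trial1"
  out <- data.frame(subject_id = records$subject_id, arm = records$arm,
                    trial = records$trial, time_days = records$time,
                    event = records$event)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a field-assessment CSV
#'
#' Columns: `location,plot,arm,n_before,n_after,dpt,damage_before,damage_after`.
#'
#' @param path CSV path.
#' @return Field-assessment data frame.
#' @export
read_field_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("location", "plot", "arm", "n_before", "n_after", "dpt",
            "damage_before", "damage_after")
  if (!all(need %in% names(df))) {
    stop(sprintf("field CSV must have columns: %s", paste(need, collapse = ",")))
  }
  if (any(df$n_before < 0 | df$n_after < 0)) stop("counts must be non-negative")
  if (any(df$damage_before < 0 | df$damage_before > 100 |
          df$damage_after < 0 | df$damage_after > 100)) {
    stop("leaf damage must be in [0, 100]")
  }
  df
}

#' Write a field-assessment data frame as CSV
#'
#' @param assessments Field-assessment data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(assessments, path) {
  utils::write.csv(assessments, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
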