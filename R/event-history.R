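#' Build the day-level discrete-time event-history table
#'
#' One record per participant-day with a defined local dynamic complexity:
#' the binary outcome (a classified transition occurs on this day), the
#' progressive study day (`time`), the `duration` clock (days since the most
#' recent prior event of either direction, or since study start; 1 on the
#' first study day and on the day after an event), and the LDC predictor.
#' Censored participants — those with no events — contribute all-zero outcome
#' rows, and days with undefined LDC (the window plus lag warm-up at the start
#' of each series) are excluded; this is the only exclusion applied.
#'
#' @param trace Trace tibble from [complexity_trace()] (must carry `ldc`).
#' @param events Event tibble from [detect_transitions()].
#' @return Tibble with `participant_id`, `day`, `time`, `duration`, `ldc`,
#'   `gain`, `loss`, `event` (0/1 columns).
#' @export
#' @examples
#' cfg <- cohort_config(n_participants = 2, seed = 3)
#' coh <- simulate_cohort(cfg)
#' prep <- prepare_steps(coh$steps)
#' ev <- detect_transitions(prep)
#' tab <- build_event_table(complexity_trace(prep), ev)
#' sum(tab$event)
build_event_table <- function(trace, events) {
  check_columns(trace, c("participant_id", "day", "ldc"), "complexity trace")
  check_columns(events, c("participant_id", "day", "direction"), "events")

  ranges <- trace %>%
    group_by(.data$participant_id) %>%
    summarise(min_day = min(.data$day), max_day = max(.data$day), .groups = "drop")
  ev_chk <- events %>% left_join(ranges, by = "participant_id")
  if (any(is.na(ev_chk$min_day)) ||
    any(ev_chk$day < ev_chk$min_day | ev_chk$day > ev_chk$max_day)) {
    stop_stepdyn("event day outside the participant's series range")
  }

  trace %>%
    group_by(.data$participant_id) %>%
    group_split() %>%
    purrr::map(function(d) {
      ev <- events %>% filter(.data$participant_id == d$participant_id[1])
      gain_days <- ev$day[ev$direction == "gain"]
      loss_days <- ev$day[ev$direction == "loss"]
      ev_days <- sort(ev$day)
      # duration clock over the full day grid: day minus the most recent
      # strictly earlier event day (0 if none), so it is 1 the day after an
      # event and equals the study day before any event
      last_ev <- vapply(d$day, function(dd) {
        prior <- ev_days[ev_days < dd]
        if (length(prior) == 0) 0L else as.integer(max(prior))
      }, integer(1))
      tibble(
        participant_id = d$participant_id[1],
        day = d$day,
        time = d$day,
        duration = d$day - last_ev,
        ldc = d$ldc,
        gain = as.integer(d$day %in% gain_days),
        loss = as.integer(d$day %in% loss_days),
        event = as.integer(d$day %in% ev_days)
      )
    }) %>%
    bind_rows() %>%
    filter(!is.na(.data$ldc))
}

#' Z-score continuous predictors over all included records
#'
#' Grand (pooled) standardization: each predictor is centred on its mean and
#' scaled by its SD over all rows, so model coefficients are per-1-SD effects.
#' The scaling metadata is attached for back-transformation.
#'
#' @param records Event-history tibble from [build_event_table()].
#' @param vars Character vector of columns to standardize.
#' @return `records` with the named columns z-scored and an attribute
#'   `"scaling"`: a tibble of `variable`, `mean`, `sd`.
#' @export
standardize_predictors <- function(records, vars = c("time", "duration", "ldc")) {
  check_columns(records, vars, "event-history records")
  scaling <- tibble(
    variable = vars,
    mean = vapply(vars, function(v) mean(records[[v]]), numeric(1)),
    sd = vapply(vars, function(v) sd(records[[v]]), numeric(1))
  )
  zero <- scaling$variable[scaling$sd == 0 | is.na(scaling$sd)]
  if (length(zero) > 0) {
    stop_stepdyn(sprintf(
      "predictor(s) with zero variance: %s", paste(zero, collapse = ", ")
    ))
  }
  for (v in vars) {
    records[[v]] <- (records[[v]] - scaling$mean[scaling$variable == v]) /
      scaling$sd[scaling$variable == v]
  }
  attr(records, "scaling") <- scaling
  records
}

#' Fit the multilevel discrete-time event-history model
#'
#' Mixed-effects logistic regression of the daily event hazard on the
#' standardized progressive day (`time`), inter-event `duration` clock, and
#' local dynamic complexity (`ldc`), with a random intercept and mutually
#' uncorrelated random slopes for all three predictors by participant
#' (diagonal random-effects covariance, i.e. the `||` formula):
#'
#' `outcome ~ time + duration + ldc + (1 + time + duration + ldc || participant_id)`
#'
#' Estimation is maximum likelihood with the Laplace approximation
#' ([lme4::glmer()]). When the fit is singular (a random-slope variance
#' estimated at zero), the offending slope with the smallest variance is
#' dropped and the model refit, with a message; the random intercept is always
#' retained.
#'
#' @param records Event-history tibble from [build_event_table()].
#' @param outcome `"both"` (any event), `"gains"` or `"losses"`. The
#'   single-direction models keep only participants with at least one event of
#'   that direction and code the outcome as that direction only (other-direction
#'   event days remain at-risk days with outcome 0; the duration clock still
#'   resets at every event).
#' @param standardize Z-score `time`, `duration`, `ldc` before fitting
#'   (default `TRUE`).
#' @param drop_singular Drop zero-variance random slopes and refit (default
#'   `TRUE`).
#' @param control A [lme4::glmerControl()]; the default uses `bobyqa` with
#'   derivative checks off for speed and determinism.
#' @param nAGQ Integration order passed to [lme4::glmer()] (default 1,
#'   Laplace).
#' @return An object of class `stepdyn_ehm`.
#' @export
fit_event_model <- function(records, outcome = c("both", "gains", "losses"),
                            standardize = TRUE, drop_singular = TRUE,
                            control = NULL, nAGQ = 1L) {
  outcome <- match.arg(outcome)
  check_columns(records, c("participant_id", "time", "duration", "ldc",
                           "gain", "loss", "event"), "event-history records")
  control <- control %||% lme4::glmerControl(
    optimizer = "bobyqa", calc.derivs = FALSE,
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4)
  )

  yvar <- switch(outcome, both = "event", gains = "gain", losses = "loss")
  dat <- records
  if (outcome != "both") {
    keep <- dat %>%
      group_by(.data$participant_id) %>%
      summarise(has = sum(.data[[yvar]]) > 0, .groups = "drop") %>%
      filter(.data$has) %>%
      pull(.data$participant_id)
    dat <- dat %>% filter(.data$participant_id %in% keep)
  }
  if (n_distinct(dat$participant_id) < 2) {
    stop_stepdyn("fewer than 2 participants after outcome subsetting")
  }
  if (length(unique(dat[[yvar]])) < 2) {
    stop_stepdyn("outcome has a single class; cannot fit")
  }

  scaling <- NULL
  if (standardize) {
    dat <- standardize_predictors(dat)
    scaling <- attr(dat, "scaling")
  }
  dat$.y <- dat[[yvar]]
  dat$participant_id <- factor(dat$participant_id)

  slopes <- c("time", "duration", "ldc")
  fit_with <- function(sl) {
    re <- paste(c("1", sl), collapse = " + ")
    f <- as.formula(paste0(".y ~ time + duration + ldc + (", re, " || participant_id)"))
    lme4::glmer(f, data = dat, family = binomial(), control = control, nAGQ = nAGQ)
  }
  fit <- fit_with(slopes)
  dropped <- character(0)
  if (drop_singular) {
    while (length(slopes) > 0 && lme4::isSingular(fit, tol = 1e-4)) {
      vc <- as.data.frame(lme4::VarCorr(fit))
      vc <- vc[vc$var1 %in% slopes & is.na(vc$var2), ]
      worst <- vc$var1[which.min(vc$vcov)]
      message(sprintf(
        "singular fit: dropping random slope for '%s' and refitting", worst
      ))
      dropped <- c(dropped, worst)
      slopes <- setdiff(slopes, worst)
      fit <- fit_with(slopes)
    }
  }
  conv <- fit@optinfo$conv$opt == 0 &&
    length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0

  structure(
    list(
      fit = fit,
      outcome = outcome,
      data = dat,
      scaling = scaling,
      random_slopes = slopes,
      dropped_slopes = dropped,
      n_participants = n_distinct(dat$participant_id),
      n_records = nrow(dat),
      n_events = sum(dat$.y),
      converged = conv,
      singular = lme4::isSingular(fit, tol = 1e-4)
    ),
    class = "stepdyn_ehm"
  )
}

#' Odds ratios with confidence intervals for an event-history model
#'
#' `OR = exp(beta)` for each fixed effect. Profile confidence intervals are
#' computed by bisection on the profiled deviance at the chi-square(1) cutoff:
#' each fixed-effect coefficient is in turn constrained via an offset and the
#' model refit, and the interval bound is the coefficient value where the
#' deviance rises by `qchisq(level, 1)` above the minimum. Wald intervals
#' (`beta +/- z * SE`) are the fallback when profiling fails, flagged in
#' `ci_method`.
#'
#' @param object A `stepdyn_ehm` from [fit_event_model()].
#' @param method `"wald"` (fast, default) or `"profile"` (likelihood profile,
#'   as reported in the main analysis of this design).
#' @param level Confidence level (default 0.95).
#' @param terms Fixed-effect terms to report (default: all but the intercept).
#' @return Tibble with `term`, `estimate` (log-odds), `or`, `conf.low`,
#'   `conf.high` (on the OR scale), `ci_method`.
#' @export
compute_odds_ratios <- function(object, method = c("wald", "profile"),
                                level = 0.95, terms = NULL) {
  stopifnot(inherits(object, "stepdyn_ehm"))
  method <- match.arg(method)
  fit <- object$fit
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  terms <- terms %||% setdiff(names(beta), "(Intercept)")
  z <- qnorm(1 - (1 - level) / 2)

  rows <- purrr::map(terms, function(tm) {
    b <- beta[[tm]]
    s <- se[[tm]]
    lo <- b - z * s
    hi <- b + z * s
    ci_method <- "wald"
    if (method == "profile") {
      prof <- tryCatch(
        profile_ci_offset(object, tm, level = level),
        error = function(e) NULL
      )
      if (!is.null(prof) && all(is.finite(prof)) && prof[1] < b && prof[2] > b) {
        lo <- prof[1]
        hi <- prof[2]
        ci_method <- "profile"
      } else {
        warning(sprintf(
          "profile CI failed for '%s'; falling back to Wald", tm
        ), call. = FALSE)
      }
    }
    tibble(
      term = tm, estimate = b, or = exp(b),
      conf.low = exp(lo), conf.high = exp(hi), ci_method = ci_method
    )
  })
  bind_rows(rows)
}

#' Profile one fixed-effect coefficient by offset refitting
#'
#' The coefficient of `term` is fixed at trial values `b` by moving
#' `b * x_term` into the model offset and dropping the column; the profiled
#' deviance as a function of `b` is bisected (via [uniroot()]) for the points
#' where it exceeds the full-model deviance by the chi-square(1) quantile.
#'
#' @noRd
profile_ci_offset <- function(object, term, level = 0.95) {
  fit <- object$fit
  dat <- object$data
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  b_hat <- beta[[term]]
  s_hat <- se[[term]]
  cutoff <- qchisq(level, 1)
  dev_hat <- deviance(fit)

  others <- setdiff(c("time", "duration", "ldc"), term)
  re <- paste(c("1", object$random_slopes), collapse = " + ")
  rhs <- paste(
    c(others, "offset(.off)", sprintf("(%s || participant_id)", re)),
    collapse = " + "
  )
  f <- as.formula(paste0(".y ~ ", rhs))
  x <- dat[[term]]
  control <- lme4::glmerControl(
    optimizer = "bobyqa", calc.derivs = FALSE,
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4)
  )
  prof_dev <- function(b) {
    dat$.off <- b * x
    m <- suppressWarnings(suppressMessages(lme4::glmer(f,
      data = dat, family = binomial(),
      control = control, nAGQ = 1L
    )))
    deviance(m)
  }
  g <- function(b) prof_dev(b) - dev_hat - cutoff

  find_bound <- function(direction) {
    span <- 2
    repeat {
      b_out <- b_hat + direction * span * s_hat
      if (g(b_out) > 0 || span > 16) break
      span <- span * 2
    }
    if (g(b_out) <= 0) {
      stop("profiled deviance did not cross the cutoff")
    }
    uniroot(g, sort(c(b_hat, b_out)), tol = s_hat * 1e-3)$root
  }
  c(find_bound(-1), find_bound(1))
}

#' @export
print.stepdyn_ehm <- function(x, ...) {
  cat(sprintf(
    "<stepdyn_ehm> outcome = %s | N = %d participants, k = %d person-days, %d events\n",
    x$outcome, x$n_participants, x$n_records, x$n_events
  ))
  if (length(x$dropped_slopes) > 0) {
    cat("  dropped singular random slopes:", paste(x$dropped_slopes, collapse = ", "), "\n")
  }
  ors <- compute_odds_ratios(x)
  for (i in seq_len(nrow(ors))) {
    cat(sprintf(
      "  %-9s OR = %.3f  95%% CI [%.3f, %.3f]\n",
      ors$term[i], ors$or[i], ors$conf.low[i], ors$conf.high[i]
    ))
  }
  invisible(x)
}

#' Tidy an event-history model fit
#'
#' @param x A `stepdyn_ehm` from [fit_event_model()].
#' @param exponentiate Report odds ratios instead of log-odds (default
#'   `FALSE`).
#' @param conf.int Include confidence intervals (default `TRUE`).
#' @param conf.level Confidence level.
#' @param ci_method `"wald"` or `"profile"`.
#' @param ... Unused.
#' @return A tibble with one row per fixed effect.
#' @importFrom broom tidy
#' @method tidy stepdyn_ehm
#' @export
tidy.stepdyn_ehm <- function(x, exponentiate = FALSE, conf.int = TRUE,
                             conf.level = 0.95, ci_method = "wald", ...) {
  ors <- compute_odds_ratios(x, method = ci_method, level = conf.level)
  out <- ors %>%
    mutate(
      estimate = if (exponentiate) .data$or else .data$estimate,
      conf.low = if (exponentiate) .data$conf.low else log(.data$conf.low),
      conf.high = if (exponentiate) .data$conf.high else log(.data$conf.high)
    ) %>%
    select(all_of(c("term", "estimate", "conf.low", "conf.high", "ci_method")))
  if (!conf.int) out <- out %>% select(all_of(c("term", "estimate")))
  out
}

#' Glance at an event-history model fit
#'
#' @param x A `stepdyn_ehm`.
#' @param ... Unused.
#' @return One-row tibble of model-level summaries.
#' @importFrom broom glance
#' @method glance stepdyn_ehm
#' @export
glance.stepdyn_ehm <- function(x, ...) {
  tibble(
    outcome = x$outcome,
    n_participants = x$n_participants,
    n_records = x$n_records,
    n_events = x$n_events,
    logLik = as.numeric(logLik(x$fit)),
    AIC = AIC(x$fit),
    BIC = BIC(x$fit),
    deviance = deviance(x$fit),
    converged = x$converged,
    singular = x$singular,
    dropped_slopes = paste(x$dropped_slopes, collapse = ",")
  )
}

#' @export
broom::tidy

#' @export
broom::glance
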