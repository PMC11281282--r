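#' One- and two-tailed unpaired two-sample t-test
#'
#' Student's t-test for two independent groups, from raw values or from
#' summary statistics (mean, sd, n) as printed in demographic tables. The
#' default is the pooled-variance Student test; `pooled = FALSE` gives the
#' Welch test with Satterthwaite degrees of freedom. Both the one-sided
#' p-value (for the stated `alternative` on group A vs group B) and the
#' two-sided p-value are reported.
#'
#' @param groupA,groupB numeric vectors of raw values, or numeric vectors
#'   named `mean`, `sd`, `n` (e.g. `c(mean = 42.0, sd = 6.5, n = 12)`).
#' @param alternative `"greater"` (A > B) or `"less"` (A < B); direction of
#'   the one-sided alternative.
#' @param pooled use the pooled-variance Student test (default) or Welch.
#' @return list with `t`, `df`, `p_one_sided`, `p_two_sided`, `estimate`
#'   (difference of means A - B), `pooled`, `alternative`.
#' @examples
#' tTestOneTailed(c(mean = 42.0, sd = 6.5, n = 12),
#'                c(mean = 47.9, sd = 6.6, n = 14), alternative = "less")
#' @export
tTestOneTailed <- function(groupA, groupB,
                           alternative = c("greater", "less"),
                           pooled = TRUE) {
  alternative <- match.arg(alternative)
  summarize <- function(g) {
    if (!is.null(names(g)) && all(c("mean", "sd", "n") %in% names(g))) {
      list(mean = unname(g["mean"]), sd = unname(g["sd"]),
           n = unname(g["n"]))
    } else {
      if (length(g) < 2L)
        stop("each group needs n >= 2 raw values (or mean/sd/n summaries)")
      list(mean = mean(g), sd = stats::sd(g), n = length(g))
    }
  }
  a <- summarize(groupA)
  b <- summarize(groupB)
  if (a$n < 2 || b$n < 2)
    stop("each group needs n >= 2")
  if (a$sd == 0 && b$sd == 0 && a$mean == b$mean)
    stop("t statistic undefined: both groups have zero variance and equal ",
         "means")
  diff <- a$mean - b$mean
  if (pooled) {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    va <- a$sd^2 / a$n
    vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  t <- diff / se
  pTwo <- 2 * stats::pt(-abs(t), df)
  pOne <- if (alternative == "greater") {
    stats::pt(t, df, lower.tail = FALSE)
  } else {
    stats::pt(t, df)
  }
  list(t = t, df = df, p_one_sided = pOne, p_two_sided = pTwo,
       estimate = diff, pooled = pooled, alternative = alternative)
}

#' Random-intercept model on log percent fiber volume
#'
#' Fits `log(percent_fiber_volume) ~ group + (1 | patient_id)` by restricted
#' maximum likelihood: the tissue block (patient) is the random intercept and
#' recurrence status the fixed effect. Individual FOV volumes are
#' right-skewed, so the natural log is taken before fitting. The two-sided
#' p-value for the group effect uses Satterthwaite degrees of freedom
#' (falling back to the normal approximation if unavailable; the choice is
#' recorded in `df_method`), and the one-sided p-value tests the alternative
#' that the recurrent group has higher volumes.
#'
#' Non-positive volumes abort by default, naming the offending records; set
#' `zeroPolicy = "offset"` to fit `log(x + delta)` with `delta` half the
#' smallest positive observed volume.
#'
#' @param fovs data.frame with columns `patient_id`, `group` (values
#'   `non_recurrent` / `recurrent`), `percent_fiber_volume`.
#' @param zeroPolicy `"error"` (default) or `"offset"`.
#' @return list with `beta_group`, `se_beta`, `df`, `df_method`,
#'   `p_two_sided`, `p_one_sided`, `var_between`, `var_within`,
#'   `n_patients`, `n_fovs`, `transform`, and the fitted `model`.
#' @export
fitRandomIntercept <- function(fovs, zeroPolicy = c("error", "offset")) {
  zeroPolicy <- match.arg(zeroPolicy)
  need <- c("patient_id", "group", "percent_fiber_volume")
  if (!all(need %in% names(fovs)))
    stop("'fovs' must have columns ", paste(need, collapse = ", "))
  v <- fovs$percent_fiber_volume
  offset <- 0
  if (any(v <= 0)) {
    if (zeroPolicy == "error") {
      bad <- which(v <= 0)
      stop("non-positive percent fiber volume for record(s) ",
           paste(utils::head(bad, 10), collapse = ", "),
           "; use zeroPolicy = \"offset\" to fit log(x + delta)")
    }
    pos <- v[v > 0]
    if (length(pos) == 0L)
      stop("no positive volumes to define the offset")
    offset <- min(pos) / 2
  }
  grp <- factor(as.character(fovs$group),
                levels = c("non_recurrent", "recurrent"))
  if (anyNA(grp))
    stop("'group' must be 'non_recurrent' or 'recurrent'")
  nPat <- table(unique(data.frame(g = grp, p = fovs$patient_id))$g)
  if (any(nPat < 2L))
    stop("need at least 2 patients per group")
  dat <- data.frame(y = log(v + offset), group = grp,
                    patient_id = factor(fovs$patient_id))
  fit <- lmerTest::lmer(y ~ group + (1 | patient_id), data = dat,
                        REML = TRUE)
  cf <- tryCatch(stats::coef(summary(fit)), error = function(e) NULL)
  beta <- lme4::fixef(fit)[["grouprecurrent"]]
  vc <- as.data.frame(lme4::VarCorr(fit))
  varBetween <- vc$vcov[vc$grp == "patient_id"]
  varWithin <- vc$vcov[vc$grp == "Residual"]
  if (!is.null(cf) && "Pr(>|t|)" %in% colnames(cf) &&
      is.finite(cf["grouprecurrent", "Pr(>|t|)"])) {
    se <- cf["grouprecurrent", "Std. Error"]
    df <- cf["grouprecurrent", "df"]
    pTwo <- cf["grouprecurrent", "Pr(>|t|)"]
    dfMethod <- "satterthwaite"
  } else {
    se <- sqrt(diag(stats::vcov(fit)))[["grouprecurrent"]]
    df <- Inf
    pTwo <- 2 * stats::pnorm(-abs(beta / se))
    dfMethod <- "normal"
  }
  pOne <- if (beta > 0) pTwo / 2 else 1 - pTwo / 2
  list(beta_group = beta, se_beta = se, df = df, df_method = dfMethod,
       p_two_sided = pTwo, p_one_sided = pOne, var_between = varBetween,
       var_within = varWithin,
       n_patients = length(unique(fovs$patient_id)), n_fovs = nrow(fovs),
       transform = if (offset > 0) sprintf("log(x + %.6g)", offset) else
         "log", model = fit)
}

#' Median split of patients by mean fiber volume
#'
#' Dichotomizes a patient table at the sample median of `mean_volume`:
#' strictly greater goes to the high-fiber group, less than or equal
#' (including ties at the median) to the low-fiber group. The tie policy is
#' recorded in the output.
#'
#' @param patients data.frame with columns `patient_id`, `mean_volume` (and
#'   typically `time`, `event`).
#' @return list with `threshold`, `high`, `low` (row subsets), `assignment`
#'   (factor aligned to the input rows, levels `low`/`high`) and
#'   `tie_policy`.
#' @export
medianSplit <- function(patients) {
  if (!all(c("patient_id", "mean_volume") %in% names(patients)))
    stop("'patients' must have columns patient_id and mean_volume")
  if (nrow(patients) < 4L)
    stop("median split needs at least 4 patients")
  v <- patients$mean_volume
  if (length(unique(v)) == 1L)
    stop("all volumes identical: median split undefined")
  thr <- stats::median(v)
  hi <- v > thr
  list(threshold = thr,
       high = patients[hi, , drop = FALSE],
       low = patients[!hi, , drop = FALSE],
       assignment = factor(ifelse(hi, "high", "low"),
                           levels = c("low", "high")),
       tie_policy = "ties_to_low")
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function. Censored subjects leave
#' the risk set after their recorded time; the curve starts at 1 and is
#' non-increasing.
#'
#' @param times positive survival times.
#' @param events event indicators (1 = event observed, 0 = censored).
#' @return data.frame with columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`, one row per distinct observed time.
#' @examples
#' km <- kaplanMeier(c(1, 2, 3, 4, 5), c(1, 0, 1, 1, 0))
#' km$surv
#' @export
kaplanMeier <- function(times, events) {
  if (any(times <= 0))
    stop("survival times must be > 0")
  if (!all(events %in% c(0, 1)))
    stop("'events' must be 0/1")
  sf <- survival::survfit(survival::Surv(times, events) ~ 1,
                          conf.type = "none")
  data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
             n_censor = sf$n.censor, surv = sf$surv)
}

#' Log-rank test and hazard ratio between two survival groups
#'
#' Standard log-rank statistic over the pooled event times, with the hazard
#' ratio of the high group versus the low group estimated from the log-rank
#' observed and expected event counts, `(O_high/E_high) / (O_low/E_low)`. A
#' Cox partial-likelihood estimate is reported alongside as `hr_cox`.
#'
#' @param high,low data.frames with columns `time` and `event` (e.g. the
#'   `high`/`low` elements of [medianSplit()]).
#' @return list with `chi2`, `p`, `hr` (O/E estimator), `hr_cox`, `obs`,
#'   `expected` (named per group), `n`.
#' @export
logrankHazardRatio <- function(high, low) {
  for (df in list(high, low))
    if (!all(c("time", "event") %in% names(df)))
      stop("'high' and 'low' need columns time and event")
  if (nrow(high) == 0L || nrow(low) == 0L)
    stop("both groups must be non-empty")
  dat <- data.frame(
    time = c(high$time, low$time),
    event = c(high$event, low$event),
    grp = factor(rep(c("high", "low"), c(nrow(high), nrow(low))),
                 levels = c("low", "high")))
  if (sum(dat$event) == 0L)
    stop("no events: log-rank test undefined")
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, data = dat)
  obs <- sd$obs
  expd <- sd$exp
  names(obs) <- names(expd) <- levels(dat$grp)
  hr <- if (obs["low"] == 0 || expd["high"] == 0) {
    Inf
  } else {
    (obs["high"] / expd["high"]) / (obs["low"] / expd["low"])
  }
  hrCox <- tryCatch(
    unname(exp(stats::coef(survival::coxph(
      survival::Surv(time, event) ~ grp, data = dat)))),
    warning = function(w) NA_real_, error = function(e) NA_real_)
  list(chi2 = sd$chisq, p = stats::pchisq(sd$chisq, df = 1,
       lower.tail = FALSE), hr = unname(hr), hr_cox = hrCox,
       obs = obs, expected = expd, n = nrow(dat))
}

#' Median-split survival analysis
#'
#' Convenience chain: [medianSplit()] on the patient table, Kaplan-Meier
#' curves per group, and the log-rank test with the O/E hazard ratio.
#'
#' @param patients data.frame with columns `patient_id`, `mean_volume`,
#'   `time`, `event`.
#' @return list with `split`, `km_high`, `km_low`, and `test`
#'   (the [logrankHazardRatio()] output).
#' @export
survivalByFiberVolume <- function(patients) {
  if (!all(c("time", "event") %in% names(patients)))
    stop("'patients' must have columns time and event")
  sp <- medianSplit(patients)
  list(split = sp,
       km_high = kaplanMeier(sp$high$time, sp$high$event),
       km_low = kaplanMeier(sp$low$time, sp$low$event),
       test = logrankHazardRatio(sp$high, sp$low))
}

#' SHG detection wavelength
#'
#' Second harmonic generation emits at exactly half the excitation
#' wavelength; an 860 nm excitation is detected at 430 nm.
#'
#' @param excitationNm excitation wavelength in nanometres.
#' @return detection wavelength in nanometres.
#' @examples
#' shgDetectionWavelength(860)
#' @export
shgDetectionWavelength <- function(excitationNm) {
  stopifnot(is.numeric(excitationNm), all(excitationNm > 0))
  excitationNm / 2
}
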