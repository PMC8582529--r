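# Survival and group-comparison statistics: Wilcoxon rank-sum,
# Kaplan-Meier / log-rank, Cox proportional hazards, Pearson correlation
# and contingency summaries. All standard machinery is delegated to
# stats and the survival package; these wrappers fix the conventions
# (two-sided tests, Efron ties, Wald CIs) and the output shapes used by
# the evaluation report.

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when the smaller group has at most 8 observations
#' and there are no ties; otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param x,y numeric vectors, both non-empty.
#' @return list with `statistic` (the Mann-Whitney U of `x` vs `y`) and
#'   `p.value`.
#' @examples
#' wilcoxonRankSum(c(1, 2), c(3, 4))$p.value  # 1/3 by exact enumeration
#' @export
wilcoxonRankSum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= 8 && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Kaplan-Meier curves and log-rank comparison
#'
#' Product-limit estimates with right censoring per group, and the
#' log-rank chi-square test across groups.
#'
#' @param time non-negative event/censoring times.
#' @param event 0/1 event indicators.
#' @param group group labels (any atomic vector; every group must be
#'   non-empty).
#' @return list with `curves` (data.frame: `group`, `time`, `nRisk`,
#'   `nEvent`, `surv`), `chisq`, `df`, `p.value`, and the underlying
#'   `survfit` object as `fit`.
#' @export
kmLogrank <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (any(time < 0)) stop("times must be non-negative")
  group <- as.factor(group)
  if (any(table(group) == 0) || nlevels(group) < 2)
    stop("every group must contain at least one subject")
  df <- data.frame(time = time, event = .asBinary(event), group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  strata <- rep(names(fit$strata), fit$strata)
  curves <- data.frame(group = sub("^group=", "", strata),
                       time = fit$time, nRisk = fit$n.risk,
                       nEvent = fit$n.event, surv = fit$surv)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  dfree <- length(sd$n) - 1
  list(curves = curves, chisq = sd$chisq, df = dfree,
       p.value = stats::pchisq(sd$chisq, dfree, lower.tail = FALSE),
       fit = fit)
}

#' Cox proportional-hazards analysis
#'
#' Univariate mode fits one model per covariate; multivariate mode fits
#' all covariates jointly. Ties are handled by the Efron approximation
#' and confidence intervals are Wald-based. Covariates with zero variance
#' are rejected; a monotone partial likelihood (perfect separation,
#' detected by a diverging coefficient or an outsized standard error) is
#' flagged and its estimates withheld.
#'
#' @param data data.frame holding times, events and covariates.
#' @param covariates character vector of covariate column names.
#' @param time,event column names of the time and 0/1 event indicator
#'   (defaults `"df_months"`, `"recurrence_event"`).
#' @param mode `"univariate"` or `"multivariate"`.
#' @return data.frame of class `CoxResult`: `covariate`, `term`, `hr`,
#'   `ciLow`, `ciHigh`, `p.value`, `flagged`, `model`.
#' @export
coxPH <- function(data, covariates, time = "df_months",
                  event = "recurrence_event",
                  mode = c("univariate", "multivariate")) {
  mode <- match.arg(mode)
  stopifnot(all(c(time, event, covariates) %in% names(data)))
  if (sum(data[[event]]) < 2) stop("need at least 2 events")
  for (cv in covariates) {
    v <- data[[cv]]
    if (length(unique(v[!is.na(v)])) < 2)
      stop("zero-variance covariate: ", cv)
  }
  fitOne <- function(cvs) {
    fml <- stats::as.formula(paste0(
      "survival::Surv(", time, ", ", event, ") ~ ",
      paste(sprintf("`%s`", cvs), collapse = " + ")))
    fit <- survival::coxph(fml, data = data, ties = "efron")
    s <- summary(fit)
    co <- s$coefficients
    terms <- rownames(co)
    flagged <- abs(co[, "coef"]) > 15 | co[, "se(coef)"] > 100
    out <- data.frame(
      covariate = rep(cvs, vapply(cvs, function(cv)
        sum(startsWith(terms, cv) | startsWith(terms, paste0("`", cv, "`"))),
        0L)),
      term = terms,
      hr = ifelse(flagged, NA_real_, exp(co[, "coef"])),
      ciLow = ifelse(flagged, NA_real_, s$conf.int[, "lower .95"]),
      ciHigh = ifelse(flagged, NA_real_, s$conf.int[, "upper .95"]),
      p.value = ifelse(flagged, NA_real_, co[, "Pr(>|z|)"]),
      flagged = flagged, row.names = NULL)
    out
  }
  res <- if (mode == "univariate")
    do.call(rbind, lapply(covariates, fitOne))
  else
    fitOne(covariates)
  res$model <- mode
  if (any(res$flagged))
    warning("monotone likelihood suspected for: ",
            paste(unique(res$covariate[res$flagged]), collapse = ", "))
  class(res) <- c("CoxResult", "data.frame")
  res
}

#' Pearson product-moment correlation with t-based p-value
#'
#' @param x,y numeric vectors of equal length (n >= 3), neither constant.
#' @return list with `r` and `p.value`.
#' @export
pearsonCorr <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance input")
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p.value = ht$p.value)
}

#' Per-stratum event summary
#'
#' Counts patients and events in each level of a stratifying variable and
#' reports the event percentage to one decimal, the layout of a standard
#' univariate outcome table. Empty strata are reported with a count of 0
#' and an omitted (NA) percentage.
#'
#' @param data data.frame of patient records.
#' @param stratifier column name (or a factor/vector of the same length)
#'   defining the strata; must be defined (non-NA) for all records.
#' @param event column name of the 0/1 event indicator.
#' @return data.frame: `stratum`, `patients`, `events`, `percent`.
#' @examples
#' d <- data.frame(g = rep(c("high", "low"), c(22, 42)),
#'                 death = c(rep(1, 16), rep(0, 6), rep(1, 9), rep(0, 33)))
#' stratumSummary(d, "g", "death")  # 72.7% and 21.4%
#' @export
stratumSummary <- function(data, stratifier, event) {
  s <- if (length(stratifier) == 1 && is.character(stratifier))
    data[[stratifier]] else stratifier
  if (anyNA(s)) stop("stratifier must be defined for all records")
  ev <- .asBinary(data[[event]])
  s <- as.factor(s)
  patients <- as.integer(table(s))
  events <- as.integer(tapply(ev, s, sum, default = 0L))
  percent <- ifelse(patients > 0, round(100 * events / patients, 1),
                    NA_real_)
  data.frame(stratum = levels(s), patients = patients, events = events,
             percent = percent)
}
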