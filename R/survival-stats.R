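#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()] and returns the curve as a tidy table plus
#' the median survival under the convention "smallest event time with
#' S(t) <= 0.5" (undefined, `NA`, when the curve never reaches 0.5).
#'
#' @param times follow-up times in days (>= 0).
#' @param events logical (or 0/1) event indicators; `FALSE` = censored.
#' @return A `km_curve` object: tibble with `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`, and attributes `median` (days or `NA`), `n`,
#'   `n_events`.
#' @examples
#' km <- km_estimate(c(1, 2, 3, 4), c(TRUE, TRUE, TRUE, TRUE))
#' km_median(km) # 2
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events), length(times) >= 1,
            all(times >= 0))
  events <- as.logical(events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  tab <- tibble::tibble(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, survival = fit$surv
  )
  med <- km_median_from_curve(tab)
  structure(tab, class = c("km_curve", class(tab)),
            median = med, n = length(times), n_events = sum(events))
}

km_median_from_curve <- function(tab) {
  hit <- tab$time[tab$n_event > 0 & tab$survival <= 0.5 + 1e-12]
  if (length(hit) == 0) NA_real_ else min(hit)
}

#' @rdname km_estimate
#' @param km a `km_curve` object.
#' @export
km_median <- function(km) attr(km, "median")

#' @export
print.km_curve <- function(x, ...) {
  med <- attr(x, "median")
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, median = %s\n",
              attr(x, "n"), attr(x, "n_events"),
              if (is.na(med)) "not reached" else format(med)))
  NextMethod()
}

#' Log-rank test
#'
#' Wraps [survival::survdiff()]; the chi-square statistic compares observed
#' with expected event counts under the hypergeometric variance, with
#' `groups - 1` degrees of freedom. The per-event-time audit table of
#' observed/expected/variance contributions (two-group case) is available
#' from [logrank_table()].
#'
#' @param times,events as in [km_estimate()].
#' @param group group membership (factor-like, >= 2 non-empty groups).
#' @return A list of class `logrank_test` with `chi_square`, `df`,
#'   `p_value`, `n`, `obs`, `exp`.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(as.vector(group))
  if (nlevels(droplevels(group)) < 2) {
    abort("Log-rank test needs >= 2 non-empty groups.")
  }
  group <- droplevels(group)
  events <- as.logical(events)
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  df <- length(sd$n) - 1
  structure(
    list(chi_square = unname(sd$chisq), df = df,
         p_value = unname(pchisq(sd$chisq, df, lower.tail = FALSE)),
         n = as.vector(sd$n), obs = as.vector(sd$obs),
         exp = as.vector(sd$exp)),
    class = "logrank_test"
  )
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4f on %d df, p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  invisible(x)
}

#' Per-event-time observed/expected/variance table (two groups)
#'
#' The exact intermediate quantities of the two-group log-rank statistic:
#' at each distinct event time, the number at risk per group, observed
#' events in group 1, its hypergeometric expectation and variance. Summing
#' `(sum(o1 - e1))^2 / sum(v)` reproduces the log-rank chi-square.
#'
#' @inheritParams logrank_test
#' @return A tibble with `time`, `n_risk`, `n_risk_1`, `n_event`,
#'   `obs_1`, `exp_1`, `var_1`.
#' @export
logrank_table <- function(times, events, group) {
  group <- as.factor(as.vector(group))
  stopifnot(nlevels(droplevels(group)) == 2)
  group <- droplevels(group)
  events <- as.logical(events)
  ts <- sort(unique(times[events]))
  rows <- purrr::map(ts, function(t) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == levels(group)[1])
    d <- sum(events & times == t)
    d1 <- sum(events & times == t & group == levels(group)[1])
    e1 <- d * n1 / n
    v1 <- if (n > 1) d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1) else 0
    tibble::tibble(time = t, n_risk = n, n_risk_1 = n1, n_event = d,
                   obs_1 = d1, exp_1 = e1, var_1 = v1)
  })
  dplyr::bind_rows(rows)
}

#' Cox proportional-hazards fit
#'
#' Wraps [survival::coxph()] with Efron handling of tied event times and
#' Wald inference. Supports univariate and multivariate models (e.g. bulky
#' disease adjusted for TMTV, or bulky disease with extra stage).
#'
#' @param data data frame holding outcomes and covariates.
#' @param time,event column names (strings) of the follow-up time and event
#'   indicator.
#' @param covariates character vector of covariate column names.
#' @return A `cox_fit` object; use [tidy()] for per-covariate estimates
#'   (log HR, HR, SE, Wald p, 95% CI) and [glance()] for model-level
#'   summaries.
#' @examples
#' coh <- make_cohort(cohort_spec(n_patients = 60, seed = 3))
#' fit <- cox_fit(coh$patients, "pfs_days", "pfs_event", "bulky")
#' tidy(fit)
#' @export
cox_fit <- function(data, time, event, covariates) {
  stopifnot(is.data.frame(data), length(covariates) >= 1)
  ev <- as.logical(data[[event]])
  if (sum(ev) < 2) abort("Cox fit needs >= 2 events.")
  for (cv in covariates) {
    v <- data[[cv]]
    if (is.null(v)) abort(sprintf("Covariate '%s' not found.", cv))
    if (length(unique(v[!is.na(v)])) < 2) {
      abort(sprintf("Covariate '%s' is constant.", cv))
    }
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(", time, ",", event, ") ~",
    paste(covariates, collapse = " + ")
  ))
  fit <- survival::coxph(fml, data = data, ties = "efron")
  if (any(!is.finite(sqrt(diag(fit$var)))) ||
      any(abs(stats::coef(fit)) > 15)) {
    abort("Monotone partial likelihood (complete separation): coefficients diverge.")
  }
  structure(list(fit = fit, covariates = covariates,
                 time = time, event = event),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  print(tidy(x))
  invisible(x)
}

#' @rdname cox_fit
#' @param x a `cox_fit` object.
#' @param ... unused.
#' @export
tidy.cox_fit <- function(x, ...) {
  fit <- x$fit
  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  z <- beta / se
  tibble::tibble(
    term = names(beta),
    estimate = unname(beta),
    hazard_ratio = exp(unname(beta)),
    std_error = unname(se),
    statistic = unname(z),
    p_value = unname(2 * pnorm(-abs(z))),
    conf_low = exp(unname(beta - qnorm(0.975) * se)),
    conf_high = exp(unname(beta + qnorm(0.975) * se))
  )
}

#' @rdname cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  fit <- x$fit
  tibble::tibble(
    n = fit$n, n_events = fit$nevent,
    log_likelihood = fit$loglik[2],
    concordance = unname(fit$concordance["concordance"])
  )
}

#' Spearman rank correlation
#'
#' Mid-rank transform of both vectors followed by the product-moment
#' correlation of the ranks; the two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return A tibble with `rho`, `statistic`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("Spearman correlation needs >= 3 paired observations.")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    abort("Spearman correlation undefined for a constant vector.")
  }
  rho <- stats::cor(x, y, method = "spearman")
  if (abs(rho) >= 1) {
    p <- 0
    tstat <- Inf * sign(rho)
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  tibble::tibble(rho = rho, statistic = tstat, p_value = p, n = n)
}

#' ROC curve and Youden-index cutoff
#'
#' Builds the ROC curve with the call convention "positive when
#' score > cutoff"; candidate cutoffs are the midpoints between consecutive
#' distinct score values, so a perfectly separating cutoff falls strictly
#' between the classes. The AUC is computed by the trapezoidal rule and the
#' selected cutoff maximizes the Youden index
#' `sensitivity + specificity - 1` (ties broken toward the smallest cutoff,
#' so the output is deterministic). The p-value tests AUC = 0.5 via the
#' normal approximation to the Mann-Whitney statistic.
#'
#' @param score numeric predictor (higher = more likely positive).
#' @param label logical (or 0/1) class labels; both classes must be present.
#' @return A `roc_result`: list with `curve` (tibble of cutoff,
#'   sensitivity, specificity), `auc`, `p_value`, `youden_cutoff`,
#'   `youden_index`, `n_pos`, `n_neg`.
#' @examples
#' r <- roc_youden(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
#' r$auc # 1: perfectly separated
#' @export
roc_youden <- function(score, label) {
  label <- as.logical(label)
  ok <- stats::complete.cases(score, label)
  score <- score[ok]; label <- label[ok]
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0 || n0 == 0) abort("Both classes must be present.")
  u <- sort(unique(score))
  cuts <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
  sens <- vapply(cuts, function(ct) mean(score[label] > ct), 0)
  spec <- vapply(cuts, function(ct) mean(score[!label] <= ct), 0)
  curve <- tibble::tibble(cutoff = cuts, sensitivity = sens, specificity = spec)
  # trapezoid over (FPR, TPR), endpoints (0,0) and (1,1)
  fpr <- c(1, 1 - spec, 0)
  tpr <- c(1, sens, 0)
  auc <- sum((head(fpr, -1) - fpr[-1]) * (head(tpr, -1) + tpr[-1]) / 2)
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)[1]  # smallest cutoff among ties
  # Mann-Whitney normal approximation for AUC = 0.5
  mw <- stats::wilcox.test(score[label], score[!label], exact = FALSE,
                           correct = FALSE)
  structure(
    list(curve = curve, auc = auc, p_value = unname(mw$p.value),
         youden_cutoff = cuts[best], youden_index = j[best],
         n_pos = n1, n_neg = n0),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC = %.3f (p = %.4g), Youden cutoff = %.4g (J = %.3f), n+ = %d, n- = %d\n",
    x$auc, x$p_value, x$youden_cutoff, x$youden_index, x$n_pos, x$n_neg
  ))
  invisible(x)
}

#' @rdname roc_youden
#' @param x a `roc_result`.
#' @param ... unused.
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @rdname roc_youden
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, p_value = x$p_value, youden_cutoff = x$youden_cutoff,
    youden_index = x$youden_index, n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' Stratified survival by aggregation-dissemination group
#'
#' Kaplan-Meier curves per synergy stratum (`neither` / `either` / `both`)
#' and the two pairwise log-rank comparisons of interest: `both` vs
#' `either`, and `neither` vs `either`. Comparisons involving an empty
#' stratum are skipped with a warning.
#'
#' @param data patient table with a `synergy_group` column (see
#'   [synergy_group()]).
#' @param time,event column names of the outcome, default PFS.
#' @return A `synergy_result`: list with `curves` (tibble: stratum, time,
#'   n_risk, n_event, survival), `medians` (tibble: stratum, n, n_events,
#'   median), `comparisons` (tibble: comparison, chi_square, p_value).
#' @export
synergy_analysis <- function(data, time = "pfs_days", event = "pfs_event") {
  stopifnot("synergy_group" %in% names(data))
  strata <- levels(data$synergy_group)
  present <- strata[strata %in% as.character(data$synergy_group)]
  if (length(present) <= 1) {
    warn("All patients fall in a single synergy stratum; no comparisons possible.")
  }
  curves <- purrr::map(present, function(s) {
    sel <- data$synergy_group == s
    km <- km_estimate(data[[time]][sel], data[[event]][sel])
    dplyr::mutate(tibble::as_tibble(km), stratum = s, .before = 1)
  }) |> dplyr::bind_rows()
  medians <- purrr::map(present, function(s) {
    sel <- data$synergy_group == s
    km <- km_estimate(data[[time]][sel], data[[event]][sel])
    tibble::tibble(stratum = s, n = sum(sel),
                   n_events = sum(as.logical(data[[event]][sel])),
                   median = km_median(km))
  }) |> dplyr::bind_rows()
  pairs <- list(c("both", "either"), c("neither", "either"))
  comparisons <- purrr::map(pairs, function(p) {
    if (!all(p %in% present)) {
      warn(sprintf("Stratum missing for comparison %s vs %s; skipped.",
                   p[1], p[2]))
      return(NULL)
    }
    sel <- data$synergy_group %in% p
    lr <- logrank_test(data[[time]][sel], data[[event]][sel],
                       droplevels(data$synergy_group[sel]))
    tibble::tibble(comparison = paste(p[1], "vs", p[2]),
                   chi_square = lr$chi_square, p_value = lr$p_value)
  }) |> dplyr::bind_rows()
  structure(list(curves = curves, medians = medians, comparisons = comparisons),
            class = "synergy_result")
}

#' @export
print.synergy_result <- function(x, ...) {
  cat("Survival by aggregation-dissemination stratum\n")
  print(x$medians)
  print(x$comparisons)
  invisible(x)
}
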