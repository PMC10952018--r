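test_that("Kaplan-Meier matches the product-limit closed form and median convention", {
  km <- km_estimate(c(1, 2, 3, 4), c(TRUE, TRUE, TRUE, TRUE))
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))
  expect_equal(km_median(km), 2)  # first time with S(t) <= 0.5

  allc <- km_estimate(c(3, 8, 12), c(FALSE, FALSE, FALSE))
  expect_true(all(allc$survival == 1))
  expect_true(is.na(km_median(allc)))
})

test_that("Kaplan-Meier reproduces a hand-computed mixed-censoring table", {
  times <- c(1, 2, 3, 4, 4, 5, 6, 7)
  events <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  km <- km_estimate(times, events)
  ev <- km[km$n_event > 0, ]
  expect_equal(ev$time, c(1, 3, 4, 5, 7))
  expect_equal(ev$n_risk, c(8, 6, 5, 3, 1))
  expect_equal(ev$survival,
               c(7 / 8, 7 / 8 * 5 / 6, 7 / 8 * 5 / 6 * 4 / 5,
                 7 / 8 * 5 / 6 * 4 / 5 * 2 / 3, 0))
  expect_equal(km_median(km), 5)
})

test_that("without censoring the KM curve equals the empirical survival function", {
  withr::with_seed(5, {
    t <- round(rexp(40, 0.01)) + 1
    km <- km_estimate(t, rep(TRUE, 40))
    at_events <- vapply(km$time, function(u) mean(t > u), 0)
    expect_equal(km$survival, at_events)
  })
})

test_that("log-rank is zero for identical groups and invariant to label swap", {
  t <- c(3, 6, 8, 12, 3, 6, 8, 12)
  e <- rep(TRUE, 8)
  g <- rep(c("a", "b"), each = 4)
  lr <- logrank_test(t, e, g)
  expect_equal(lr$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)

  withr::with_seed(6, {
    t2 <- rexp(30); e2 <- runif(30) < 0.7; g2 <- rep(c("x", "y"), 15)
    a <- logrank_test(t2, e2, g2)
    b <- logrank_test(t2, e2, ifelse(g2 == "x", "y", "x"))
    expect_equal(a$chi_square, b$chi_square)
  })
  expect_error(logrank_test(t, e, rep("a", 8)), "2 non-empty groups")
})

test_that("log-rank chi-square matches the hand-computed O/E/V hypergeometric sum", {
  # n = 10, two groups, some censoring and a tie
  times <- c(2, 4, 4, 7, 9, 3, 5, 8, 10, 12)
  events <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
  group <- rep(c("A", "B"), each = 5)

  # explicit arithmetic, independent of the implementation
  o1 <- e1 <- v1 <- 0
  for (tt in sort(unique(times[events]))) {
    at <- times >= tt
    n <- sum(at); n1 <- sum(at & group == "A")
    d <- sum(events & times == tt)
    d1 <- sum(events & times == tt & group == "A")
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    v1 <- v1 + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi_hand <- (o1 - e1)^2 / v1

  lr <- logrank_test(times, events, group)
  expect_equal(lr$chi_square, chi_hand, tolerance = 1e-10)

  tab <- logrank_table(times, events, group)
  expect_equal(sum(tab$obs_1), o1)
  expect_equal(sum(tab$exp_1), e1)
  expect_equal(sum(tab$var_1), v1)
})

test_that("Cox coefficient matches grid maximization of the explicit partial likelihood", {
  d <- tibble::tibble(
    time = c(2, 5, 1, 7, 9, 4),
    event = rep(TRUE, 6),
    x = c(0.2, 1.1, -0.4, 1.8, 0.9, -1.2)
  )
  fit <- cox_fit(d, "time", "event", "x")
  beta_hat <- tidy(fit)$estimate
  beta_grid <- cox_grid_mle(d$time, d$event, d$x)
  expect_equal(beta_hat, beta_grid, tolerance = 1e-4)
})

test_that("Cox fit validates inputs and flags separation", {
  d <- tibble::tibble(time = 1:6, event = rep(TRUE, 6), x = rep(1, 6),
                      y = c(1, 1, 1, 0, 0, 0))
  expect_error(cox_fit(d, "time", "event", "x"), "constant")
  # perfect separation: covariate orders exactly with event times
  suppressWarnings(expect_error(cox_fit(d, "time", "event", "y"), "separation"))
})

test_that("a null covariate yields a near-zero coefficient at large n", {
  withr::with_seed(11, {
    n <- 600
    d <- tibble::tibble(
      time = rexp(n), event = rep(TRUE, n), x = rbinom(n, 1, 0.4)
    )
    fit <- cox_fit(d, "time", "event", "x")
    expect_lt(abs(tidy(fit)$estimate), 0.2)
  })
})

test_that("Cox coefficient converges to the log rate ratio for exponential groups", {
  bias <- vapply(1:5, function(s) {
    withr::with_seed(100 + s, {
      n <- 2000
      x <- rep(0:1, each = n / 2)
      t <- rexp(n, rate = ifelse(x == 1, 3, 1))
      d <- tibble::tibble(time = t, event = rep(TRUE, n), x = x)
      tidy(cox_fit(d, "time", "event", "x"))$estimate - log(3)
    })
  }, 0)
  expect_lt(abs(mean(bias)), 0.05)
})

test_that("Spearman correlation: monotone invariance, reversal, and the rank-Pearson oracle", {
  x <- c(2, 9, 4, 1, 7, 5, 8)
  expect_equal(spearman_cor(x, exp(x))$rho, 1)
  expect_equal(spearman_cor(x, -x^3)$rho, -1)

  withr::with_seed(13, {
    a <- rnorm(30)
    b <- 0.5 * a + rnorm(30)
    got <- spearman_cor(a, b)
    expect_equal(got$rho, stats::cor(rank(a), rank(b)))
    ct <- stats::cor.test(a, b, method = "spearman", exact = FALSE)
    expect_equal(got$rho, unname(ct$estimate))
    expect_equal(got$p_value, ct$p.value, tolerance = 1e-6)
  })
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  expect_error(spearman_cor(1:2, 2:1), ">= 3")
})

test_that("ROC handles perfect separation and symmetric null data", {
  r <- roc_youden(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$youden_index, 1)
  expect_gt(r$youden_cutoff, 3)   # strictly between the classes
  expect_lt(r$youden_cutoff, 10)

  null <- roc_youden(c(1, 2, 3, 4), c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(null$auc, 0.5)

  expect_error(roc_youden(1:5, rep(TRUE, 5)), "Both classes")
})

test_that("Youden cutoff equals exhaustive search; AUC equals the Mann-Whitney statistic", {
  skip_if_not_installed("pROC")
  for (seed in 1:10) {
    withr::with_seed(seed, {
      n <- 40
      score <- round(rnorm(n, sd = 2), 2)
      label <- runif(n) < stats::plogis(score)
    })
    if (sum(label) == 0 || sum(label) == n) next
    r <- roc_youden(score, label)

    # exhaustive oracle over every midpoint candidate, naive counting
    u <- sort(unique(score))
    cands <- (u[-1] + u[-length(u)]) / 2
    best_j <- -Inf; best_c <- NA
    for (ct in cands) {
      tp <- sum(score > ct & label); fn <- sum(score <= ct & label)
      tn <- sum(score <= ct & !label); fp <- sum(score > ct & !label)
      j <- tp / (tp + fn) + tn / (tn + fp) - 1
      if (j > best_j + 1e-12) { best_j <- j; best_c <- ct }
    }
    expect_equal(r$youden_cutoff, best_c)
    expect_equal(r$youden_index, best_j)

    # AUC = U / (n1 * n0), and agrees with pROC
    n1 <- sum(label); n0 <- sum(!label)
    u_stat <- sum(vapply(score[label], function(s) {
      sum(s > score[!label]) + 0.5 * sum(s == score[!label])
    }, 0))
    expect_equal(r$auc, u_stat / (n1 * n0))
    expect_equal(
      r$auc,
      as.numeric(suppressMessages(pROC::auc(pROC::roc(label, score, quiet = TRUE))))
    )
  }
})

test_that("synergy analysis orders medians under additive log-hazards and warns on a single stratum", {
  coh <- make_cohort(cohort_spec(
    n_patients = 400, p_bulky = 0.45, p_extra = 0.45,
    log_hr_bulky = log(2.5), log_hr_extra = log(2.5), seed = 17
  ), lesions = FALSE)
  pats <- dplyr::mutate(coh$patients,
                        synergy_group = synergy_group(bulky, extra_stage))
  res <- synergy_analysis(pats)
  med <- setNames(res$medians$median, res$medians$stratum)
  expect_lt(med["both"], med["either"])
  expect_lt(med["either"], med["neither"])
  expect_equal(nrow(res$comparisons), 2)

  one <- pats[pats$synergy_group == "neither", ]
  w <- capture_warnings(synergy_analysis(one))
  expect_true(any(grepl("single synergy stratum", w)))
  expect_true(any(grepl("skipped", w)))
})
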