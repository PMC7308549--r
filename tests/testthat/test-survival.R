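test_that("Kaplan-Meier estimates match the product-limit hand calculation", {
  km <- km_estimate(make_records(time = c(1, 2, 3), event = c(1, 0, 1)))
  expect_equal(km$surv[km$time == 1], 2 / 3)
  expect_equal(km$surv[km$time == 3], 0)

  # no censoring: reduces to the empirical survival function
  set.seed(8)
  t <- sample(1:50, 30, replace = TRUE)
  km2 <- km_estimate(make_records(time = t, event = rep(1, 30)))
  emp <- sapply(km2$time, function(u) mean(t > u))
  expect_equal(km2$surv, emp)
  expect_true(all(diff(km2$surv) <= 0))

  # all censored: survival stays at 1
  km3 <- km_estimate(make_records(time = c(5, 10, 15), event = c(0, 0, 0)))
  expect_true(all(km3$surv == 1))

  expect_error(km_estimate(make_records(time = c(1, 0), event = c(1, 1))), "> 0")
})

test_that("log-rank test is zero for identical groups and matches the textbook formula", {
  rec <- make_records(time = c(3, 5, 7, 9, 11), event = c(1, 0, 1, 1, 0))
  dup <- rbind(rec, rec)
  lr <- logrank_test(dup, rep(c("a", "b"), each = 5))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_error(logrank_test(rec, rep("a", 5)), "two")

  set.seed(15)
  for (k in 1:10) {
    n <- 40
    rec <- make_records(time = rexp(n, 0.1) + 0.01,
                        event = rbinom(n, 1, 0.7))
    grp <- rbinom(n, 1, 0.5) == 1
    if (length(unique(grp)) < 2) next
    lr <- logrank_test(rec, grp)
    o <- oracle_logrank2(rec$time, rec$event, grp)
    expect_equal(lr$statistic, unname(o["chi"]), tolerance = 1e-10)
    expect_equal(lr$p, unname(o["p"]), tolerance = 1e-10)
  }
})

test_that("Cox fits recover planted effects and respect partial-likelihood structure", {
  # planted two-group hazard ratio 2, moderate censoring: mean estimate
  # over replicates close to ln 2
  set.seed(22)
  est <- replicate(20, {
    n <- 1000
    x <- rbinom(n, 1, 0.5)
    t <- rexp(n, 0.01 * exp(log(2) * x))
    rec <- make_records(time = pmin(t, 100), event = as.integer(t <= 100), x = x)
    cox_fit(rec, "x")$coefficients$beta
  })
  expect_lt(abs(mean(est) - log(2)), 0.05)

  # a covariate independent of the hazard: estimates center on zero
  set.seed(23)
  est0 <- replicate(20, {
    n <- 1000
    z <- rnorm(n)
    t <- rexp(n, 0.01)
    rec <- make_records(time = pmin(t, 100), event = as.integer(t <= 100), z = z)
    cox_fit(rec, "z")$coefficients$beta
  })
  expect_lt(abs(mean(est0)), 0.05)

  # duplicating every record: estimate approximately unchanged (the copies
  # introduce ties, so Efron weighting perturbs it slightly), LR doubles
  set.seed(24)
  n <- 120
  x <- rnorm(n)
  t <- rexp(n, 0.05 * exp(0.5 * x))
  rec <- make_records(time = pmin(t, 40), event = as.integer(t <= 40), x = x)
  f1 <- cox_fit(rec, "x")
  f2 <- cox_fit(rbind(rec, rec), "x")
  expect_equal(f2$coefficients$beta, f1$coefficients$beta, tolerance = 0.02)
  expect_equal(f2$lr, 2 * f1$lr, tolerance = 0.05)

  # hazard ratio / CI consistency
  expect_equal(f1$coefficients$hr, exp(f1$coefficients$beta))
  expect_true(f1$coefficients$lower < f1$coefficients$hr &&
                f1$coefficients$hr < f1$coefficients$upper)
  expect_gte(f1$lr, 0)
})

test_that("degenerate Cox inputs raise diagnostic errors", {
  rec <- make_records(time = 1:10, event = rep(0, 10), x = rnorm(10))
  expect_error(cox_fit(rec, "x"), "event")
  rec2 <- make_records(time = 1:10, event = rep(1, 10), x = rep(3, 10))
  expect_error(cox_fit(rec2, "x"), "constant.*x")
  # perfect separation: the early deaths are exactly the x = 1 group
  rec3 <- make_records(time = c(1:5, 101:105),
                       event = c(rep(1, 5), rep(0, 5)),
                       x = c(rep(1, 5), rep(0, 5)))
  expect_error(cox_fit(rec3, "x"), "x")
})

test_that("optimal cutoff equals the exhaustive scan and flags degenerate input", {
  # constructed separating gap: deaths at indicator < 5, survivors above
  rec <- make_records(time = c(2, 3, 4, 90, 95, 100, 105, 110, 120, 130),
                      event = c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0))
  vals <- c(1, 2, 4, 6, 7, 8, 9, 10, 11, 12)
  cut <- optimal_cutoff(rec, vals)
  expect_gt(cut$cutoff, 4)
  expect_lt(cut$cutoff, 6)
  expect_true(cut$selection_biased)

  set.seed(33)
  for (k in 1:10) {
    n <- 50
    v <- round(rnorm(n, 10, 3), 1)
    t <- rexp(n, 0.02 * exp(0.15 * (v - 10)))
    r <- make_records(time = pmin(t, 80), event = as.integer(t <= 80))
    res <- optimal_cutoff(r, v)
    oracle <- oracle_cutoff_scan(r$time, r$event, v)
    expect_equal(res$cutoff, oracle$cutoff)
    expect_equal(res$p, oracle$p, tolerance = 1e-9)
  }

  const <- optimal_cutoff(rec, rep(1, 10))
  expect_true(is.na(const$cutoff))
  expect_match(const$reason, "constant")
})

test_that("correlation pruning follows the greedy priority rule", {
  # exact sample correlations via an orthonormal basis of centered noise
  set.seed(44)
  n <- 100
  Z0 <- scale(matrix(rnorm(n * 3), n), center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(Z0))
  R <- matrix(c(1, 0.95, 0.85,
                0.95, 1, 0.95,
                0.85, 0.95, 1), 3, 3)
  X <- as.data.frame(Q %*% chol(R))
  names(X) <- c("A", "B", "C")
  expect_equal(cor(X$A, X$B), 0.95, tolerance = 1e-10)
  expect_equal(cor(X$A, X$C), 0.85, tolerance = 1e-10)
  expect_equal(prune_correlated(X, threshold = 0.90, priority = c("A", "B", "C")),
               c("A", "C"))

  # duplicated column: exactly one survives
  dup <- data.frame(a = rnorm(50))
  dup$b <- dup$a
  expect_equal(prune_correlated(dup), "a")

  # independent noise columns both survive
  set.seed(45)
  noise <- data.frame(u = rnorm(100), v = rnorm(100))
  expect_equal(prune_correlated(noise), c("u", "v"))
})

test_that("leave-one-out subset selection finds planted covariates", {
  set.seed(55)
  n <- 60
  x <- rnorm(n)
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  t <- rexp(n, 0.02 * exp(1 * x))
  rec <- make_records(time = pmin(t, 100), event = as.integer(t <= 100),
                      x = x, z1 = z1, z2 = z2)
  tab <- loo_subset_frequency(rec, c("x", "z1", "z2"))
  expect_equal(sum(tab$folds), n)
  expect_match(tab$subset[1], "x")
  expect_gt(sum(tab$folds[grepl("x", tab$subset)]) / n, 0.5)

  # all-noise candidates: the empty subset is modal
  set.seed(56)
  t0 <- rexp(n, 0.02)
  rec0 <- make_records(time = pmin(t0, 100), event = as.integer(t0 <= 100),
                       z1 = rnorm(n), z2 = rnorm(n))
  tab0 <- loo_subset_frequency(rec0, c("z1", "z2"))
  expect_equal(tab0$subset[1], "(none)")

  expect_error(loo_subset_frequency(rec[1:5, ], "x"), "10")
})

test_that("PR stratification cuts at 20 and 80 percent", {
  expect_equal(as.character(stratify_pr_groups(c(19.9, 20, 50, 80, 80.1))),
               c("low", "moderate", "moderate", "moderate", "high"))
  expect_equal(levels(stratify_pr_groups(50)), c("low", "moderate", "high"))
  expect_error(stratify_pr_groups(101), "\\[0, 100\\]")
})
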