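# Survival layer: Kaplan-Meier estimation, log-rank testing, Cox
# proportional-hazards models (Efron ties), significance-based optimal
# cutpoint scanning, correlation pruning, and leave-one-out
# subset-frequency selection. Model fitting is delegated to the
# 'survival' package; the selection procedures around it live here.

check_records <- function(records) {
  records <- as.data.frame(records)
  for (col in c("time", "event")) {
    if (!col %in% names(records)) stop("survival records need a '", col, "' column")
  }
  if (any(!is.finite(records$time)) || any(records$time <= 0)) {
    stop("follow-up times must be finite and > 0")
  }
  ev <- records$event
  if (is.logical(ev)) ev <- as.integer(ev)
  if (!all(ev %in% c(0L, 1L))) stop("'event' must be 0/1 or logical")
  records$event <- ev
  records
}

#' Kaplan-Meier estimate of the survival function
#'
#' Product-limit estimator; censored times reduce the risk set without
#' producing steps.
#'
#' @param records Data frame with `time` (months, > 0) and `event`
#'   (1 = death observed, 0 = censored).
#' @return Data frame of class `km_estimate` with columns `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv` (non-increasing, S(0) = 1
#'   implicitly).
#' @export
km_estimate <- function(records) {
  records <- check_records(records)
  if (nrow(records) < 1L) stop("need at least one record")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                    n_censor = fit$n.censor, surv = fit$surv)
  class(out) <- c("km_estimate", "data.frame")
  out
}

#' Log-rank test between survival groups
#'
#' @param records Data frame with `time` and `event`.
#' @param group Group assignment (factor/character/numeric), at least two
#'   non-empty groups.
#' @return List with `statistic` (chi-square), `df` and `p`.
#' @export
logrank_test <- function(records, group) {
  records <- check_records(records)
  if (length(group) != nrow(records)) stop("'group' must match the records")
  g <- factor(group)
  if (nlevels(droplevels(g)) < 2L) stop("log-rank test needs at least two non-empty groups")
  records$.group <- g
  sd <- survival::survdiff(survival::Surv(time, event) ~ .group, data = records)
  df <- length(sd$n) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Multivariable Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with the Efron tie approximation.
#' Reports per-covariate log-hazard coefficients, hazard ratios with 95%
#' confidence intervals and Wald p-values, plus the model likelihood-ratio
#' statistic against the null model.
#'
#' @param records Data frame with `time`, `event` and covariate columns.
#' @param covariates Character vector of covariate column names.
#' @return List of class `cox_model`: `coefficients` (data frame with
#'   `term`, `beta`, `hr`, `lower`, `upper`, `p`), `lr`, `lr_df`, `lr_p`,
#'   `loglik`, `n`, `n_events`.
#' @export
cox_fit <- function(records, covariates) {
  records <- check_records(records)
  stopifnot(length(covariates) >= 1L)
  miss <- setdiff(covariates, names(records))
  if (length(miss)) stop("missing covariate column(s): ", paste(miss, collapse = ", "))
  if (sum(records$event) < 1L) stop("no events in the data; Cox model undefined")
  const <- covariates[vapply(covariates, function(v) {
    x <- records[[v]]
    length(unique(x[!is.na(x)])) < 2L
  }, logical(1L))]
  if (length(const)) {
    stop("constant covariate(s): ", paste(const, collapse = ", "))
  }
  f <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")
  ))
  warns <- character()
  fit <- withCallingHandlers(
    survival::coxph(f, data = records, ties = "efron"),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  bad <- names(beta)[!is.finite(beta) | !is.finite(se) | abs(beta) > 15 | se > 100]
  if (length(bad) || any(grepl("infinite|did not converge", warns))) {
    culprit <- if (length(bad)) bad else covariates
    stop("Cox fit did not converge (possible separation) for: ",
         paste(gsub("`", "", culprit), collapse = ", "))
  }
  z <- stats::qnorm(0.975)
  coefs <- data.frame(term = gsub("`", "", names(beta)),
                      beta = unname(beta),
                      hr = exp(unname(beta)),
                      lower = exp(unname(beta) - z * se),
                      upper = exp(unname(beta) + z * se),
                      p = 2 * stats::pnorm(-abs(unname(beta) / se)),
                      stringsAsFactors = FALSE)
  lr <- unname(2 * (fit$loglik[2L] - fit$loglik[1L]))
  structure(list(coefficients = coefs, lr = lr, lr_df = length(beta),
                 lr_p = stats::pchisq(lr, length(beta), lower.tail = FALSE),
                 loglik = fit$loglik, n = fit$n, n_events = fit$nevent),
            class = "cox_model")
}

#' @export
print.cox_model <- function(x, ...) {
  cat(sprintf("<cox_model> n = %d, events = %d, LR = %.2f on %d df (p = %.2g)\n",
              x$n, x$n_events, x$lr, x$lr_df, x$lr_p))
  print(transform(x$coefficients, beta = signif(beta, 4), hr = signif(hr, 4),
                  lower = signif(lower, 4), upper = signif(upper, 4),
                  p = signif(p, 3)))
  invisible(x)
}

#' Optimal survival cutpoint of a continuous indicator
#'
#' Scans candidate cutoffs at the midpoints of consecutive sorted unique
#' indicator values, keeps splits where both groups contain at least
#' `min_group_frac` of the cases, and returns the cutoff minimizing the
#' log-rank p-value (ties broken toward the smallest cutoff). The
#' returned p-value and hazard ratio are selection-biased: the scan
#' optimizes over cutpoints without multiplicity correction.
#'
#' @param records Data frame with `time` and `event`.
#' @param values Numeric indicator, aligned with `records` rows.
#' @param min_group_frac Minimum fraction of cases per group (default 0.1).
#' @return List of class `cutoff_result`: `cutoff`, `p`, `statistic`,
#'   `hr` (high vs. low group), `n_low`, `n_high`,
#'   `selection_biased = TRUE`; `cutoff` is `NA` with a `reason` when no
#'   admissible split exists.
#' @export
optimal_cutoff <- function(records, values, min_group_frac = 0.1) {
  records <- check_records(records)
  if (length(values) != nrow(records)) stop("'values' must match the records")
  ok <- !is.na(values)
  v <- values[ok]
  rec <- records[ok, , drop = FALSE]
  n <- length(v)
  undefined <- function(reason) {
    structure(list(cutoff = NA_real_, p = NA_real_, statistic = NA_real_,
                   hr = NA_real_, n_low = NA_integer_, n_high = NA_integer_,
                   selection_biased = TRUE, reason = reason),
              class = "cutoff_result")
  }
  u <- sort(unique(v))
  if (length(u) < 2L) return(undefined("constant indicator"))
  cand <- (u[-length(u)] + u[-1L]) / 2
  min_size <- ceiling(min_group_frac * n)
  best <- NULL
  for (cut in cand) {
    high <- v > cut
    n_high <- sum(high)
    if (min(n_high, n - n_high) < min_size) next
    sd <- survival::survdiff(survival::Surv(time, event) ~ high, data = rec)
    p <- stats::pchisq(sd$chisq, 1L, lower.tail = FALSE)
    if (is.null(best) || p < best$p) {
      best <- list(cutoff = cut, p = p, statistic = unname(sd$chisq),
                   n_low = n - n_high, n_high = n_high)
    }
  }
  if (is.null(best)) return(undefined("no admissible split"))
  hr <- tryCatch({
    rec$.high <- as.integer(v > best$cutoff)
    exp(unname(stats::coef(survival::coxph(
      survival::Surv(time, event) ~ .high, data = rec, ties = "efron"))))
  }, error = function(e) NA_real_, warning = function(w) NA_real_)
  structure(c(best[c("cutoff", "p", "statistic")], list(hr = hr),
              best[c("n_low", "n_high")],
              list(selection_biased = TRUE, reason = NULL)),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  if (is.na(x$cutoff)) {
    cat("<cutoff_result> undefined:", x$reason, "\n")
  } else {
    cat(sprintf("<cutoff_result> cutoff = %.4g, log-rank p = %.3g (selection-biased), HR(high vs low) = %.3g, n = %d/%d\n",
                x$cutoff, x$p, x$hr, x$n_low, x$n_high))
  }
  invisible(x)
}

#' Greedy elimination of highly correlated indicators
#'
#' Walks the indicators in priority order and drops any whose absolute
#' Pearson correlation with an already-retained indicator exceeds the
#' threshold, to avoid multicollinearity in multivariable models.
#'
#' @param indicators Data frame of numeric indicator columns.
#' @param threshold Correlation threshold (default 0.90, strict
#'   inequality: an indicator is dropped when |r| > threshold).
#' @param priority Column names in decreasing retention priority
#'   (default: column order).
#' @return Character vector of retained indicator names.
#' @export
prune_correlated <- function(indicators, threshold = 0.90,
                             priority = names(indicators)) {
  indicators <- as.data.frame(indicators)
  stopifnot(all(priority %in% names(indicators)), length(priority) >= 2L)
  retained <- character()
  for (nm in priority) {
    x <- indicators[[nm]]
    drop <- FALSE
    for (r in retained) {
      cc <- suppressWarnings(stats::cor(x, indicators[[r]],
                                        use = "pairwise.complete.obs"))
      if (isTRUE(abs(cc) > threshold)) {
        drop <- TRUE
        break
      }
    }
    if (!drop) retained <- c(retained, nm)
  }
  retained
}

# Forward selection on the Cox partial likelihood: at each step add the
# covariate with the smallest likelihood-ratio p-value, if below 'alpha'.
forward_select_cox <- function(records, covariates, alpha = 0.05) {
  current <- character()
  ll_cur <- NULL
  repeat {
    rem <- setdiff(covariates, current)
    if (!length(rem)) break
    best <- NULL
    for (v in rem) {
      fit <- tryCatch({
        f <- stats::as.formula(paste(
          "survival::Surv(time, event) ~",
          paste(sprintf("`%s`", c(current, v)), collapse = " + ")
        ))
        suppressWarnings(survival::coxph(f, data = records, ties = "efron"))
      }, error = function(e) NULL)
      if (is.null(fit)) next
      ll1 <- fit$loglik[2L]
      ll0 <- if (length(current)) ll_cur else fit$loglik[1L]
      lr <- 2 * (ll1 - ll0)
      p <- stats::pchisq(lr, 1L, lower.tail = FALSE)
      if (is.null(best) || p < best$p) best <- list(v = v, p = p, ll = ll1)
    }
    if (is.null(best) || best$p >= alpha) break
    current <- c(current, best$v)
    ll_cur <- best$ll
  }
  current
}

#' Leave-one-out subset-frequency selection
#'
#' For each leave-one-out fold, runs forward selection on the Cox partial
#' likelihood (entry criterion: likelihood-ratio p < `alpha`) over the
#' candidate covariates and tallies which covariate subsets were
#' selected across folds; with a limited cohort, the most frequent
#' subsets are the stable candidates for the final model.
#'
#' @param records Data frame with `time`, `event` and covariate columns
#'   (n >= 10).
#' @param covariates Candidate covariate names.
#' @param alpha Entry p-value threshold (default 0.05).
#' @return Data frame with `subset` (covariate names joined by `+`, or
#'   `"(none)"`), `folds` and `frequency`, sorted by frequency; attribute
#'   `n_failed` counts degenerate folds that were skipped.
#' @export
loo_subset_frequency <- function(records, covariates, alpha = 0.05) {
  records <- check_records(records)
  n <- nrow(records)
  if (n < 10L) stop("leave-one-out selection needs at least 10 records")
  subsets <- character(n)
  failed <- 0L
  for (i in seq_len(n)) {
    sel <- tryCatch(
      forward_select_cox(records[-i, , drop = FALSE], covariates, alpha),
      error = function(e) NULL
    )
    if (is.null(sel)) {
      failed <- failed + 1L
      subsets[i] <- NA_character_
    } else {
      subsets[i] <- if (length(sel)) paste(sort(sel), collapse = "+") else "(none)"
    }
  }
  if (failed > 0L) warning(failed, " degenerate fold(s) skipped")
  tab <- sort(table(subsets[!is.na(subsets)]), decreasing = TRUE)
  out <- data.frame(subset = names(tab), folds = as.integer(tab),
                    frequency = as.integer(tab) / (n - failed),
                    stringsAsFactors = FALSE)
  attr(out, "n_failed") <- failed
  out
}

#' Three-group stratification of PR expression
#'
#' Labels PR positivity percentages as `low` (< 20), `moderate`
#' (20 to 80, inclusive) or `high` (> 80); the moderate range is where
#' high intratumoral heterogeneity of PR is observed.
#'
#' @param pr_percent Numeric vector of percentages in \[0, 100\].
#' @return Factor with levels `low`, `moderate`, `high`.
#' @export
stratify_pr_groups <- function(pr_percent) {
  if (any(!is.finite(pr_percent)) || any(pr_percent < 0 | pr_percent > 100)) {
    stop("PR percentages must lie in [0, 100]")
  }
  factor(ifelse(pr_percent < 20, "low",
                ifelse(pr_percent <= 80, "moderate", "high")),
         levels = c("low", "moderate", "high"))
}
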