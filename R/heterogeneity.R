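# Intratumoral heterogeneity indicators on the hexagon sample:
# decile binning of per-hexagon positivity, a symmetric normalized
# co-occurrence matrix over adjacent hexagon pairs, five Haralick texture
# features, and Ashman's D bimodality from a two-component Gaussian
# mixture fitted by EM.

N_BINS <- 10L

#' Decile bin of a positivity percentage
#'
#' Percentages are ranked linearly into ten intervals: bin 1 is
#' \[0, 10\], bin k is (10(k-1), 10k\] for k = 2..10.
#'
#' @param p Numeric vector of percentages in \[0, 100\].
#' @return Integer bins in 1..10.
#' @export
bin_percent <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 100)) {
    stop("percentages must lie in [0, 100]")
  }
  pmax(1L, as.integer(ceiling(p / 10)))
}

#' Co-occurrence matrix of decile-binned hexagon percentages
#'
#' For every unordered pair of adjacent retained hexagons with bins
#' (a, b), equal mass is added at (a, b) and (b, a); the matrix is then
#' normalized to sum 1, so it is symmetric by construction.
#'
#' @param lattice A filtered `hex_lattice` (see [filter_hexes()]).
#' @return Object of class `cooc_matrix`: list with `P` (10x10 matrix)
#'   and `n_pairs`. When no adjacent retained pair exists, `P` is `NULL`
#'   and `n_pairs` is 0 (indicators downstream are undefined).
#' @export
cooccurrence <- function(lattice) {
  pairs <- neighbor_pairs(lattice)
  if (nrow(pairs) == 0L) {
    return(structure(list(P = NULL, n_pairs = 0L), class = "cooc_matrix"))
  }
  a <- bin_percent(lattice$percent[pairs[, "i"]])
  b <- bin_percent(lattice$percent[pairs[, "j"]])
  P <- matrix(0, N_BINS, N_BINS)
  tab <- table(factor(c(a, b), levels = 1:N_BINS),
               factor(c(b, a), levels = 1:N_BINS))
  P <- unclass(tab) / (2 * nrow(pairs))
  dimnames(P) <- NULL
  structure(list(P = P, n_pairs = nrow(pairs)), class = "cooc_matrix")
}

#' @export
print.cooc_matrix <- function(x, ...) {
  cat("<cooc_matrix>", x$n_pairs, "adjacent pairs\n")
  if (!is.null(x$P)) print(signif(x$P, 3))
  invisible(x)
}

#' Haralick texture features of a normalized co-occurrence matrix
#'
#' Standard grey-level co-occurrence definitions with bin indices i, j:
#' contrast = sum (i-j)^2 P_ij; dissimilarity = sum |i-j| P_ij;
#' entropy = -sum P_ij log P_ij (natural log, 0 log 0 := 0);
#' energy (angular second moment) = sum P_ij^2;
#' homogeneity (inverse difference moment) = sum P_ij / (1 + (i-j)^2).
#'
#' @param P A `cooc_matrix` or a normalized square probability matrix.
#' @return Named numeric vector with elements `contrast`,
#'   `dissimilarity`, `entropy`, `energy`, `homogeneity`.
#' @export
haralick <- function(P) {
  if (inherits(P, "cooc_matrix")) {
    if (is.null(P$P)) {
      return(c(contrast = NA_real_, dissimilarity = NA_real_, entropy = NA_real_,
               energy = NA_real_, homogeneity = NA_real_))
    }
    P <- P$P
  }
  P <- as.matrix(P)
  if (nrow(P) != ncol(P)) stop("'P' must be square")
  if (any(P < 0) || abs(sum(P) - 1) > 1e-8) {
    stop("'P' must be a normalized probability matrix (non-negative, sum 1)")
  }
  n <- nrow(P)
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  d <- i - j
  nz <- P > 0
  c(contrast = sum(d^2 * P),
    dissimilarity = sum(abs(d) * P),
    entropy = -sum(P[nz] * log(P[nz])),
    energy = sum(P^2),
    homogeneity = sum(P / (1 + d^2)))
}

#' Two-component Gaussian mixture by EM
#'
#' Expectation-maximization with multiple restarts (first restart
#' initialized at the 25\% and 75\% sample quantiles, later restarts
#' randomly perturbed), a variance floor, and convergence on the
#' log-likelihood change. The best restart by log-likelihood is kept.
#' Restart perturbations use R's current random number generator.
#'
#' @param x Numeric data vector.
#' @param restarts Number of EM restarts (default 5).
#' @param max_iter Maximum EM iterations per restart (default 500).
#' @param tol Convergence threshold on the log-likelihood change
#'   (default 1e-8).
#' @param var_floor Lower bound on component variances (default 1e-4).
#' @param w_min Lower bound on the mixing weights (default 0.05). Guards
#'   against the spurious likelihood maxima of Gaussian mixtures, where
#'   one component collapses onto a handful of outlying points; a spatial
#'   expression mode supported by less than 5\% of the hexagons is treated
#'   as insufficient sampling, in the same spirit as the minimum-cell
#'   hexagon filter.
#' @return List with `mu`, `sigma`, `w` (two each) and `loglik`.
#' @export
fit_mixture2 <- function(x, restarts = 5L, max_iter = 500L, tol = 1e-8,
                         var_floor = 1e-4, w_min = 0.05) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop("need at least 2 observations")
  sx <- stats::sd(x)
  if (!is.finite(sx) || sx < sqrt(var_floor)) {
    m <- mean(x)
    return(list(mu = c(m, m), sigma = rep(sqrt(var_floor), 2L), w = c(0.5, 0.5),
                loglik = sum(stats::dnorm(x, m, sqrt(var_floor), log = TRUE))))
  }
  best <- NULL
  for (rst in seq_len(restarts)) {
    mu <- as.numeric(stats::quantile(x, c(0.25, 0.75)))
    if (rst > 1L) mu <- mu + stats::rnorm(2L, 0, sx / 4)
    sig2 <- rep(max(sx^2 / 4, var_floor), 2L)
    w <- c(0.5, 0.5)
    ll_old <- -Inf
    ll <- -Inf
    for (it in seq_len(max_iter)) {
      l1 <- log(w[1L]) + stats::dnorm(x, mu[1L], sqrt(sig2[1L]), log = TRUE)
      l2 <- log(w[2L]) + stats::dnorm(x, mu[2L], sqrt(sig2[2L]), log = TRUE)
      m12 <- pmax(l1, l2)
      den <- m12 + log(exp(l1 - m12) + exp(l2 - m12))
      r1 <- exp(l1 - den)
      ll <- sum(den)
      n1 <- sum(r1)
      n2 <- n - n1
      if (n1 < 1e-8 || n2 < 1e-8) break  # component collapsed
      w <- c(n1, n2) / n
      w <- pmax(w, w_min)
      w <- w / sum(w)
      mu <- c(sum(r1 * x) / n1, sum((1 - r1) * x) / n2)
      sig2 <- c(sum(r1 * (x - mu[1L])^2) / n1,
                sum((1 - r1) * (x - mu[2L])^2) / n2)
      sig2 <- pmax(sig2, var_floor)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    if (is.finite(ll) && (is.null(best) || ll > best$loglik)) {
      best <- list(mu = mu, sigma = sqrt(sig2), w = w, loglik = ll)
    }
  }
  if (is.null(best)) stop("EM failed to produce a finite log-likelihood")
  best
}

#' Ashman's D bimodality of per-hexagon percentages
#'
#' Fits a two-component Gaussian mixture to the retained-hexagon
#' positivity percentages and returns
#' D = sqrt(2) |mu1 - mu2| / sqrt(sigma1^2 + sigma2^2). Large D indicates
#' a bimodal (spatially patchy) expression distribution.
#'
#' @param percents Numeric vector of per-hexagon percentages.
#' @param min_n Minimum number of hexagons required (default 10); below
#'   this the indicator is undefined.
#' @param ... Passed to [fit_mixture2()].
#' @return List with `d` (numeric, `NA` when undefined), `fit` (the
#'   mixture fit or `NULL`) and `n` (number of values used).
#' @export
ashman_d <- function(percents, min_n = 10L, ...) {
  percents <- percents[!is.na(percents)]
  n <- length(percents)
  if (n < min_n) {
    return(list(d = NA_real_, fit = NULL, n = n, reason = "too_few_hexagons"))
  }
  fit <- fit_mixture2(percents, ...)
  d <- sqrt(2) * abs(fit$mu[1L] - fit$mu[2L]) / sqrt(sum(fit$sigma^2))
  list(d = d, fit = fit, n = n, reason = NULL)
}

#' End-to-end heterogeneity indicators for one case and marker
#'
#' Runs the full chain: random hexagonal grid over the map bounds, cell
#' assignment, minimum-cell filtering, decile co-occurrence matrix,
#' Haralick features, and Ashman's D on the retained percentage vector.
#' Undefined stages propagate as `NA` with a reason code, never as zeros.
#'
#' @param cellmap A [cell_map()].
#' @param marker Binary marker name.
#' @param compartment Compartment analysed (default `"tumor"`).
#' @param side Hexagon side length in micrometers (default 257).
#' @param min_cells Minimum cells per hexagon (default 50).
#' @param min_hexes Minimum retained hexagons for Ashman's D (default 10).
#' @param seed Integer seed controlling the grid placement and EM
#'   restarts; `NULL` uses the current RNG state (seed recorded as `NA`).
#' @return One-row data frame: `case_id`, `marker`, `percent_global`,
#'   `contrast`, `dissimilarity`, `entropy`, `energy`, `homogeneity`,
#'   `ashman_d`, `n_hexagons`, `n_pairs`, `seed`, `reason`.
#' @export
compute_indicators <- function(cellmap, marker, compartment = "tumor",
                               side = 257, min_cells = 50, min_hexes = 10,
                               seed = NULL) {
  stopifnot(inherits(cellmap, "cell_map"))
  if (!is.null(seed)) set.seed(seed)
  grid <- build_grid(cellmap$bounds, side = side)
  lat <- assign_cells(cellmap, grid, marker, compartment = compartment)
  lat <- filter_hexes(lat, min_cells = min_cells)
  n_hex <- sum(lat$retained)
  har <- c(contrast = NA_real_, dissimilarity = NA_real_, entropy = NA_real_,
           energy = NA_real_, homogeneity = NA_real_)
  ash <- NA_real_
  n_pairs <- 0L
  reason <- NA_character_
  if (n_hex == 0L) {
    reason <- "no_retained_hexagons"
  } else {
    cm <- cooccurrence(lat)
    n_pairs <- cm$n_pairs
    if (n_pairs == 0L) {
      reason <- "no_adjacent_pairs"
    } else {
      har <- haralick(cm)
    }
    a <- ashman_d(lat$percent[lat$retained], min_n = min_hexes)
    ash <- a$d
    if (is.na(ash) && is.na(reason)) reason <- a$reason
  }
  data.frame(case_id = cellmap$case_id, marker = marker,
             percent_global = global_percent(cellmap, marker, compartment),
             contrast = unname(har["contrast"]),
             dissimilarity = unname(har["dissimilarity"]),
             entropy = unname(har["entropy"]),
             energy = unname(har["energy"]),
             homogeneity = unname(har["homogeneity"]),
             ashman_d = ash,
             n_hexagons = n_hex, n_pairs = n_pairs,
             seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
             reason = reason,
             stringsAsFactors = FALSE)
}
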