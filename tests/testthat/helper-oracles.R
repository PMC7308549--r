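# Independent oracles and small fixture builders, kept deliberately naive
# (explicit loops, brute-force scans) so they share no code path with the
# implementation they check.

# Haralick features by explicit double summation.
oracle_haralick <- function(P) {
  n <- nrow(P)
  contrast <- dissim <- entropy <- energy <- homog <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      p <- P[i, j]
      contrast <- contrast + (i - j)^2 * p
      dissim <- dissim + abs(i - j) * p
      if (p > 0) entropy <- entropy - p * log(p)
      energy <- energy + p^2
      homog <- homog + p / (1 + (i - j)^2)
    }
  }
  c(contrast = contrast, dissimilarity = dissim, entropy = entropy,
    energy = energy, homogeneity = homog)
}

# Two-group log-rank chi-square from the textbook O-E / hypergeometric
# variance formula.
oracle_logrank2 <- function(time, event, grp) {
  grp <- as.logical(grp)
  ts <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ts) {
    at <- time >= t
    n <- sum(at)
    n1 <- sum(at & grp)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi <- (O1 - E1)^2 / V
  c(chi = chi, p = stats::pchisq(chi, 1, lower.tail = FALSE))
}

# Brute-force cutpoint scan: every admissible split, log-rank p from the
# oracle formula, minimum p wins (first on ties, scanning ascending).
oracle_cutoff_scan <- function(time, event, values, min_frac = 0.1) {
  u <- sort(unique(values))
  cand <- (u[-length(u)] + u[-1]) / 2
  n <- length(values)
  best <- NULL
  for (cut in cand) {
    high <- values > cut
    if (min(sum(high), n - sum(high)) < ceiling(min_frac * n)) next
    p <- oracle_logrank2(time, event, high)[["p"]]
    if (is.null(best) || p < best$p) best <- list(cutoff = cut, p = p)
  }
  best
}

# Random symmetric normalized co-occurrence-like matrix.
random_sym_matrix <- function(n = 10) {
  M <- matrix(stats::runif(n * n), n, n)
  M <- M + t(M)
  M / sum(M)
}

# Minimal cell map from coordinate vectors.
make_map <- function(x, y, compartment = "tumor", geometry = NULL,
                     bounds = NULL, case_id = "toy", ...) {
  cells <- data.frame(x = x, y = y,
                      compartment = rep(compartment, length.out = length(x)),
                      stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) cells[[nm]] <- extra[[nm]]
  cell_map(case_id, cells, geometry = geometry, bounds = bounds)
}

# Hand-built hexagon lattice (bypasses cell assignment) for co-occurrence
# and adjacency tests.
make_lattice <- function(q, r, percent, retained = TRUE, n_tot = 100L) {
  n_pos <- as.integer(round(percent / 100 * n_tot))
  grid <- build_grid(c(0, 0, 10000, 10000), side = 257, offset = c(0, 0))
  ctr <- hex_center(q, r, grid)
  structure(
    data.frame(q = as.integer(q), r = as.integer(r),
               cx = ctr[, "x"], cy = ctr[, "y"],
               n_pos = n_pos, n_neg = n_tot - n_pos,
               percent = percent,
               retained = rep(retained, length.out = length(q))),
    class = c("hex_lattice", "data.frame"),
    grid = grid, marker = "pr", compartment = "tumor", min_cells = 0L
  )
}

# Survival records helper.
make_records <- function(time, event, ...) {
  out <- data.frame(time = time, event = event)
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}
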