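test_that("decile binning follows the (10(k-1), 10k] intervals", {
  expect_equal(bin_percent(c(0, 10, 10.5, 30, 100)), c(1L, 1L, 2L, 3L, 10L))
  expect_equal(bin_percent(99.999), 10L)
  expect_error(bin_percent(-1), "\\[0, 100\\]")
  expect_error(bin_percent(101), "\\[0, 100\\]")
})

test_that("co-occurrence matrix is symmetric, normalized, and matches a brute-force pair scan", {
  # degenerate: all retained hexes in bin 3
  lat <- make_lattice(q = c(0, 1, 2), r = c(0, 0, 0), percent = c(22, 25, 28))
  cm <- cooccurrence(lat)
  expect_equal(cm$n_pairs, 2L)
  expect_equal(cm$P[3, 3], 1)
  expect_equal(sum(cm$P), 1)

  # one pair with bins (1, 2): symmetric half mass each
  lat2 <- make_lattice(q = c(0, 1), r = c(0, 0), percent = c(5, 15))
  cm2 <- cooccurrence(lat2)
  expect_equal(cm2$P[1, 2], 0.5)
  expect_equal(cm2$P[2, 1], 0.5)

  # random lattice vs. exhaustive enumeration over all hexagon pairs
  set.seed(17)
  patch <- expand.grid(q = 0:5, r = 0:5)
  lat3 <- make_lattice(patch$q, patch$r, percent = runif(nrow(patch), 0, 100))
  lat3$retained <- runif(nrow(lat3)) > 0.2
  cm3 <- cooccurrence(lat3)
  P_oracle <- matrix(0, 10, 10)
  n_oracle <- 0L
  hex_dist <- function(q1, r1, q2, r2) {
    (abs(q1 - q2) + abs(r1 - r2) + abs(q1 + r1 - q2 - r2)) / 2
  }
  for (i in seq_len(nrow(lat3) - 1)) {
    for (j in seq(i + 1, nrow(lat3))) {
      if (!lat3$retained[i] || !lat3$retained[j]) next
      if (hex_dist(lat3$q[i], lat3$r[i], lat3$q[j], lat3$r[j]) != 1) next
      a <- bin_percent(lat3$percent[i])
      b <- bin_percent(lat3$percent[j])
      P_oracle[a, b] <- P_oracle[a, b] + 1
      P_oracle[b, a] <- P_oracle[b, a] + 1
      n_oracle <- n_oracle + 1L
    }
  }
  expect_equal(cm3$n_pairs, n_oracle)
  expect_equal(cm3$P, P_oracle / sum(P_oracle))
  expect_equal(cm3$P, t(cm3$P))

  # no adjacent retained pair: undefined
  none <- make_lattice(q = c(0, 4), r = c(0, 4), percent = c(10, 90))
  expect_equal(cooccurrence(none)$n_pairs, 0L)
  expect_true(all(is.na(haralick(cooccurrence(none)))))
})

test_that("Haralick features match hand-computed and closed-form values", {
  # all mass on one diagonal cell
  P <- matrix(0, 10, 10)
  P[4, 4] <- 1
  expect_equal(haralick(P),
               c(contrast = 0, dissimilarity = 0, entropy = 0,
                 energy = 1, homogeneity = 1))
  # one symmetric off-diagonal pair
  P2 <- matrix(0, 10, 10)
  P2[1, 2] <- P2[2, 1] <- 0.5
  expect_equal(haralick(P2),
               c(contrast = 1, dissimilarity = 1, entropy = log(2),
                 energy = 0.5, homogeneity = 0.5))
  # uniform matrix: entropy ln 100, energy 0.01,
  # contrast = 2 Var(uniform 1..10) = 16.5, dissimilarity = (10^2-1)/30
  U <- matrix(1 / 100, 10, 10)
  h <- haralick(U)
  expect_equal(unname(h["entropy"]), log(100))
  expect_equal(unname(h["energy"]), 0.01)
  expect_equal(unname(h["contrast"]), 16.5)
  expect_equal(unname(h["dissimilarity"]), 3.3)

  expect_error(haralick(matrix(1, 10, 10)), "normalized")
})

test_that("Haralick features equal the double-sum oracle and its invariances", {
  set.seed(11)
  for (k in 1:25) {
    P <- random_sym_matrix(10)
    h <- haralick(P)
    o <- oracle_haralick(P)
    expect_equal(h, o, tolerance = 1e-13)
    # support bounds for the 10x10 case
    expect_lte(h[["entropy"]], log(100))
    expect_gte(h[["energy"]], 0.01)
    # bin-label reversal i -> 11 - i leaves all five unchanged
    rev_idx <- 10:1
    expect_equal(haralick(P[rev_idx, rev_idx]), h, tolerance = 1e-13)
  }
})

test_that("Ashman's D separates bimodal from unimodal hexagon distributions", {
  # all percents equal: D = 0
  expect_equal(ashman_d(rep(42, 30))$d, 0)
  # too few hexagons: undefined with reason
  short <- ashman_d(rnorm(9, 50, 5))
  expect_true(is.na(short$d))
  expect_equal(short$reason, "too_few_hexagons")

  # closed form: 0.5 N(20, 5^2) + 0.5 N(80, 5^2) gives
  # D = sqrt(2)*60 / sqrt(50) = 12
  set.seed(3)
  x <- c(rnorm(2500, 20, 5), rnorm(2500, 80, 5))
  set.seed(3)
  res <- ashman_d(x)
  expect_lt(abs(res$d - 12) / 12, 0.05)
  expect_equal(sort(res$fit$mu), c(20, 80), tolerance = 0.02)

  # unimodal sample scores at least 3x lower, across seeds
  for (s in 1:5) {
    set.seed(s)
    xu <- rnorm(300, 50, 10)
    set.seed(s)
    du <- ashman_d(xu)$d
    expect_lt(du, res$d / 3)
  }
})

test_that("the EM fit agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(14)
  x <- c(rnorm(400, 30, 6), rnorm(600, 70, 9))
  set.seed(14)
  fit <- fit_mixture2(x)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(fit$loglik, mc$loglik, tolerance = 1e-4)
  expect_equal(sort(fit$mu), sort(unname(mc$parameters$mean)), tolerance = 0.02)
  expect_equal(sort(fit$sigma), sort(sqrt(mc$parameters$variance$sigmasq)),
               tolerance = 0.05)
})

test_that("indicator pipeline is deterministic and propagates undefined stages", {
  spec <- scenario_spec(width_mm = 2, height_mm = 2,
                        fields = list(pr = field_patchy(0.2, 0.8)), seed = 9)
  m <- generate_cell_map(spec)
  a <- compute_indicators(m, "pr", seed = 77)
  b <- compute_indicators(m, "pr", seed = 77)
  expect_identical(a, b)
  expect_true(all(!is.na(a[c("entropy", "energy", "ashman_d")])))

  # sparse map: everything filtered out, indicators undefined with reason
  sparse <- generate_cell_map(scenario_spec(width_mm = 1, height_mm = 1,
                                            lambda = c(tumor = 30),
                                            fields = list(pr = field_homogeneous(0.5)),
                                            seed = 2))
  u <- compute_indicators(sparse, "pr", min_cells = 50, seed = 3)
  expect_true(is.na(u$entropy) && is.na(u$ashman_d))
  expect_true(u$reason %in% c("no_retained_hexagons", "no_adjacent_pairs",
                              "too_few_hexagons"))
})
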