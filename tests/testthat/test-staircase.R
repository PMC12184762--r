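test_that("staircase switch weights follow the cosh profile and its limit", {
  sol <- staircase_allocation(6, 1, 1)
  expect_equal(sol$q * 35, c(5, 8, 9, 8, 5), tolerance = 1e-12)
  for (K in c(4, 6, 9, 12))
    expect_equal(staircase_allocation(K, 1, 1)$q[1], 6 / (K * (K + 1)),
                 tolerance = 1e-12)
  # symmetry and positivity
  for (ar in c(0.3, 0.8, 1)) {
    q <- staircase_allocation(7, 1, ar)$q
    expect_equal(q, rev(q), tolerance = 1e-12)
    expect_true(all(q > 0))
  }
  # continuity in alpha*r at 1
  q99 <- staircase_allocation(4, 1, 0.99)$q
  q1 <- staircase_allocation(4, 1, 1)$q
  expect_lt(max(abs(q99 - q1)), 0.01)
  expect_lt(max(abs(staircase_allocation(8, 1, 1 - 1e-8)$q -
                      staircase_allocation(8, 1, 1)$q)), 1e-6)
  expect_error(staircase_allocation(5, 0, 0.5), "\\(0, 1\\]")
  # the allocation sits exactly on the staircase cells and sums to 1
  expect_equal(sum(sol$allocation), 1)
  expect_equal(unname(sol$allocation > 0), staircase_support_of(6))
})

test_that("the closed-form staircase variance matches the GLS engine", {
  for (K in c(3, 6, 10)) for (ar in c(0.3, 0.6, 0.9, 1)) {
    lay <- sw_layout(K)
    pi_sc <- staircase_allocation(K, 1, ar)$allocation
    a_sc <- 2 * (2 * lay$Z - 1) * pi_sc
    # two family members with the same first-order autocorrelation alpha*r
    for (cac in list(cac_model(1, ar), cac_model(ar, 1))) {
      sc <- design_scale(N = 300, K = K, rho = 0.1)
      v <- variance_of(a_sc, pi_sc, lay, cac, sc)$variance
      expect_equal(v, staircase_variance(K, cac$alpha, cac$r, 300, 0.1),
                   tolerance = 1e-10)
    }
  }
  # alpha*r -> 1 limit of the cosh form agrees with the polynomial form
  expect_equal(staircase_variance(7, 1, 1 - 1e-8, 500, 0.2),
               staircase_variance(7, 1, 1, 500, 0.2), tolerance = 1e-6)
  # no cluster-level term at rho = 0
  expect_equal(staircase_variance(5, 0.9, 0.9, 123, 0), 4 / 123)
})

test_that("staircase best-naturality conditions agree between routes and match the tables", {
  # numerical dual check vs printed BEX/DTD closed forms on a grid
  for (K in 3:10) {
    for (a in c(0.5, 0.7, 0.9, 0.97))
      expect_silent(staircase_is_best_na(K, a, 1, method = "both"))
    for (r in c(0.5, 0.7, 0.9, 0.97))
      expect_silent(staircase_is_best_na(K, 1, r, method = "both"))
  }
  # BEX K = 4 threshold is exactly 2/3
  expect_true(staircase_is_best_na(4, 2 / 3 + 1e-4, 1))
  expect_false(staircase_is_best_na(4, 2 / 3 - 1e-4, 1))
  expect_equal(cac_threshold(4, "bex"), 2 / 3, tolerance = 1e-4)
  # DTD K = 4 threshold solves cosh(4*phi) = (1+r)/(1-r): golden-ratio value
  expect_equal(cac_threshold(4, "dtd"), 0.618034, tolerance = 1e-4)
  expect_equal(cac_threshold(3, "dtd"), 0.5, tolerance = 1e-4)
  # exchangeable: staircase for every K
  expect_true(staircase_is_best_na(40, 1, 1))
  expect_equal(max_k_staircase(1, 1), Inf)
  expect_equal(max_k_staircase(0.95, 0.9, K_max = 15), 8)
})

test_that("the tabulated maximum staircase K is reproduced across the parameter grid", {
  printed <- rbind(
    c(2, 2, 2, 2, 2, 2, 2, 3),
    c(2, 2, 2, 2, 3, 3, 3, 3),
    c(2, 2, 2, 3, 3, 4, 4, 4),
    c(2, 2, 3, 4, 4, 4, 5, 5),
    c(2, 3, 4, 5, 6, 7, 7, 7),
    c(2, 3, 4, 6, 8, 9, 10, 10),
    c(2, 3, 5, 7, 12, 17, 22, 24),
    c(3, 3, 5, 8, 15, 27, 84, Inf))
  alphas <- c(0.5, 0.6, 0.7, 0.8, 0.9, 0.95, 0.99, 1)
  rs <- c(0.5, 0.6, 0.7, 0.8, 0.9, 0.95, 0.99, 1)
  for (i in seq_along(alphas)) for (j in seq_along(rs)) {
    v <- printed[i, j]
    if (is.infinite(v)) {
      expect_true(staircase_is_best_na(40, alphas[i], rs[j]))
    } else {
      expect_true(staircase_is_best_na(v, alphas[i], rs[j]),
                  label = sprintf("staircase at K=%d, a=%g r=%g", v, alphas[i], rs[j]))
      expect_false(staircase_is_best_na(v + 1, alphas[i], rs[j]),
                   label = sprintf("no staircase at K=%d, a=%g r=%g", v + 1, alphas[i], rs[j]))
      expect_false(staircase_is_best_na(v + 2, alphas[i], rs[j]),
                   label = sprintf("no staircase at K=%d, a=%g r=%g", v + 2, alphas[i], rs[j]))
    }
  }
})

test_that("tabulated autocorrelation thresholds reproduce to three decimals", {
  tab <- table_cac_thresholds(Ks = c(3, 4, 6, 8, 10))
  expect_equal(round(tab$dtd_r_threshold, 3), c(0.500, 0.618, 0.726, 0.792, 0.835))
  expect_equal(round(tab$bex_alpha_threshold, 3), c(0.500, 0.667, 0.839, 0.907, 0.939))
  expect_equal(round(tab$dtd_rK_threshold, 3), c(0.125, 0.146, 0.147, 0.154, 0.164))
})

test_that("staircase ICV thresholds and cluster-size bounds are consistent", {
  s <- staircase_s1(6, 1, 1)
  expect_equal(s$S1, 0.7, tolerance = 1e-9)
  expect_equal(s$m, 7 / 3, tolerance = 1e-8)
  # exchangeable boundary identity: at rho = (K+1)/(K+1+3M) the bound is exactly M
  K <- 6; M <- 40
  rho_b <- (K + 1) / (K + 1 + 3 * M)
  expect_equal(staircase_s1(K, 1, 1, rho = rho_b)$max_M, M)
  # every tabulated scenario has S1 >= 1/2, i.e. m >= 1
  for (K in c(6, 10, 20)) {
    s <- staircase_s1(K, 1, 0.66^(1 / K))
    expect_gte(s$S1, 0.5)
    expect_gte(s$m, 1)
  }
  expect_error(staircase_s1(10, 0.5, 0.5), "not the best natural")
})

test_that("the cluster-size table reproduces the published limits where the\n  closed-form threshold is exact", {
  tab <- table_max_cluster_size(Ks = c(6, 10), rhos = c(0.05, 0.10, 0.25))
  get <- function(K, rho) tab$max_M[tab$K == K & tab$rho == rho]
  expect_equal(get(10, 0.05), 79)
  expect_equal(get(10, 0.10), 37)
  expect_equal(get(10, 0.25), 12)
  expect_equal(get(6, 0.05), 53)
  expect_equal(get(6, 0.10), 25)
  expect_equal(get(6, 0.25), 8)
})

test_that("the exchangeable optimum above threshold decomposes around the staircase", {
  K <- 6; S <- 7 / 8
  res <- exc_optimum(K, S)
  expect_equal(res$staircase_weight, 1 / 3, tolerance = 1e-12)
  # at the threshold itself the combination is a pure staircase
  at_thr <- exc_optimum(K, 7 / 10)
  expect_equal(at_thr$staircase_weight, 1)
  expect_equal(unname(at_thr$allocation > 0), staircase_support_of(K))
  # decomposition: remove the weighted staircase and a nonnegative component
  # with corner hotspots remains
  pi_sc <- staircase_allocation(K, 1, 1)$allocation
  comp2 <- (res$allocation - res$staircase_weight * pi_sc) /
    (1 - res$staircase_weight)
  expect_gt(min(comp2, na.rm = TRUE), -1e-6)
  expect_gt(comp2[1, 1], 0.02)
  expect_gt(comp2[K, K + 1], 0.02)
  # the staircase is about 84% efficient against this optimum
  lay <- sw_layout(K)
  sc <- design_scale(K = K, S = S)
  v_opt <- blue_coefficients(lay, res$allocation, cac_exc(), sc)$variance$variance
  v_sc <- natural_variance(pi_sc, lay, cac_exc(), sc)
  expect_equal(round(100 * v_opt / v_sc), 84)
  expect_error(exc_optimum(6, 1.2), "\\(0, 1\\)")
})
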