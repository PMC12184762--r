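# the worked 4-cluster example: BEX alpha = 0.7, N*rho/(1-rho) = 80/3
fit4 <- optimal_allocation(sw_layout(4), cac_bex(0.7), design_scale(K = 4, ratio = 80 / 3))

test_that("descent is monotone and the limit is a fixed point of the update map", {
  expect_true(all(diff(fit4$trace) <= 1e-12 * fit4$trace[-1]))
  expect_true(fit4$converged)
  expect_lt(fit4$fixres, 1e-8)
  # fixed point: pi proportional to |a|
  a <- abs(fit4$coefficients[!is.na(fit4$coefficients)])
  p <- fit4$allocation[!is.na(fit4$allocation)]
  expect_lt(max(abs(p - a / sum(a))), 1e-8)
})

test_that("the optimized 4-cluster design has the published support and efficiency", {
  supp_expected <- matrix(FALSE, 4, 5)
  supp_expected[1, c(1, 2, 3, 5)] <- TRUE
  supp_expected[2, c(2, 3, 4)] <- TRUE
  supp_expected[3, c(2, 3, 4)] <- TRUE
  supp_expected[4, c(1, 3, 4, 5)] <- TRUE
  expect_equal(unname(fit4$support), supp_expected)
  eff <- design_efficiency(uniform_allocation(sw_layout(4)), sw_layout(4),
                           cac_bex(0.7), design_scale(K = 4, ratio = 80 / 3),
                           optimum = fit4)
  expect_equal(round(100 * eff), 73)
})

test_that("with uncorrelated cluster-periods the optimum matches the closed form", {
  K <- 6
  lay <- sw_layout(K)
  cf <- identity_na(K)
  for (S in c(0.2, 0.7)) {
    fit <- optimal_allocation(lay, cac_model(0, 0.5), design_scale(K = K, S = S))
    expect_lt(max(abs(fit$allocation - cf$allocation), na.rm = TRUE), 1e-6)
  }
})

test_that("two-sequence optima match the parallel and cross-over closed forms", {
  for (T in c(3, 4, 6)) for (r in c(0.3, 0.7, 0.9)) for (S in c(0.3, 0.8)) {
    sc <- design_scale(K = 2, S = S)
    fit_p <- optimal_allocation(parallel_layout(T), cac_dtd(r), sc)
    expect_lt(max(abs(fit_p$allocation - parallel_crossover_na(T, r, "parallel"))),
              1e-6)
    fit_x <- optimal_allocation(crossover_layout(T), cac_dtd(r), sc)
    expect_lt(max(abs(fit_x$allocation - parallel_crossover_na(T, r, "crossover"))),
              1e-6)
  }
  # endpoint/interior weights for T = 4, r = 0.5: 1/6 and 0.5/6
  pp <- parallel_crossover_na(4, 0.5, "parallel")
  expect_equal(pp[1, 1], 1 / 6, tolerance = 1e-12)
  expect_equal(pp[1, 2], 0.5 / 6, tolerance = 1e-12)
  px <- parallel_crossover_na(3, 0.5, "crossover")
  expect_equal(px[1, 2], 1.5 / (2 * (2 + 1.5)), tolerance = 1e-12)
})

test_that("stepped-wedge optima are skew-symmetric", {
  lay <- sw_layout(5)
  fit <- optimal_allocation(lay, cac_dtd(0.8), design_scale(K = 5, S = 0.6))
  expect_lt(max(abs(fit$allocation - skew_transform(fit$allocation)), na.rm = TRUE),
            1e-6)
  # exchangeable model: non-unique optimum, but the symmetrized average cannot be worse
  lay6 <- sw_layout(6)
  sc6 <- design_scale(K = 6, S = 7 / 8)
  fit6 <- optimal_allocation(lay6, cac_exc(), sc6)
  sym <- (fit6$allocation + skew_transform(fit6$allocation)) / 2
  v_sym <- blue_coefficients(lay6, sym, cac_exc(), sc6)$variance$variance
  expect_lte(v_sym, fit6$variance$variance + 1e-10)
})

test_that("sub-layout optimization honours prohibited cells", {
  K <- 6
  lay <- sw_layout(K)
  sc <- design_scale(K = K, S = 0.5)
  keep <- staircase_support_of(K)
  fit <- optimize_sublayout(lay, prohibited_cells = !keep & !is.na(lay$Z),
                            cac = cac_exc(), scale = sc)
  q <- staircase_allocation(K, 1, 1)$q
  expect_lt(max(abs(fit$allocation[keep] -
                      staircase_allocation(K, 1, 1)$allocation[keep])), 1e-7)
  expect_true(all(fit$allocation[!keep & !is.na(lay$Z)] == 0))
  # prohibiting an entire arm at every epoch destroys the contrast
  expect_error(
    optimize_sublayout(lay, prohibited_cells = (lay$Z == 1) & !is.na(lay$Z),
                       cac = cac_exc(), scale = sc),
    "contrast")
  # prohibiting cells outside the optimum's support leaves the optimum unchanged
  lay4 <- sw_layout(4)
  sc4 <- design_scale(K = 4, ratio = 80 / 3)
  base <- optimal_allocation(lay4, cac_bex(0.7), sc4)
  outside <- !base$support & !is.na(lay4$Z)
  fit2 <- optimize_sublayout(lay4, prohibited_cells = outside,
                             cac = cac_bex(0.7), scale = sc4)
  expect_equal(fit2$variance$variance, base$variance$variance, tolerance = 1e-9)
})

test_that("an initial allocation with empty permitted cells warns", {
  lay <- sw_layout(3)
  init <- uniform_allocation(lay)
  init[1, 1] <- 0
  init <- init / sum(init, na.rm = TRUE)
  expect_warning(
    optimal_allocation(lay, cac_bex(0.5), design_scale(K = 3, S = 0.4),
                       init = init, restart = FALSE),
    "never re-enter")
})

test_that("rounding produces integer designs summing to N with deterministic ties", {
  lay <- sw_layout(2)
  pi <- matrix(NA_real_, 2, 3)
  pi[cbind(lay$cells$k, lay$cells$t)] <- 0
  pi[1, 2] <- 0.5; pi[2, 2] <- 0.5
  rd <- round_design(pi, 7, lay, method = "largest_remainder")
  expect_equal(rd$n[1, 2], 4)  # first cell in (k, t) order wins the tie
  expect_equal(rd$n[2, 2], 3)
  expect_equal(sum(rd$n, na.rm = TRUE), 7)
  # an all-integer target is returned unchanged by both methods
  rd2 <- round_design(pi, 10, lay, method = "apportionment")
  expect_equal(rd2$n[1, 2], 5)
  # rounding the optimum at large N barely affects efficiency
  sc <- design_scale(N = 1e4, K = 4, rho = (80 / 3) / (1e4 + 80 / 3))
  rd3 <- round_design(fit4$allocation, 1e4, sw_layout(4), method = "apportionment")
  eff <- design_efficiency(rd3$realized, sw_layout(4), cac_bex(0.7), sc, optimum = fit4)
  expect_gte(eff, 0.999)
  expect_equal(sum(rd3$n, na.rm = TRUE), 1e4)
  expect_error(round_design(pi, 1, lay, min_one = TRUE), "cannot place")
})

test_that("fit objects print, summarize and expose coefficients", {
  expect_output(print(fit4), "var\\(theta_hat\\)")
  s <- summary(fit4)
  expect_output(print(s), "support")
  expect_equal(dim(coef(fit4)), c(4, 5))
  expect_equal(as.matrix(fit4), fit4$allocation)
})
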