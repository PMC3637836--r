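test_that("per-region OLS reproduces simple-regression closed forms", {
  # perfect line and constant series
  y <- rbind(2 + 3 * (1:5), rep(4, 5))
  p <- panel_from_matrix(y)
  ols <- per_region_ols(p)
  expect_equal(ols$intercept, c(2, 4), tolerance = 1e-12)
  expect_equal(ols$slope, c(3, 0), tolerance = 1e-12)
  expect_equal(ols$sigma2, c(0, 0), tolerance = 1e-12)

  # noisy series against lm(), with the ML variance denominator T
  p2 <- panel_from_matrix(rbind(c(1, 3, 2), c(0.5, 0.1, 0.9)))
  ols2 <- per_region_ols(p2)
  for (i in 1:2) {
    ref <- lm(p2$y[i, ] ~ p2$time_index)
    expect_equal(ols2$intercept[i], unname(coef(ref)[1]), tolerance = 1e-10)
    expect_equal(ols2$slope[i], unname(coef(ref)[2]), tolerance = 1e-10)
    expect_equal(ols2$sigma2[i], mean(residuals(ref)^2), tolerance = 1e-10)
  }
})

test_that("starting values use interpolated quantiles, medians and uniform weights", {
  init <- structure(data.frame(region = paste0("R", 1:5),
                               intercept = c(1, 2, 3, 4, 5),
                               slope = c(0.1, 0.2, 0.3, 0.25, 0.15),
                               sigma2 = c(0.5, 0.4, 0.6, 0.3, 0.45)),
                    class = c("region_ols", "data.frame"))
  st3 <- initial_params(init, J = 3)
  expect_equal(st3$intercepts, c(2, 3, 4), tolerance = 1e-12)
  expect_equal(st3$slope, median(init$slope), tolerance = 1e-12)
  expect_equal(st3$sigma2, median(init$sigma2), tolerance = 1e-12)
  expect_equal(st3$weights, rep(1 / 3, 3))
  # J = 1: quantile convention reduces to the median
  expect_equal(initial_params(init, 1)$intercepts, median(init$intercept))
  # degenerate start is caught when the floor is disabled
  init$sigma2 <- rep(0, 5)
  expect_error(initial_params(init, 2, sigma2_floor = 0), "degenerate")
  expect_gt(initial_params(init, 2)$sigma2, 0)
})

test_that("E-step responsibilities follow Bayes' rule", {
  p <- panel_from_matrix(rbind(c(0.9, 2.2, 2.9), c(4.1, 4.9, 6.2)))
  par <- mixture_params(c(0.3, 0.7), c(0, 3), 1, 0.4)
  e <- e_step(p, par)
  # direct Bayes arithmetic per region
  for (i in 1:2) {
    f <- c(prod(dnorm(p$y[i, ], 0 + 1:3, sqrt(0.4))),
           prod(dnorm(p$y[i, ], 3 + 1:3, sqrt(0.4))))
    expect_equal(unname(e[i, ]), c(0.3, 0.7) * f / sum(c(0.3, 0.7) * f),
                 tolerance = 1e-12)
  }
  expect_equal(unname(rowSums(e)), c(1, 1), tolerance = 1e-12)

  # identical components with uniform weights: symmetric responsibilities
  par_sym <- mixture_params(c(0.5, 0.5), c(1, 1), 0.5, 0.3)
  expect_true(all(abs(e_step(p, par_sym) - 0.5) < 1e-12))
  # J = 1: all ones
  expect_true(all(e_step(p, mixture_params(1, 1, 1, 1)) == 1))
})

test_that("M-step updates equal independent transcription of the closed forms", {
  set.seed(31)
  p <- panel_from_matrix(matrix(rnorm(9, 5), 3, 3))
  y <- p$y; t <- p$time_index; T <- 3; n <- 3
  e <- matrix(c(0.8, 0.2, 0.5, 0.2, 0.8, 0.5), 3, 2)
  prev <- mixture_params(c(0.5, 0.5), c(4.5, 5.5), 0.3, 0.6)

  # naive loops over the printed formulas (literal order: all from prev)
  alpha_ref <- sapply(1:2, function(j)
    sum(sapply(1:n, function(i) e[i, j] * sum(y[i, ] - prev$slope * t))) /
      (T * sum(e[, j])))
  beta_ref <- sum(sapply(1:n, function(i) sum(sapply(1:2, function(j)
    e[i, j] * sum((y[i, ] - prev$intercepts[j]) * t))))) / (n * sum(t^2))
  s2_ref <- sum(sapply(1:n, function(i) sum(sapply(1:2, function(j)
    e[i, j] * sum((y[i, ] - prev$intercepts[j] - prev$slope * t)^2))))) /
    (T * n)

  lit <- m_step(p, e, prev, order = "literal")
  expect_equal(lit$weights, colSums(e) / n, tolerance = 1e-12)
  expect_equal(lit$intercepts, alpha_ref, tolerance = 1e-12)
  expect_equal(lit$slope, beta_ref, tolerance = 1e-12)
  expect_equal(lit$sigma2, s2_ref, tolerance = 1e-12)

  # refreshed order: slope consumes the NEW intercepts
  refreshed <- m_step(p, e, prev, order = "refreshed")
  beta_ref2 <- sum(sapply(1:n, function(i) sum(sapply(1:2, function(j)
    e[i, j] * sum((y[i, ] - alpha_ref[j]) * t))))) / (n * sum(t^2))
  expect_equal(refreshed$intercepts, alpha_ref, tolerance = 1e-12)
  expect_equal(refreshed$slope, beta_ref2, tolerance = 1e-12)

  # per-component slope variant
  prev_cs <- mixture_params(c(0.5, 0.5), c(4.5, 5.5), c(0.3, 0.3), 0.6,
                            spec = model_spec(slope = "component"))
  cs <- m_step(p, e, prev_cs, order = "literal")
  beta_j_ref <- sapply(1:2, function(j)
    sum(sapply(1:n, function(i)
      e[i, j] * sum((y[i, ] - prev_cs$intercepts[j]) * t))) /
      (sum(e[, j]) * sum(t^2)))
  expect_equal(cs$slope, beta_j_ref, tolerance = 1e-12)

  # per-component variance variant
  prev_cv <- mixture_params(c(0.5, 0.5), c(4.5, 5.5), 0.3, c(0.6, 0.6),
                            spec = model_spec(variance = "component"))
  cv <- m_step(p, e, prev_cv, order = "literal")
  s2_j_ref <- sapply(1:2, function(j)
    sum(sapply(1:n, function(i)
      e[i, j] * sum((y[i, ] - prev_cv$intercepts[j] - 0.3 * t)^2))) /
      (T * sum(e[, j])))
  expect_equal(cv$sigma2, s2_j_ref, tolerance = 1e-12)

  # J = 1 with slope held at truth: intercept is the detrended grand mean
  e1 <- matrix(1, 3, 1)
  prev1 <- mixture_params(1, 0, 0.3, 0.6)
  up1 <- m_step(p, e1, prev1, order = "literal")
  expect_equal(up1$intercepts, mean(sweep(y, 2, 0.3 * t)), tolerance = 1e-12)
})

test_that("EM likelihood is monotone and the fit respects normalisation", {
  tp <- mixture_params(c(0.4, 0.6), c(70, 73), 0.25, 0.3)
  sim <- simulate_panel(tp, n = 30, T = 10, seed = 19)
  fit <- fit_em(sim$panel, 2)
  expect_true(all(diff(fit$trace) >= -1e-8))
  expect_true(all(abs(rowSums(fit$posterior) - 1) < 1e-12))
  expect_lt(abs(sum(fit$params$weights) - 1), 1e-12)
  expect_true(all(fit$params$sigma2 > 0))
  expect_true(fit$converged)
  # components reported in ascending intercept order
  expect_true(!is.unsorted(fit$params$intercepts))
})

test_that("J = 1 EM equals the pooled single-line OLS closed forms", {
  set.seed(23)
  sim <- simulate_panel(mixture_params(1, 71, 0.2, 0.4), n = 12, T = 8,
                        seed = 29)
  fit <- fit_em(sim$panel, 1, control = em_control(tol = 1e-11))
  ref <- pooled_ols(sim$panel)
  expect_equal(fit$params$intercepts, ref$intercept, tolerance = 1e-8)
  expect_equal(fit$params$slope, ref$slope, tolerance = 1e-8)
  expect_equal(fit$params$sigma2, ref$sigma2, tolerance = 1e-8)
})

test_that("converged common slope equals the pooled least-squares slope", {
  # the mechanism behind the slope column being constant in J
  tp <- nrw_mixture_params("men")
  sim <- simulate_panel(tp, n = 54, T = 21, seed = 37)
  target <- pooled_slope(sim$panel)
  for (J in c(2, 5, 7)) {
    fit <- fit_em(sim$panel, J, control = em_control(tol = 1e-6))
    expect_equal(fit$params$slope, target, tolerance = 10 * 1e-6)
  }
})

test_that("well-separated components are recovered with labels intact", {
  tp <- mixture_params(c(0.5, 0.5), c(0, 6), 0.5, 1)  # gap = 6 sigma
  sim <- simulate_panel(tp, n = 40, T = 12, seed = 41)
  fit <- fit_em(sim$panel, 2)
  se <- sqrt(1 / (0.5 * 40 * 12))  # rough alpha standard error
  expect_lt(abs(fit$params$intercepts[1] - 0), 3 * se + 0.3)
  expect_lt(abs(fit$params$intercepts[2] - 6), 3 * se + 0.3)
  expect_equal(mean(map_classify(fit)$class == sim$truth$z), 1)
})

test_that("EM attains the brute-force direct maximum of the mixture likelihood", {
  panel <- toy_two_group_panel()
  y <- panel$y
  fit <- fit_em(panel, 2,
                control = em_control(tol = 1e-10, n_starts = 4, seed = 7))
  # independent oracle: direct numerical maximization of the observed
  # likelihood over (alpha1, alpha2, beta, log sigma2, logit p1) from a grid
  negll <- function(th) {
    s2 <- exp(th[4]); p1 <- plogis(th[5]); t <- 1:3
    -sum(apply(y, 1, function(yi)
      log(p1 * prod(dnorm(yi, th[1] + th[3] * t, sqrt(s2))) +
          (1 - p1) * prod(dnorm(yi, th[2] + th[3] * t, sqrt(s2))))))
  }
  best <- Inf
  for (a1 in c(-0.5, 0.5)) for (a2 in c(2.5, 3.5)) for (ls in c(-4, -1))
    for (lp in c(-0.5, 0.5)) {
      o <- optim(c(a1, a2, 1, ls, lp), negll, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-13))
      o <- suppressWarnings(optim(o$par, negll, method = "BFGS",
                                  control = list(reltol = 1e-13)))
      best <- min(best, o$value)
    }
  expect_gte(fit$loglik, -best - 1e-6)
})

test_that("component-number sweep tabulates fits and selects by BIC", {
  tp <- mixture_params(c(0.3, 0.4, 0.3), c(70, 73, 76), 0.25, 0.25)
  sim <- simulate_panel(tp, n = 60, T = 10, seed = 43)
  sw <- sweep_components(sim$panel, 1:4)
  expect_equal(sw$table$J, 1:4)
  expect_equal(sw$selected, 3L)
  # the common slope column is constant across J
  expect_lt(diff(range(sw$table$slope)), 1e-3)
  # one-row sweep trivially selects its only candidate
  sw1 <- sweep_components(sim$panel, 1)
  expect_equal(nrow(sw1$table), 1L)
  expect_equal(sw1$selected, 1L)
  expect_error(sweep_components(sim$panel, 0:2), "within")
})

test_that("nested likelihood-ratio test reproduces the chi-square tail", {
  f0 <- structure(list(loglik = -2920.2 / 2, r = 15L),
                  class = "growth_mixture_fit")
  f1 <- structure(list(loglik = -2919.0 / 2, r = 16L),
                  class = "growth_mixture_fit")
  lrt <- lrt_nested(f0, f1)
  expect_equal(lrt$statistic, 1.2, tolerance = 1e-10)
  expect_equal(lrt$df, 1L)
  expect_lt(abs(lrt$p.value - 0.27), 0.01)
  # identical fits: zero statistic, p = 1
  same <- lrt_nested(f0, structure(list(loglik = f0$loglik, r = 16L),
                                   class = "growth_mixture_fit"))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  # canonical 5% point
  expect_equal(lrt_nested(f0, structure(list(loglik = f0$loglik + 3.84 / 2,
                                             r = 16L), class = "growth_mixture_fit"))$p.value,
               0.05, tolerance = 0.001)
  # an alternative below the null signals optimizer failure
  expect_warning(lrt_nested(f1, structure(list(loglik = f1$loglik - 1,
                                               r = 17L),
                                          class = "growth_mixture_fit")),
                 "below the null")
})

test_that("quadratic trend fit nests the linear fit and is testable", {
  tp <- mixture_params(c(0.5, 0.5), c(70, 73), 0.25, 0.2)
  sim <- simulate_panel(tp, n = 30, T = 10, seed = 47)
  lin <- fit_em(sim$panel, 2)
  quad <- fit_em(sim$panel, 2, spec = model_spec(mean = "quadratic"))
  expect_identical(quad$r, lin$r + 1L)
  expect_gte(quad$loglik, lin$loglik - 1e-6)
  lrt <- lrt_nested(lin, quad)
  expect_identical(lrt$df, 1L)
  # data were generated without curvature: no significant improvement
  expect_gt(lrt$p.value, 0.01)
})
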