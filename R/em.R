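#' Per-region ordinary least squares
#'
#' Fits a separate straight line of outcome on the time index 1..T for each
#' region (simple regression closed forms).  The residual variance uses the
#' maximum-likelihood denominator T, consistent with the mixture variance
#' definition.  These per-region coefficients seed the EM starting values.
#'
#' @param panel A `"growth_panel"`.
#' @return Object of class `"region_ols"`: a data frame with one row per
#'   region and columns `region`, `intercept`, `slope`, `sigma2`.
#' @export
per_region_ols <- function(panel) {
  stopifnot(inherits(panel, "growth_panel"))
  y <- panel$y
  t <- panel$time_index
  T <- length(t)
  if (T < 3L) stop("per-region OLS needs T >= 3", call. = FALSE)
  tbar <- mean(t)
  stt <- sum((t - tbar)^2)
  ybar <- rowMeans(y)
  b <- as.vector(y %*% (t - tbar)) / stt
  a <- ybar - b * tbar
  fitted <- outer(a, rep(1, T)) + outer(b, t)
  s2 <- rowSums((y - fitted)^2) / T
  structure(data.frame(region = panel$region_ids, intercept = a,
                       slope = b, sigma2 = s2,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("region_ols", "data.frame"))
}

#' EM starting values from per-region OLS coefficients
#'
#' Starting intercepts are empirical quantiles of the per-region OLS
#' intercepts at probabilities j/(J+1), j = 1..J (linear interpolation,
#' reducing to the median at J = 1); the starting slope and variance are the
#' medians of the per-region slopes and residual variances; weights start
#' uniform.  The variance start is floored at a small positive constant so a
#' perfectly linear panel does not produce a degenerate start.
#'
#' @param init A `"region_ols"` object from [per_region_ols()].
#' @param J Number of components.
#' @param spec A [model_spec()]; per-component slopes/variances are started
#'   at the common value, curvature at 0.
#' @param sigma2_floor Lower bound for the starting variance (default 1e-8);
#'   set to 0 to disable (then an all-zero residual panel is an error).
#' @return A [mixture_params()] object.
#' @export
initial_params <- function(init, J, spec = model_spec(),
                           sigma2_floor = 1e-8) {
  stopifnot(J >= 1)
  a <- init$intercept
  alpha0 <- unname(stats::quantile(a, probs = seq_len(J) / (J + 1),
                                   type = 7))
  beta0 <- stats::median(init$slope)
  s20 <- max(stats::median(init$sigma2), sigma2_floor)
  if (s20 <= 0)
    stop("all per-region residual variances are zero and the variance ",
         "floor is disabled: degenerate start", call. = FALSE)
  mixture_params(
    weights = rep(1 / J, J),
    intercepts = alpha0,
    slope = if (spec$slope == "common") beta0 else rep(beta0, J),
    sigma2 = if (spec$variance == "common") s20 else rep(s20, J),
    curvature = if (spec$mean == "quadratic") 0 else NULL,
    spec = spec)
}

#' E-step: posterior component membership probabilities
#'
#' Applies Bayes' theorem per region: the responsibility of component j for
#' region i is proportional to the mixing weight times the component density
#' of the region's trajectory.  Computed in log space with a per-row
#' log-sum-exp normalisation.
#'
#' @param panel A `"growth_panel"`.
#' @param params A [mixture_params()] object.
#' @return An n x J matrix of responsibilities; rows (named by region) sum
#'   to 1.
#' @export
e_step <- function(panel, params) {
  lw <- ifelse(params$weights > 0, log(params$weights), -Inf)
  lm <- sweep(logdens_matrix(panel, params), 2L, lw, `+`)
  mx <- apply(lm, 1L, max)
  bad <- !is.finite(mx)
  if (any(bad))
    stop("numerically degenerate posterior (all components at -Inf) for ",
         "region(s): ",
         paste(panel$region_ids[bad], collapse = ", "), call. = FALSE)
  e <- exp(lm - mx)
  e <- e / rowSums(e)
  dimnames(e) <- list(panel$region_ids, NULL)
  e
}

#' M-step: closed-form parameter updates
#'
#' Updates weights, intercepts, slope(s), optional curvature and
#' variance(s) by the closed-form maximisers of the expected complete-data
#' log-likelihood.  With `order = "refreshed"` (the default used by
#' [fit_em()]) each formula consumes the most recently updated values:
#' intercepts use the previous slope, the slope update uses the new
#' intercepts, and the variance uses both new values — this is the
#' coordinate-ascent ordering under which the observed likelihood is
#' monotone.  With `order = "literal"` every right-hand side uses the
#' previous cycle's values.
#'
#' Components whose total responsibility falls below 1e-10 are frozen at
#' their previous parameter values for the cycle, with a warning.  The
#' variance update is floored at 1e-10 (with a warning) to guard against
#' the degeneracy of the likelihood as the variance approaches zero.
#'
#' @param panel A `"growth_panel"`.
#' @param e Responsibility matrix from [e_step()].
#' @param prev Previous-cycle [mixture_params()].
#' @param order `"refreshed"` or `"literal"`.
#' @return Updated [mixture_params()].
#' @export
m_step <- function(panel, e, prev, order = c("refreshed", "literal")) {
  order <- match.arg(order)
  spec <- prev$spec
  y <- panel$y
  t <- panel$time_index
  T <- length(t)
  n <- nrow(y)
  J <- prev$J
  St <- sum(t); St2 <- sum(t^2); St3 <- sum(t^3); St4 <- sum(t^4)

  w <- colSums(e)                       # total responsibility per component
  empty <- w < 1e-10
  if (any(empty))
    warning("component(s) ", paste(which(empty), collapse = ", "),
            " received (near) zero total responsibility; parameters frozen ",
            "for this cycle", call. = FALSE)
  p_new <- w / n

  ys <- rowSums(y)                      # sum_t y_it
  yt <- as.vector(y %*% t)              # sum_t y_it * t
  yt2 <- as.vector(y %*% t^2)           # sum_t y_it * t^2
  ewys <- as.vector(crossprod(e, ys))   # sum_i e_ij sum_t y_it
  ewyt <- as.vector(crossprod(e, yt))

  gam_prev <- if (is.null(prev$curvature)) 0 else prev$curvature
  beta_prev <- if (spec$slope == "common") rep(prev$slope, J) else prev$slope

  # --- intercepts (always from the previous slope/curvature) -------------
  alpha_new <- (ewys - w * (beta_prev * St + gam_prev * St2)) / (T * w)
  alpha_new[empty] <- prev$intercepts[empty]

  alpha_for_slope <- switch(order, refreshed = alpha_new,
                            literal = prev$intercepts)

  # --- slope(s) / curvature ---------------------------------------------
  gam_new <- prev$curvature
  if (spec$mean == "quadratic") {
    A1 <- sum(yt) - St * sum(w * alpha_for_slope)
    A2 <- sum(yt2) - St2 * sum(w * alpha_for_slope)
    sol <- solve(matrix(c(St2, St3, St3, St4), 2L, 2L), c(A1, A2) / n)
    beta_new <- sol[1L]
    gam_new <- sol[2L]
  } else if (spec$slope == "common") {
    beta_new <- (sum(yt) - St * sum(w * alpha_for_slope)) / (n * St2)
  } else {
    beta_new <- (ewyt - w * alpha_for_slope * St) / (w * St2)
    beta_new[empty] <- prev$slope[empty]
  }

  alpha_for_var <- switch(order, refreshed = alpha_new,
                          literal = prev$intercepts)
  beta_for_var <- switch(order,
                         refreshed = if (spec$slope == "common")
                           rep(beta_new, J) else beta_new,
                         literal = beta_prev)
  gam_for_var <- switch(order, refreshed = gam_new, literal = prev$curvature)

  # --- variance(s) -------------------------------------------------------
  rss <- numeric(J)                     # sum_i e_ij sum_t resid^2
  for (j in seq_len(J)) {
    mu <- component_mean(t, alpha_for_var[j], beta_for_var[j], gam_for_var)
    rj <- rowSums(sweep(y, 2L, mu)^2)
    rss[j] <- sum(e[, j] * rj)
  }
  if (spec$variance == "common") {
    s2_new <- sum(rss) / (T * n)
  } else {
    s2_new <- rss / (T * w)
    s2_new[empty] <- prev$sigma2[empty]
  }
  if (any(s2_new < 1e-10)) {
    warning("variance update fell below 1e-10; floored (likelihood ",
            "degeneracy guard)", call. = FALSE)
    s2_new <- pmax(s2_new, 1e-10)
  }

  mixture_params(weights = p_new, intercepts = alpha_new,
                 slope = if (spec$slope == "common") beta_new else beta_new,
                 sigma2 = s2_new, curvature = gam_new, spec = spec)
}

#' EM fitting control settings
#'
#' @param tol Convergence threshold for the maximum absolute per-parameter
#'   change between consecutive cycles (default 1e-4).
#' @param max_iter Maximum number of EM cycles (default 10000).
#' @param order M-step update ordering, `"refreshed"` (default; monotone
#'   likelihood) or `"literal"` (all updates from the previous cycle).
#' @param n_starts Number of EM runs; runs beyond the first perturb the
#'   starting intercepts with seeded normal noise and the best final
#'   likelihood wins (default 1, the deterministic quantile start).
#' @param seed Integer seed for the multi-start perturbations.
#' @param verbose Print the likelihood trajectory while fitting.
#' @return A list of class `"em_control"`.
#' @export
em_control <- function(tol = 1e-4, max_iter = 10000L,
                       order = c("refreshed", "literal"),
                       n_starts = 1L, seed = NULL, verbose = FALSE) {
  stopifnot(tol > 0, max_iter >= 1, n_starts >= 1)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 order = match.arg(order), n_starts = as.integer(n_starts),
                 seed = seed, verbose = isTRUE(verbose)),
            class = "em_control")
}

param_vector <- function(p) {
  c(p$weights, p$intercepts, p$slope, p$sigma2,
    if (!is.null(p$curvature)) p$curvature)
}

run_em_once <- function(panel, params, control) {
  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    e <- e_step(panel, params)
    ll_trace[iter] <- mixture_loglik(panel, params)
    if (control$verbose)
      cat(sprintf("iter %4d  loglik %.6f\n", iter, ll_trace[iter]))
    new <- m_step(panel, e, params, order = control$order)
    delta <- max(abs(param_vector(new) - param_vector(params)))
    params <- new
    if (delta < control$tol) { converged <- TRUE; break }
    if (iter >= control$max_iter) break
  }
  list(params = params, n_iter = iter, converged = converged,
       trace = ll_trace)
}

#' Fit a growth-line mixture by the EM algorithm
#'
#' Alternates [e_step()] and [m_step()] from the [initial_params()] start
#' until the maximum absolute change over all parameters drops below
#' `control$tol`, then reports the fit with components sorted by ascending
#' intercept, the observed log-likelihood, the free-parameter count and
#' both BIC variants.
#'
#' @param panel A `"growth_panel"`.
#' @param J Number of mixture components.
#' @param spec A [model_spec()].
#' @param control An [em_control()].
#' @return Object of class `"growth_mixture_fit"`: list with `params`,
#'   `posterior` (n x J responsibilities), `loglik`, `r`, `BIC`, `BIC2`,
#'   `n_iter`, `converged`, `trace` (log-likelihood per iteration), `spec`,
#'   `control`, `region_ids`, `n`, `T`.
#' @export
fit_em <- function(panel, J, spec = model_spec(), control = em_control()) {
  stopifnot(inherits(panel, "growth_panel"), J >= 1)
  init <- per_region_ols(panel)
  start <- initial_params(init, J, spec)

  best <- NULL
  for (s in seq_len(control$n_starts)) {
    st <- start
    if (s > 1L) {
      if (!is.null(control$seed)) set.seed(control$seed + s)
      spread <- stats::sd(init$intercept)
      if (!is.finite(spread) || spread == 0) spread <- 1
      st$intercepts <- start$intercepts + stats::rnorm(J, 0, spread / 2)
    }
    run <- run_em_once(panel, st, control)
    run$loglik <- mixture_loglik(panel, run$params)
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  if (!best$converged)
    warning("EM did not converge within ", control$max_iter,
            " iterations (tol = ", control$tol, ")", call. = FALSE)

  params <- sort_components(best$params)
  post <- e_step(panel, params)
  ll <- mixture_loglik(panel, params)
  n <- n_regions(panel); T <- n_times(panel)
  ic <- information_criteria(ll, J, n, T, spec)

  structure(list(params = params, posterior = post, loglik = ll,
                 r = ic$r, BIC = ic$BIC, BIC2 = ic$BIC2,
                 n_iter = best$n_iter, converged = best$converged,
                 trace = best$trace, spec = spec, control = control,
                 region_ids = panel$region_ids, n = n, T = T),
            class = "growth_mixture_fit")
}

#' @export
print.growth_mixture_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Growth-line mixture fit: J = %d, n = %d regions, T = %d\n",
              x$params$J, x$n, x$T))
  cat(sprintf("  loglik %.4f | r = %d | BIC %.2f | BIC2 %.2f\n",
              x$loglik, x$r, x$BIC, x$BIC2))
  cat(sprintf("  %d EM iterations (%sconverged)\n", x$n_iter,
              if (x$converged) "" else "NOT "))
  print(x$params, digits = digits)
  invisible(x)
}

#' @export
logLik.growth_mixture_fit <- function(object, ...) {
  structure(object$loglik, df = object$r, nobs = object$n * object$T,
            class = "logLik")
}

#' Fit a range of component numbers and select by BIC
#'
#' Runs [fit_em()] for each candidate J and tabulates slope, variance and
#' both BIC variants (one row per J).  The selected J minimises BIC (ties
#' resolved toward the smaller J); the BIC2 minimiser is reported alongside.
#'
#' @param panel A `"growth_panel"`.
#' @param J_range Integer vector of candidate component numbers (default
#'   `1:10`).
#' @param spec A [model_spec()].
#' @param control An [em_control()].
#' @return Object of class `"mixture_sweep"`: list with `table` (data frame
#'   with columns J, slope, sigma2, loglik, BIC, BIC2, converged),
#'   `fits` (list of `"growth_mixture_fit"`), `selected` (BIC argmin) and
#'   `selected_bic2`.
#' @export
sweep_components <- function(panel, J_range = 1:10, spec = model_spec(),
                             control = em_control()) {
  J_range <- sort(unique(as.integer(J_range)))
  if (any(J_range < 1L) || any(J_range > n_regions(panel)))
    stop("J_range must lie within [1, number of regions]", call. = FALSE)
  fits <- lapply(J_range, function(J) fit_em(panel, J, spec, control))
  tab <- data.frame(
    J = J_range,
    slope = vapply(fits, function(f)
      if (spec$slope == "common") f$params$slope else NA_real_, 1),
    sigma2 = vapply(fits, function(f)
      if (spec$variance == "common") f$params$sigma2 else NA_real_, 1),
    loglik = vapply(fits, function(f) f$loglik, 1),
    BIC = vapply(fits, function(f) f$BIC, 1),
    BIC2 = vapply(fits, function(f) f$BIC2, 1),
    converged = vapply(fits, function(f) f$converged, TRUE))
  structure(list(table = tab, fits = fits,
                 selected = J_range[which.min(tab$BIC)],
                 selected_bic2 = J_range[which.min(tab$BIC2)]),
            class = "mixture_sweep")
}

#' @export
print.mixture_sweep <- function(x, digits = 4, ...) {
  cat("Component-number sweep\n")
  tab <- x$table
  tab$slope <- round(tab$slope, digits)
  tab$sigma2 <- round(tab$sigma2, digits)
  tab$loglik <- round(tab$loglik, 2)
  tab$BIC <- round(tab$BIC, 2)
  tab$BIC2 <- round(tab$BIC2, 2)
  print(tab, row.names = FALSE)
  cat(sprintf("selected J = %d by BIC (BIC2 selects J = %d)\n",
              x$selected, x$selected_bic2))
  invisible(x)
}

#' Likelihood-ratio test of nested mixture specifications
#'
#' Compares two fits of nested specifications on the same panel and the
#' same J (for example a linear against a quadratic time trend).  The
#' statistic is twice the log-likelihood difference; the p-value comes from
#' the chi-square upper tail with degrees of freedom equal to the
#' difference in free-parameter counts.
#'
#' @param fit_null,fit_alt Fits from [fit_em()]; `fit_null` must be nested
#'   in `fit_alt`.
#' @return A list with `statistic`, `df` and `p.value`.
#' @export
lrt_nested <- function(fit_null, fit_alt) {
  stat <- 2 * (fit_alt$loglik - fit_null$loglik)
  df <- fit_alt$r - fit_null$r
  if (df < 1L)
    stop("alternative model must have more free parameters than the null",
         call. = FALSE)
  if (stat < -1e-6)
    warning("alternative log-likelihood is below the null beyond tolerance",
            " (optimizer failure signal); statistic truncated at 0",
            call. = FALSE)
  stat <- max(stat, 0)
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}
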