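#' Simulate a balanced panel from the generative mixture model
#'
#' Each region draws a latent component from the mixing weights, then its
#' trajectory is the component's growth line plus independent mean-zero
#' normal errors at every time point.
#'
#' @param params A [mixture_params()] object (the generating truth).
#' @param n Number of regions (default 54).
#' @param T Number of time points (default 21).
#' @param seed Integer seed; the draw is fully reproducible from it.
#' @param region_ids Optional region labels (default `"R1".."Rn"`).
#' @param years Optional calendar years (default `seq_len(T)` shifted to
#'   1990 when T = 21, mirroring the study period, else `1:T`).
#' @param covariate Optional named 0/1 vector attached to the panel.
#' @return A list with `panel` (a `"growth_panel"`) and `truth` (class
#'   `"sim_truth"`: the generating `params`, the latent labels `z` and the
#'   `seed`).
#' @export
simulate_panel <- function(params, n = 54, T = 21, seed = NULL,
                           region_ids = NULL, years = NULL,
                           covariate = NULL) {
  stopifnot(inherits(params, "mixture_params"), n >= 1, T >= 1)
  if (!is.null(seed)) set.seed(seed)
  J <- params$J
  z <- sample.int(J, size = n, replace = TRUE, prob = params$weights)
  t <- seq_len(T)
  slopes <- if (params$spec$slope == "common")
    rep(params$slope, J) else params$slope
  s2 <- if (params$spec$variance == "common")
    rep(params$sigma2, J) else params$sigma2
  mu <- t(vapply(z, function(j)
    component_mean(t, params$intercepts[j], slopes[j], params$curvature),
    numeric(T)))
  noise <- matrix(stats::rnorm(n * T, sd = sqrt(s2[z])), n, T)
  y <- mu + noise
  if (is.null(region_ids)) region_ids <- paste0("R", seq_len(n))
  if (is.null(years)) years <- if (T == 21) 1989 + t else t
  rownames(y) <- region_ids; colnames(y) <- years
  panel <- structure(list(y = y, region_ids = region_ids, years = years,
                          time_index = t, covariate = covariate),
                     class = "growth_panel")
  truth <- structure(list(params = params, z = z, seed = seed),
                     class = "sim_truth")
  list(panel = panel, truth = truth)
}

#' Parameter-recovery simulation study
#'
#' Repeatedly simulates panels from a known truth, refits each with
#' [fit_em()] at the true J, aligns components by ascending intercept and
#' scores per-parameter bias and RMSE plus the agreement between MAP
#' classes and the true latent labels.  Optionally also sweeps the
#' component number on each replicate and records how often BIC selects
#' the true J.
#'
#' @param true_params Generating [mixture_params()].
#' @param n,T Panel geometry (defaults 54 x 21).
#' @param reps Number of replicates (default 10).
#' @param seed Master seed; replicate r uses `seed * 1000 + r`.
#' @param control An [em_control()] passed to the fits.
#' @param sweep_range Optional integer vector; when given, BIC selection is
#'   scored over this range per replicate (slower).
#' @return Object of class `"recovery_report"`: list with `estimates`
#'   (one row per replicate: slope, sigma2, intercepts, weights, label
#'   agreement, convergence), `bias` and `rmse` (named vectors over all
#'   scalar parameters), `label_agreement` (mean), `selection` (table of
#'   selected J, or `NULL`), `seeds`, `true_params`.
#' @export
recovery_study <- function(true_params, n = 54, T = 21, reps = 10,
                           seed = 1, control = em_control(),
                           sweep_range = NULL) {
  stopifnot(reps >= 1)
  J <- true_params$J
  seeds <- seed * 1000 + seq_len(reps)
  rows <- vector("list", reps)
  selected <- integer(0)
  for (r in seq_len(reps)) {
    sim <- simulate_panel(true_params, n = n, T = T, seed = seeds[r])
    fit <- tryCatch(fit_em(sim$panel, J, true_params$spec, control),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[r]] <- data.frame(rep = r, failed = TRUE)
      next
    }
    cls <- map_classify(fit)
    est <- c(slope = if (true_params$spec$slope == "common")
               fit$params$slope else NA_real_,
             sigma2 = if (true_params$spec$variance == "common")
               fit$params$sigma2 else NA_real_)
    row <- data.frame(rep = r, failed = FALSE, t(est),
                      agreement = mean(cls$class == sim$truth$z),
                      converged = fit$converged)
    for (j in seq_len(J)) {
      row[[paste0("alpha", j)]] <- fit$params$intercepts[j]
      row[[paste0("p", j)]] <- fit$params$weights[j]
    }
    rows[[r]] <- row
    if (!is.null(sweep_range)) {
      sw <- sweep_components(sim$panel, sweep_range, true_params$spec,
                             control)
      selected <- c(selected, sw$selected)
    }
  }
  est <- do.call(rbind, rows[!vapply(rows, function(x) isTRUE(x$failed),
                                     TRUE)])
  truth_vec <- c(slope = if (true_params$spec$slope == "common")
                   true_params$slope else NA_real_,
                 sigma2 = if (true_params$spec$variance == "common")
                   true_params$sigma2 else NA_real_,
                 stats::setNames(true_params$intercepts,
                                 paste0("alpha", seq_len(J))),
                 stats::setNames(true_params$weights,
                                 paste0("p", seq_len(J))))
  truth_vec <- truth_vec[!is.na(truth_vec)]
  bias <- rmse <- stats::setNames(numeric(length(truth_vec)),
                                  names(truth_vec))
  for (nm in names(truth_vec)) {
    err <- est[[nm]] - truth_vec[[nm]]
    bias[nm] <- mean(err)
    rmse[nm] <- sqrt(mean(err^2))
  }
  structure(list(estimates = est, bias = bias, rmse = rmse,
                 label_agreement = mean(est$agreement),
                 selection = if (length(selected)) table(selected) else NULL,
                 seeds = seeds, true_params = true_params),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, digits = 4, ...) {
  cat(sprintf("Parameter-recovery study: %d replicate(s)\n",
              nrow(x$estimates)))
  cat("bias:\n"); print(round(x$bias, digits))
  cat("rmse:\n"); print(round(x$rmse, digits))
  cat(sprintf("mean MAP/truth label agreement: %.3f\n", x$label_agreement))
  if (!is.null(x$selection)) {
    cat("BIC-selected J frequencies:\n"); print(x$selection)
  }
  invisible(x)
}
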