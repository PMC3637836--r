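# fixtures built in code; no files

# wrap an n x T matrix as a validated growth panel via the long-format path
panel_from_matrix <- function(y, years = seq_len(ncol(y)), covariate = NULL) {
  n <- nrow(y); T <- ncol(y)
  ids <- rownames(y)
  if (is.null(ids)) ids <- paste0("R", seq_len(n))
  df <- data.frame(Region = rep(ids, each = T),
                   Year = rep(years, times = n),
                   LifeE = as.vector(t(y)))
  if (!is.null(covariate)) df$UrbanRural <- rep(covariate, each = T)
  as_panel(df)
}

# small deterministic two-group panel (n=4, T=3): lines 0 + t and 3 + t
toy_two_group_panel <- function() {
  y <- rbind(c(1.1, 2.0, 2.9), c(0.9, 2.1, 3.1),
             c(4.2, 5.0, 6.1), c(3.8, 5.1, 5.9))
  panel_from_matrix(y)
}

# long-format data frame mirroring the NRW file schema
toy_long_df <- function() {
  data.frame(Region = rep(c("A", "B"), each = 3),
             Year = rep(2001:2003, 2),
             LifeE = c(70.1, 70.4, 70.6, 72.0, 72.3, 72.5),
             UrbanRural = rep(c(0, 1), each = 3))
}

# pooled single-line OLS closed forms with ML variance denominator
pooled_ols <- function(panel) {
  df <- as.data.frame(panel)
  fit <- lm(outcome ~ time, data = df)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       sigma2 = mean(residuals(fit)^2))
}

# pooled least-squares slope in closed form (centred time)
pooled_slope <- function(panel) {
  t <- panel$time_index
  sum(sweep(panel$y, 2, 0) %*% (t - mean(t))) /
    (nrow(panel$y) * sum((t - mean(t))^2))
}
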