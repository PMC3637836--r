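#' Write fit, classification and sweep tables to disk
#'
#' Emits up to three delimited text files into a directory: a per-region
#' classification table (`classification.csv`: Region, Class, one posterior
#' column per component, rounded to `digits`), a parameter table
#' (`parameters.csv`: component, weight, intercept, slope, sigma2 and
#' curvature where present), and, when a sweep is supplied, the
#' model-comparison table (`sweep.csv`: J, slope, sigma2, BIC, BIC2).
#' Re-reading the classification file reproduces the MAP classes exactly
#' and the posteriors to the written precision.
#'
#' @param fit A `"growth_mixture_fit"`.
#' @param classification A [map_classify()] result for the same fit;
#'   computed from `fit` when omitted.
#' @param dir Output directory (created if absent).
#' @param sweep Optional `"mixture_sweep"`.
#' @param digits Rounding for posterior probabilities (default 2, the
#'   published tables' precision).
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(fit, classification = NULL, dir, sweep = NULL,
                          digits = 2) {
  stopifnot(inherits(fit, "growth_mixture_fit"))
  if (is.null(classification)) classification <- map_classify(fit)
  if (!setequal(classification$region, fit$region_ids))
    stop("classification and fit refer to different region sets",
         call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)

  cls <- as.data.frame(classification)
  post <- grep("^e[0-9]+$", names(cls))
  cls[post] <- lapply(cls[post], round, digits = digits)
  names(cls)[1:2] <- c("Region", "Class")
  f <- file.path(dir, "classification.csv")
  utils::write.table(cls, f, sep = ",", row.names = FALSE, quote = FALSE)
  written <- c(written, f)

  p <- fit$params
  par_tab <- data.frame(component = seq_len(p$J), weight = p$weights,
                        intercept = p$intercepts)
  par_tab$slope <- if (p$spec$slope == "common") rep(p$slope, p$J) else p$slope
  par_tab$sigma2 <- if (p$spec$variance == "common")
    rep(p$sigma2, p$J) else p$sigma2
  if (!is.null(p$curvature)) par_tab$curvature <- p$curvature
  f <- file.path(dir, "parameters.csv")
  utils::write.table(par_tab, f, sep = ",", row.names = FALSE, quote = FALSE)
  written <- c(written, f)

  if (!is.null(sweep)) {
    f <- file.path(dir, "sweep.csv")
    utils::write.table(sweep$table, f, sep = ",", row.names = FALSE,
                       quote = FALSE)
    written <- c(written, f)
  }
  invisible(written)
}

#' Read back a written classification table
#'
#' @param path Path to a `classification.csv` written by [write_results()].
#' @return A `"map_classification"` data frame.
#' @export
read_classification <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[1:2] <- c("region", "class")
  df$region <- as.character(df$region)
  structure(df, class = c("map_classification", "data.frame"))
}
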