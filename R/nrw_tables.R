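#' Published NRW life-expectancy analysis tables
#'
#' The 1990-2010 North Rhine-Westphalia life-expectancy analysis published
#' its fitted summaries but not the underlying district-level data.  These
#' helpers load the published tables shipped with the package as plain-text
#' CSV: the model-evaluation sweep over J = 1..10 (slope, variance and both
#' BIC variants, per gender), the J = 7 mixing weights and intercepts, and
#' the per-district MAP classifications with their full posterior rows and
#' the rural(0)/urban(1) indicator.
#'
#' @param gender `"men"` or `"women"`.
#' @return `nrw_model_sweep()`: a data frame with one row per J.
#'   `nrw_classification()`: a data frame with columns `Region`, `Name`,
#'   `Urban`, `Class`, `e1..e7`.  `nrw_mixture_params()`: a
#'   [mixture_params()] object combining the gender's J = 7 weights and
#'   intercepts with its common slope and variance (printed weights are
#'   renormalised to sum exactly to one).
#' @name nrw_tables
NULL

nrw_file <- function(name) {
  path <- system.file("extdata", name, package = "levelmix")
  if (!nzchar(path)) stop("bundled table not found: ", name, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname nrw_tables
#' @export
nrw_model_sweep <- function() nrw_file("nrw_model_sweep.csv")

#' @rdname nrw_tables
#' @export
nrw_classification <- function(gender = c("men", "women")) {
  gender <- match.arg(gender)
  nrw_file(paste0("nrw_map_", gender, ".csv"))
}

#' @rdname nrw_tables
#' @export
nrw_mixture_params <- function(gender = c("men", "women")) {
  gender <- match.arg(gender)
  cp <- nrw_file("nrw_cluster_params.csv")
  sw <- nrw_model_sweep()
  row7 <- sw[sw$J == 7, ]
  p <- cp[[paste0("p_", gender)]]
  mixture_params(weights = p / sum(p),   # printed weights sum to 0.9999/1.0001
                 intercepts = cp[[paste0("alpha_", gender)]],
                 slope = row7[[paste0("beta_", gender)]],
                 sigma2 = row7[[paste0("sigma2_", gender)]])
}
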