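#' Maximum-posterior (MAP) classification
#'
#' Assigns each region to the component with the largest posterior
#' membership probability; exact ties are broken toward the smaller
#' component index so that the rule is deterministic.  Component indices
#' follow the ascending-intercept ordering of the fit.
#'
#' @param x A `"growth_mixture_fit"` or an n x J posterior matrix with rows
#'   summing to 1 (row names are taken as region identifiers).
#' @return Object of class `"map_classification"`: a data frame with
#'   columns `region`, `class` and the posterior columns `e1..eJ`.
#' @export
map_classify <- function(x) {
  e <- if (inherits(x, "growth_mixture_fit")) x$posterior else as.matrix(x)
  if (any(e < -1e-12) || any(abs(rowSums(e) - 1) > 1e-6))
    stop("posterior rows must be non-negative and sum to 1", call. = FALSE)
  regions <- rownames(e)
  if (is.null(regions)) regions <- as.character(seq_len(nrow(e)))
  cls <- apply(e, 1L, which.max)        # which.max: first maximum wins
  out <- data.frame(region = regions, class = as.integer(cls),
                    stringsAsFactors = FALSE, row.names = NULL)
  ep <- as.data.frame(e, row.names = NULL)
  names(ep) <- paste0("e", seq_len(ncol(e)))
  out <- cbind(out, ep)
  structure(out, class = c("map_classification", "data.frame"))
}

#' Cross-classify MAP classes against a binary covariate
#'
#' Builds the 2 x J contingency table of a binary region-level covariate
#' (rows: 0 then 1) against the MAP classes (columns 1..J).
#'
#' @param classification A [map_classify()] result (or any data frame with
#'   `region` and `class` columns).
#' @param covariate Named 0/1 vector (names = regions) or an unnamed vector
#'   aligned with the classification rows; a `"growth_panel"` with a
#'   covariate is also accepted.
#' @param J Number of classes for the column range; defaults to the number
#'   of posterior columns if present, else `max(class)`.
#' @return A 2 x J integer matrix of class `"table"` with dimnames
#'   `covariate` (0/1) and `class`.
#' @export
contingency_by_covariate <- function(classification, covariate, J = NULL) {
  if (inherits(covariate, "growth_panel")) covariate <- covariate$covariate
  if (is.null(covariate))
    stop("covariate is required but absent", call. = FALSE)
  cls <- classification$class
  regions <- classification$region
  if (!is.null(names(covariate))) {
    miss <- setdiff(regions, names(covariate))
    if (length(miss))
      stop("covariate missing for region(s): ",
           paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
    covariate <- covariate[regions]
  } else if (length(covariate) != length(cls)) {
    stop("covariate length does not match the classification", call. = FALSE)
  }
  if (anyNA(covariate))
    stop("covariate contains missing values", call. = FALSE)
  if (is.null(J)) {
    post <- grep("^e[0-9]+$", names(classification))
    J <- if (length(post)) length(post) else max(cls)
  }
  tab <- table(covariate = factor(covariate, levels = c(0, 1)),
               class = factor(cls, levels = seq_len(J)))
  tab
}

#' Pearson chi-square test of independence
#'
#' Classic Pearson statistic sum (O - E)^2 / E with expected counts from
#' the product of margins, no continuity correction and no pooling of
#' sparse cells.  Cells whose expected count is exactly zero (a zero row or
#' column margin) are excluded with a warning, and the degrees of freedom
#' count only the non-degenerate rows and columns.
#'
#' @param table A 2-way contingency table (matrix of non-negative counts).
#' @return A list with `statistic`, `df`, `p.value` and `expected`.
#' @export
pearson_chi_square <- function(table) {
  O <- as.matrix(table)
  if (length(O) == 0 || sum(O) <= 0)
    stop("contingency table must have a positive grand total", call. = FALSE)
  if (any(O < 0)) stop("counts must be non-negative", call. = FALSE)
  rs <- rowSums(O); cs <- colSums(O)
  if (any(rs == 0) || any(cs == 0))
    warning("margin(s) with zero total excluded from the statistic",
            call. = FALSE)
  keep_r <- rs > 0; keep_c <- cs > 0
  O <- O[keep_r, keep_c, drop = FALSE]
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  stat <- sum((O - E)^2 / E)
  df <- (nrow(O) - 1L) * (ncol(O) - 1L)
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df = df, lower.tail = FALSE),
       expected = E)
}

#' Concordance of two classifications of the same regions
#'
#' Pairs up two MAP classifications (for example, the men's and women's
#' analyses of the same districts) into a J x J table of joint class
#' counts, plus the per-region pair list behind it.
#'
#' @param classes_a,classes_b [map_classify()] results over the same region
#'   set.
#' @return A list with `table` (J_a x J_b count matrix) and `pairs` (data
#'   frame `region`, `class_a`, `class_b`).
#' @export
cross_classification <- function(classes_a, classes_b) {
  if (!setequal(classes_a$region, classes_b$region))
    stop("the two classifications cover different region sets",
         call. = FALSE)
  b <- classes_b[match(classes_a$region, classes_b$region), ]
  Ja <- max(classes_a$class); Jb <- max(b$class)
  tab <- table(class_a = factor(classes_a$class, levels = seq_len(Ja)),
               class_b = factor(b$class, levels = seq_len(Jb)))
  pairs <- data.frame(region = classes_a$region,
                      class_a = classes_a$class, class_b = b$class,
                      stringsAsFactors = FALSE)
  list(table = tab, pairs = pairs)
}
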