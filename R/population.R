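#' Two-sample sex comparison of a feature
#'
#' Pooled-variance two-sample t-test of a user-level feature between males
#' (sex = 0) and females (sex = 1), with df = n_total - 2. The reported t
#' is for the male-minus-female difference.
#'
#' @param data user-level data frame with \code{sex} and the response.
#' @param response name of the response column.
#' @return list with \code{t}, \code{df}, \code{p}, and per-group means
#'   \code{mean_male}, \code{mean_female}.
#' @export
sex_ttest <- function(data, response) {
  v <- data[[response]]
  keep <- !is.na(v) & !is.na(data$sex)
  v <- v[keep]; s <- data$sex[keep]
  if (sum(s == 0) < 2 || sum(s == 1) < 2)
    stop("need at least 2 users of each sex")
  tt <- stats::t.test(v[s == 0], v[s == 1], var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_male = mean(v[s == 0]), mean_female = mean(v[s == 1]))
}

#' Within-age versus between-age variability
#'
#' Decomposes a feature's spread into the mean within-age standard
#' deviation (SD across users at each age, averaged over ages) and the
#' between-age SD (SD of the per-age means). Ages at and above
#' \code{pool_from} (default 78, where the reference population thins to
#' two or fewer users per year) are pooled into a single bin. Sexes are
#' pooled by default; \code{split_sex = TRUE} returns one decomposition per
#' sex.
#'
#' @param data user-level data frame with \code{age} (and \code{sex} when
#'   splitting) and the response.
#' @param response name of the response column.
#' @param pool_from ages >= this value form one bin.
#' @param split_sex compute separately per sex?
#' @return list with \code{between_sd}, \code{within_sd_mean} and
#'   \code{n_bins} (or a named list of such lists when splitting by sex).
#' @export
variance_decomposition <- function(data, response, pool_from = 78,
                                   split_sex = FALSE) {
  if (split_sex) {
    return(lapply(
      stats::setNames(c(0, 1), c("male", "female")),
      function(s) variance_decomposition(data[data$sex == s, , drop = FALSE],
                                         response, pool_from)))
  }
  v <- data[[response]]
  keep <- !is.na(v) & !is.na(data$age)
  v <- v[keep]
  bin <- pmin(data$age[keep], pool_from)
  if (length(unique(bin)) < 2) stop("need at least 2 age bins")
  within <- tapply(v, bin, stats::sd)
  means <- tapply(v, bin, mean)
  list(between_sd = stats::sd(means),
       within_sd_mean = mean(within, na.rm = TRUE),
       n_bins = length(means))
}

#' Cross-feature correlation
#'
#' Pearson correlation and simple-regression slope of one feature on
#' another across users (e.g. beta power on peak alpha frequency).
#'
#' @param data user-level data frame.
#' @param x,y names of the predictor and response columns.
#' @return list with \code{r}, \code{slope} (of y on x), \code{p} (of the
#'   correlation) and \code{n} (complete pairs).
#' @export
feature_correlation <- function(data, x, y) {
  xv <- data[[x]]; yv <- data[[y]]
  keep <- !is.na(xv) & !is.na(yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
    stop("zero variance in '", if (stats::sd(xv) == 0) x else y, "'")
  ct <- stats::cor.test(xv, yv)
  list(r = unname(ct$estimate),
       slope = unname(stats::coef(stats::lm(yv ~ xv))[2]),
       p = ct$p.value, n = length(xv))
}

#' Five-number distribution summary with adjacent values
#'
#' Median and quartiles plus the lower and upper adjacent values: the most
#' extreme observations inside the Tukey fences Q1 - 1.5 IQR and
#' Q3 + 1.5 IQR. These are the summary statistics drawn by a Tukey
#' box/violin plot. Quartiles are medians of the lower and upper halves of
#' the sorted sample, excluding the middle observation when n is odd (so
#' 1..7 gives Q1 = 2, Q3 = 6).
#'
#' @param values numeric vector (at least one finite value).
#' @return named numeric vector: \code{median}, \code{q1}, \code{q3},
#'   \code{lower_adjacent}, \code{upper_adjacent}.
#' @export
summarize_distribution <- function(values) {
  values <- sort(values[is.finite(values)])
  if (length(values) == 0) stop("no finite values")
  n <- length(values)
  med <- stats::median(values)
  if (n == 1) {
    q1 <- q3 <- values
  } else {
    q1 <- stats::median(values[seq_len(floor(n / 2))])
    q3 <- stats::median(values[seq(ceiling(n / 2) + 1L, n)])
  }
  iqr <- q3 - q1
  inside <- values[values >= q1 - 1.5 * iqr & values <= q3 + 1.5 * iqr]
  c(median = med, q1 = q1, q3 = q3,
    lower_adjacent = min(inside), upper_adjacent = max(inside))
}
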