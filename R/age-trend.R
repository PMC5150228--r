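#' Significance markers
#'
#' Maps p-values to the star convention used in the coefficient tables:
#' \code{*} p < 0.05, \code{**} p < 0.01, \code{***} p < 0.001,
#' \code{****} p < 0.0001.
#'
#' @param p numeric vector of p-values.
#' @return character vector of markers.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) "" else if (pi < 1e-4) "****" else if (pi < 1e-3) "***"
    else if (pi < 1e-2) "**" else if (pi < 0.05) "*" else ""
  }, character(1))
}

#' Aggregate user-level features into (age, sex) cells
#'
#' Computes the mean response and user count for every (age, sex) cell.
#' Users with a missing response (for example no detectable alpha peak) are
#' dropped first, so cell weights automatically reflect the number of users
#' actually contributing to that feature.
#'
#' @param data user-level data frame with columns \code{age}, \code{sex}
#'   and the response.
#' @param response name of the response column.
#' @return data frame with columns \code{age}, \code{sex}, \code{value}
#'   (cell mean) and \code{n} (cell weight).
#' @export
aggregate_cells <- function(data, response) {
  v <- data[[response]]
  if (is.null(v)) stop("no column '", response, "' in data")
  keep <- !is.na(v) & !is.na(data$age) & !is.na(data$sex)
  data <- data[keep, , drop = FALSE]
  if (nrow(data) == 0) stop("no usable observations for response '", response, "'")
  key <- interaction(data$age, data$sex, drop = TRUE)
  agg <- data.frame(
    age = as.numeric(tapply(data$age, key, function(x) x[1])),
    sex = as.numeric(tapply(data$sex, key, function(x) x[1])),
    value = as.numeric(tapply(data[[response]], key, mean)),
    n = as.integer(tapply(data[[response]], key, length))
  )
  agg[order(agg$age, agg$sex), ]
}

#' Weighted age-trend regression on cell means
#'
#' Fits the population age-trend model of one spectral feature: weighted
#' least squares on per-(age, sex) cell means with weights equal to cell
#' counts, with centred age (default 42 years), quadratic age, sex
#' (male = 0, female = 1) and the two age-by-sex interactions:
#'
#' \deqn{y = b_0 + b_1 a + b_2 a^2 + b_3 s + b_4 a s + b_5 a^2 s}
#'
#' with a = age - 42. The coefficient vector is algebraically identical to
#' ordinary least squares on the un-aggregated user-level rows; only R^2
#' differs (cell averaging removes within-age variance, so the cell-level
#' R^2 is higher). The intercept is the predicted value for a male at the
#' centring age; the sex coefficient is the female-male difference there.
#'
#' If the sex interactions are significant (by default a joint F-test of
#' the two interaction terms at \code{refit_alpha}; set
#' \code{refit_trigger = "either"} to trigger on either individual
#' coefficient instead - note the either-rule fires on roughly twice
#' \code{refit_alpha} of null data), separate age + age^2 models are
#' refitted per sex; a sex with fewer than 4 cells is skipped with a
#' warning.
#'
#' @param data user-level data frame with columns \code{age}, \code{sex}
#'   and the response.
#' @param response name of the response column.
#' @param center_age centring age in years.
#' @param refit_alpha significance level of the refit trigger.
#' @param refit_trigger \code{"joint"} (F-test of both interactions) or
#'   \code{"either"} (either coefficient's t-test).
#' @return an object of class \code{age_trend_fit} with
#'   \code{print}, \code{summary}, \code{coef}, \code{predict},
#'   \code{residuals}, \code{fitted} and \code{plot} methods. Components
#'   include \code{coefficients} (the coefficient table with standard
#'   errors, cell-level-df p-values and stars), \code{r_squared},
#'   \code{interaction_p}, \code{sex_fits} and \code{cells}.
#' @examples
#' prof <- sample_cohort(cohort_config(n_users = 400, seed = 7))
#' prof$peak <- simulate_user_features(
#'   prof, c(9.54, -0.019, 0, 0.06, 0, 0), noise_sd = 0.8)
#' fit <- fit_age_trend(prof, "peak")
#' coef(fit)["age_c"]
#' @export
fit_age_trend <- function(data, response, center_age = 42,
                          refit_alpha = 0.05,
                          refit_trigger = c("joint", "either")) {
  refit_trigger <- match.arg(refit_trigger)
  cells <- aggregate_cells(data, response)
  cells$age_c <- cells$age - center_age
  cells$age_c2 <- cells$age_c^2
  terms_full <- c("(Intercept)", "age_c", "age_c2", "sex", "age_c:sex", "age_c2:sex")
  if (nrow(cells) <= length(terms_full))
    stop("need more (age, sex) cells than model terms")
  fit <- stats::lm(value ~ age_c + age_c2 + sex + age_c:sex + age_c2:sex,
                   data = cells, weights = n)
  if (anyNA(stats::coef(fit))) {
    dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("design matrix is rank deficient; collinear term(s): ",
         paste(dropped, collapse = ", "))
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  coef_table <- data.frame(
    term = rownames(ct), estimate = ct[, 1], se = ct[, 2],
    p = ct[, 4], stars = significance_stars(ct[, 4]),
    row.names = NULL, stringsAsFactors = FALSE)

  reduced <- stats::lm(value ~ age_c + age_c2 + sex, data = cells, weights = n)
  p_joint <- stats::anova(reduced, fit)[2, "Pr(>F)"]
  p_each <- ct[c("age_c:sex", "age_c2:sex"), 4]
  triggered <- if (refit_trigger == "joint") p_joint < refit_alpha
               else any(p_each < refit_alpha)

  sex_fits <- NULL
  if (triggered) {
    sex_fits <- list()
    for (s in c(male = 0, female = 1)) {
      sub <- cells[cells$sex == s, , drop = FALSE]
      label <- names(which(c(male = 0, female = 1) == s))
      if (nrow(sub) < 4) {
        warning("fewer than 4 cells for ", label, "; per-sex refit skipped")
        next
      }
      sfit <- stats::lm(value ~ age_c + age_c2, data = sub, weights = n)
      sct <- summary(sfit)$coefficients
      sex_fits[[label]] <- data.frame(
        term = rownames(sct), estimate = sct[, 1], se = sct[, 2], p = sct[, 4],
        stars = significance_stars(sct[, 4]),
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }

  structure(list(
    response = response, center_age = center_age,
    coefficients = coef_table, r_squared = sm$r.squared,
    interaction_p = c(joint = p_joint, p_each),
    refit_trigger = refit_trigger, refit_alpha = refit_alpha,
    refit_triggered = triggered, sex_fits = sex_fits,
    cells = cells, n_cells = nrow(cells), n_users = sum(cells$n),
    df_residual = fit$df.residual, fit = fit,
    call = match.call()
  ), class = "age_trend_fit")
}

#' @export
coef.age_trend_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
fitted.age_trend_fit <- function(object, ...) stats::fitted(object$fit)

#' @export
residuals.age_trend_fit <- function(object, ...) stats::residuals(object$fit)

#' @rdname fit_age_trend
#' @param object,x an \code{age_trend_fit}.
#' @param newdata data frame with columns \code{age} and \code{sex}.
#' @param ... unused.
#' @export
predict.age_trend_fit <- function(object, newdata, ...) {
  newdata$age_c <- newdata$age - object$center_age
  newdata$age_c2 <- newdata$age_c^2
  stats::predict(object$fit, newdata = newdata)
}

#' @export
print.age_trend_fit <- function(x, ...) {
  cat(sprintf("Age-trend WLS fit of '%s' (age centred at %g years)\n",
              x$response, x$center_age))
  cat(sprintf("  %d users in %d (age, sex) cells; R^2 = %.3f\n",
              x$n_users, x$n_cells, x$r_squared))
  est <- stats::setNames(x$coefficients$estimate, x$coefficients$term)
  print(round(est, 5))
  if (x$refit_triggered)
    cat("  sex interaction significant; per-sex refits available via summary()\n")
  invisible(x)
}

#' @export
summary.age_trend_fit <- function(object, ...) {
  structure(object, class = c("summary.age_trend_fit", class(object)))
}

#' @export
print.summary.age_trend_fit <- function(x, ...) {
  cat(sprintf("Age-trend WLS fit of '%s'\n", x$response))
  cat(sprintf("Cells: %d (age, sex) means, weights = user counts (%d users)\n",
              x$n_cells, x$n_users))
  tab <- x$coefficients
  tab$estimate <- signif(tab$estimate, 6)
  tab$se <- signif(tab$se, 4)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("R^2 = %.4f; residual df = %d (cell level)\n",
              x$r_squared, x$df_residual))
  cat(sprintf("Sex-interaction p (joint F) = %.4g; refit %s\n",
              x$interaction_p[["joint"]],
              if (x$refit_triggered) "triggered" else "not triggered"))
  if (!is.null(x$sex_fits)) {
    for (s in names(x$sex_fits)) {
      cat("Per-sex fit (", s, "):\n", sep = "")
      print(x$sex_fits[[s]], row.names = FALSE)
    }
  }
  cat("Stars: * p<0.05, ** p<0.01, *** p<0.001, **** p<0.0001\n")
  invisible(x)
}

#' @rdname fit_age_trend
#' @export
plot.age_trend_fit <- function(x, ...) {
  cells <- x$cells
  pch <- ifelse(cells$sex == 1, 21, 19)
  graphics::plot(cells$age, cells$value, cex = 0.4 + sqrt(cells$n) / 3,
                 pch = pch, xlab = "age (years)", ylab = x$response, ...)
  ages <- seq(min(cells$age), max(cells$age), length.out = 200)
  for (s in unique(cells$sex)) {
    pred <- predict(x, data.frame(age = ages, sex = s))
    graphics::lines(ages, pred, lty = if (s == 1) 2 else 1)
  }
  graphics::legend("topright", legend = c("male", "female"),
                   pch = c(19, 21), lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Omnibus task-by-channel gating model
#'
#' User-level linear model of one feature across tasks and channels with
#' centred age, quadratic age, sex and all interactions up to the four-way
#' age-by-sex-by-task-by-channel term (treatment coding). Used only to
#' check whether task and channel interact with the demographic terms -
#' which justifies fitting each channel and task separately - not for
#' coefficient reporting.
#'
#' @param data long-format user-level data frame with columns \code{age},
#'   \code{sex}, \code{task}, \code{channel} and the response.
#' @param response name of the response column.
#' @param center_age centring age in years.
#' @return the \code{\link[stats]{anova}} table of the fitted model.
#' @export
fit_omnibus <- function(data, response, center_age = 42) {
  data <- data[!is.na(data[[response]]), , drop = FALSE]
  data$age_c <- data$age - center_age
  data$age_c2 <- data$age_c^2
  data$task <- factor(data$task)
  data$channel <- factor(data$channel)
  data$.y <- data[[response]]
  fit <- stats::lm(.y ~ (age_c + age_c2) * sex * task * channel, data = data)
  stats::anova(fit)
}
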