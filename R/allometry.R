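#' Log10-log10 ordinary least squares scaling fit
#'
#' Fits `log10(y) = slope * log10(x) + intercept` by OLS — the standard
#' allometric scaling model. 95% confidence intervals for slope and
#' intercept use the t distribution with n - 2 degrees of freedom; the
#' p-value is the two-sided t test of the slope against zero.
#'
#' @param x,y Positive numeric vectors of equal length, n >= 3.
#' @return A `scaling_fit`: list with `slope`, `intercept`, `slope_ci`
#'   (length 2), `intercept_ci`, `r_squared`, `p_value`, `n`,
#'   `transform = "log10-log10"`, and the underlying `lm` object.
#' @seealso [fit_through_origin()], [classify_allometry()], [tidy.scaling_fit()]
#' @export
fit_loglog <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3L) {
    stop("need at least 3 observations for a log-log fit", call. = FALSE)
  }
  if (any(x <= 0) || any(y <= 0)) {
    stop("domain error: log-log fit requires strictly positive values",
         call. = FALSE)
  }
  lx <- log10(x)
  ly <- log10(y)
  fit <- stats::lm(ly ~ lx)
  sf <- summary(fit)
  ci <- stats::confint(fit, level = 0.95)
  new_scaling_fit(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    slope_ci = unname(ci[2L, ]),
    intercept_ci = unname(ci[1L, ]),
    r_squared = sf$r.squared,
    p_value = unname(sf$coefficients[2L, 4L]),
    n = length(x),
    transform = "log10-log10",
    lm = fit
  )
}

#' Raw-scale regression through the origin
#'
#' Fits `y = slope * x` with no intercept on the raw (unlogged) scale, so
#' the slope acts as a single multiplicative expansion factor converting x
#' into y. Closed form: slope = sum(xy) / sum(x^2).
#'
#' @param x,y Numeric vectors, n >= 2.
#' @return A `scaling_fit` with `transform = "raw-through-origin"`;
#'   `intercept` is exactly 0 and `intercept_ci` is `NA`.
#' @export
fit_through_origin <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (all(x == 0)) {
    stop("degenerate input: all x are zero", call. = FALSE)
  }
  fit <- stats::lm(y ~ x + 0)
  sf <- summary(fit)
  ci <- stats::confint(fit, level = 0.95)
  new_scaling_fit(
    slope = unname(stats::coef(fit)[1L]),
    intercept = 0,
    slope_ci = unname(ci[1L, ]),
    intercept_ci = c(NA_real_, NA_real_),
    r_squared = sf$r.squared,
    p_value = unname(sf$coefficients[1L, 4L]),
    n = length(x),
    transform = "raw-through-origin",
    lm = fit
  )
}

new_scaling_fit <- function(slope, intercept, slope_ci, intercept_ci,
                            r_squared, p_value, n, transform, lm = NULL) {
  structure(
    list(slope = slope, intercept = intercept, slope_ci = slope_ci,
         intercept_ci = intercept_ci, r_squared = r_squared,
         p_value = p_value, n = n, transform = transform, lm = lm),
    class = "scaling_fit"
  )
}

#' Construct a scaling fit from published coefficients
#'
#' Builds a `scaling_fit` directly from slope and intercept so published
#' predictive equations can be used for prediction without refitting.
#'
#' @param slope,intercept Coefficients on the log10-log10 scale.
#' @param n Sample size behind the coefficients, if known.
#' @return A `scaling_fit` (CIs, r^2 and p are `NA`).
#' @export
scaling_fit <- function(slope, intercept, n = NA_integer_) {
  new_scaling_fit(slope, intercept, c(NA_real_, NA_real_),
                  c(NA_real_, NA_real_), NA_real_, NA_real_, n,
                  "log10-log10")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit> %s: slope %.4g, intercept %.4g (n = %s)\n",
              x$transform, x$slope, x$intercept, x$n))
  if (!is.na(x$slope_ci[1])) {
    cat(sprintf("  slope 95%% CI [%.4g, %.4g], r^2 = %.4g, p = %.3g\n",
                x$slope_ci[1], x$slope_ci[2], x$r_squared, x$p_value))
  }
  invisible(x)
}

#' Tidy a scaling fit
#'
#' @param x A `scaling_fit`.
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate`, `conf.low`,
#'   `conf.high`.
#' @export
tidy.scaling_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    conf.low = c(x$intercept_ci[1], x$slope_ci[1]),
    conf.high = c(x$intercept_ci[2], x$slope_ci[2])
  )
}

#' One-row summary of a scaling fit
#'
#' @param x A `scaling_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `slope`, `intercept`, `r.squared`, `p.value`,
#'   `n`, `transform`.
#' @export
glance.scaling_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r.squared = x$r_squared, p.value = x$p_value, n = x$n,
                 transform = x$transform)
}

#' Serialize / deserialize scaling fits as JSON
#'
#' @param fit A `scaling_fit` (or named list of them) to write.
#' @param path Output / input path.
#' @return `read_scaling_fits()` returns a named list of `scaling_fit`s.
#' @export
write_scaling_fits <- function(fit, path) {
  fits <- if (inherits(fit, "scaling_fit")) list(fit = fit) else fit
  payload <- lapply(fits, function(f) {
    list(slope = f$slope, intercept = f$intercept, slope_ci = f$slope_ci,
         intercept_ci = f$intercept_ci, r2 = f$r_squared, p = f$p_value,
         n = f$n, transform = f$transform)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scaling_fits
#' @export
read_scaling_fits <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(payload, function(f) {
    new_scaling_fit(f$slope, f$intercept, as.numeric(f$slope_ci),
                    as.numeric(f$intercept_ci), f$r2, f$p, f$n, f$transform)
  })
}

#' Classify allometry from a slope confidence interval
#'
#' Trichotomy against a null slope: positive allometry if the 95% CI lies
#' entirely above the null, negative if entirely below, isometry otherwise.
#' The null is 1 for circumference-on-length scaling and 0 for
#' robustness-on-mass scaling.
#'
#' @param fit A `scaling_fit` with a slope CI.
#' @param null_slope The slope expected under geometric similarity.
#' @return A one-row tibble: `verdict` (`"positive"`, `"negative"`,
#'   `"isometry"`), `null_slope`, `conf.low`, `conf.high`.
#' @export
classify_allometry <- function(fit, null_slope) {
  ci <- if (inherits(fit, "scaling_fit")) fit$slope_ci else as.numeric(fit)
  if (anyNA(ci)) stop("fit has no slope confidence interval", call. = FALSE)
  verdict <- if (ci[1] > null_slope) "positive"
             else if (ci[2] < null_slope) "negative"
             else "isometry"
  tibble::tibble(verdict = verdict, null_slope = null_slope,
                 conf.low = ci[1], conf.high = ci[2])
}

#' Stylopod robustness
#'
#' Robustness of a limb bone is its minimum midshaft circumference divided
#' by its length (dimensionless; both in the same unit). Stouter bones have
#' higher values. Scaling analyses regress log10 circumference on log10
#' length (null slope 1) or log10 robustness on log10 predicted body mass
#' (null slope 0) via [fit_loglog()].
#'
#' @param circumference,length Positive numerics in the same length unit.
#' @return circumference / length.
#' @export
robustness <- function(circumference, length) {
  if (any(circumference <= 0) || any(length <= 0)) {
    stop("domain error: circumference and length must be positive",
         call. = FALSE)
  }
  circumference / length
}

#' Residual normality diagnostics for a scaling fit
#'
#' Pairs ordered residuals with standard-normal quantiles at Blom plotting
#' positions ((i - 3/8) / (n + 1/4)) for quantile-quantile comparison of
#' competing fits, and reports the adjusted Fisher-Pearson sample skewness.
#' An exact fit (all-zero residuals) reports skewness 0 by convention.
#'
#' @param fit A `scaling_fit` carrying its `lm` (from [fit_loglog()] or
#'   [fit_through_origin()]).
#' @return List with `qq` (tibble: `theoretical`, `residual`) and
#'   `skewness`.
#' @export
residual_diagnostics <- function(fit) {
  if (is.null(fit$lm)) stop("fit carries no residuals", call. = FALSE)
  r <- stats::residuals(fit$lm)
  n <- length(r)
  if (n < 4L) stop("need at least 4 residuals", call. = FALSE)
  i <- seq_len(n)
  qq <- tibble::tibble(
    theoretical = stats::qnorm((i - 3 / 8) / (n + 1 / 4)),
    residual = sort(r)
  )
  list(qq = qq, skewness = sample_skewness(r))
}

# adjusted Fisher-Pearson skewness; 0 when residuals are (numerically) constant
sample_skewness <- function(x) {
  n <- length(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s < .Machine$double.eps * max(1, abs(mean(x)))) return(0)
  g1 <- mean((x - mean(x))^3) / (sqrt(mean((x - mean(x))^2)))^3
  g1 * sqrt(n * (n - 1)) / (n - 2)
}
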