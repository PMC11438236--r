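#' Percent prediction error
#'
#' Per-specimen discrepancy between known and predicted body mass. Two
#' conventions are returned side by side because the literature uses both:
#' the absolute PPE `100 * |observed - predicted| / predicted`
#' (MASSTIMATE-style denominator), used for group means, and the signed
#' variant `100 * (predicted - observed) / observed`, whose sign maps
#' underestimation to negative values (left of zero on a density plot).
#'
#' @param observed_kg,predicted_kg Positive masses in kg (vectorised).
#' @return A tibble with columns `observed_kg`, `predicted_kg`, `ppe`
#'   (absolute, %), `signed_ppe` (%).
#' @examples
#' ppe(100, 125)  # ppe 20, signed_ppe +25
#' @export
ppe <- function(observed_kg, predicted_kg) {
  if (any(observed_kg <= 0) || any(predicted_kg <= 0)) {
    stop("domain error: masses must be positive", call. = FALSE)
  }
  tibble::tibble(
    observed_kg = observed_kg,
    predicted_kg = predicted_kg,
    ppe = 100 * abs(observed_kg - predicted_kg) / predicted_kg,
    signed_ppe = 100 * (predicted_kg - observed_kg) / observed_kg
  )
}

#' Sign-preserving log transform of signed PPE
#'
#' Compresses signed percent prediction errors for density plotting while
#' keeping zero at zero and the sign intact:
#' `sign(s) * log10(1 + |s|)`. A specimen predicted exactly maps to 0;
#' underestimates stay left of zero.
#'
#' @param signed_ppe Signed PPE values in percent.
#' @return Transformed values.
#' @export
logged_ppe <- function(signed_ppe) {
  sign(signed_ppe) * log10(1 + abs(signed_ppe))
}

#' Mean PPE with a 95% confidence interval
#'
#' Group precision summary: mean of the (absolute) PPE values with a
#' t-based 95% confidence half-width, `t(0.975, n-1) * sd / sqrt(n)`.
#'
#' @param ppe_values Numeric vector of absolute PPE values (%), n >= 2.
#' @return One-row tibble: `mean_ppe`, `ci95_halfwidth`, `n`.
#' @export
mean_ppe_ci <- function(ppe_values) {
  n <- length(ppe_values)
  if (n < 2L) stop("need at least 2 PPE values", call. = FALSE)
  tibble::tibble(
    mean_ppe = mean(ppe_values),
    ci95_halfwidth = stats::qt(0.975, n - 1) * stats::sd(ppe_values) / sqrt(n),
    n = n
  )
}

#' Subsampled mean-PPE distribution
#'
#' Repeatedly subsamples `subsample_n` PPE values without replacement and
#' summarises each draw with [mean_ppe_ci()]. Used to put a large
#' element-scaling sample on the same footing as a smaller volumetric
#' sample (the study design subsamples n = 266 down to n = 33, 1000
#' times).
#'
#' @param ppe_values Numeric vector of absolute PPE values (%).
#' @param subsample_n Subsample size, at most `length(ppe_values)`.
#' @param iterations Number of subsampling iterations.
#' @param seed Integer seed; the draw sequence is fully reproducible.
#' @return Tibble with one row per iteration: `iteration`, `mean_ppe`,
#'   `ci95_halfwidth`, `n`.
#' @export
subsample_mean_ppe <- function(ppe_values, subsample_n = 33, iterations = 1000,
                               seed = 1) {
  if (subsample_n > length(ppe_values)) {
    stop("subsample_n exceeds the number of PPE values", call. = FALSE)
  }
  if (iterations < 1L) stop("iterations must be >= 1", call. = FALSE)
  rng <- local_rng(seed)
  purrr::map_dfr(seq_len(iterations), function(i) {
    draw <- sample(ppe_values, subsample_n, replace = FALSE)
    dplyr::bind_cols(tibble::tibble(iteration = i), mean_ppe_ci(draw))
  })
}

# Scope a fixed seed to the calling function without disturbing the
# caller's RNG state.
local_rng <- function(seed, envir = parent.frame()) {
  withr::local_seed(as.integer(seed) %% .Machine$integer.max,
                    .local_envir = envir)
  invisible(seed)
}
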