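specimen_columns <- c("species", "clade", "known_mass_kg", "mch_volume_m3",
                      "humerus_circ_mm", "femur_circ_mm", "humerus_len_mm",
                      "femur_len_mm", "mass_provenance")

#' Load and validate a specimen table
#'
#' Reads the CSV specimen schema (`species`, `clade`, `known_mass_kg`,
#' `mch_volume_m3`, `humerus_circ_mm`, `femur_circ_mm`, `humerus_len_mm`,
#' `femur_len_mm`, `mass_provenance`; numeric fields may be empty where
#' unknown). Rows violating the invariants — no usable predictor at all, or
#' a non-positive numeric — are rejected with their line numbers.
#'
#' @param path CSV path. `species` and `clade` are required columns.
#' @return A validated tibble of specimen records.
#' @export
load_specimen_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  miss <- setdiff(c("species", "clade"), names(tbl))
  if (length(miss)) {
    stop("schema error: missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (cl in setdiff(specimen_columns, names(tbl))) {
    tbl[[cl]] <- if (cl == "mass_provenance") NA_character_ else NA_real_
  }
  tbl <- tbl[, specimen_columns]
  validate_specimens(tbl)
}

validate_specimens <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  num_cols <- c("known_mass_kg", "mch_volume_m3", "humerus_circ_mm",
                "femur_circ_mm", "humerus_len_mm", "femur_len_mm")
  bad_rows <- integer(0)
  msgs <- character(0)
  for (i in seq_len(nrow(tbl))) {
    vals <- unlist(tbl[i, intersect(num_cols, names(tbl))])
    if (any(!is.na(vals) & vals <= 0)) {
      bad_rows <- c(bad_rows, i)
      msgs <- c(msgs, sprintf("row %d (%s): non-positive numeric field", i,
                              tbl$species[i]))
    }
    has_circ <- !is.na(tbl$humerus_circ_mm[i]) && !is.na(tbl$femur_circ_mm[i])
    has_vol <- !is.na(tbl$mch_volume_m3[i])
    if (!has_circ && !has_vol) {
      bad_rows <- c(bad_rows, i)
      msgs <- c(msgs, sprintf(
        "row %d (%s): needs a hull volume or a circumference pair", i,
        tbl$species[i]))
    }
  }
  if (length(bad_rows)) {
    stop("validation error:\n  ", paste(msgs, collapse = "\n  "),
         call. = FALSE)
  }
  tbl
}

#' Calibrate the two predictive scaling equations on extant specimens
#'
#' Fits the volumetric equation, log10 known mass on log10 (hull volume x
#' density), on records carrying hull volumes, and the stylopodial
#' equation, log10 known mass on log10 combined (humerus + femur)
#' circumference, on records carrying both circumferences. Each fit needs
#' at least 3 usable records with known masses. A warning (not an error)
#' is raised if a fit rests on a single clade, since single-clade
#' calibrations transfer poorly across amniotes.
#'
#' @param records Extant specimen tibble (see [load_specimen_table()]).
#' @param density Assumed body density, kg/m^3.
#' @return A `calibration`: list with `mch_fit` and `ss_fit`
#'   (`scaling_fit`s) and `density`.
#' @export
calibrate <- function(records, density = 1000) {
  records <- tibble::as_tibble(records)
  mch_rows <- dplyr::filter(records, !is.na(.data$mch_volume_m3),
                            !is.na(.data$known_mass_kg))
  ss_rows <- dplyr::filter(records, !is.na(.data$humerus_circ_mm),
                           !is.na(.data$femur_circ_mm),
                           !is.na(.data$known_mass_kg))
  if (nrow(mch_rows) < 3) {
    stop("calibrate needs >= 3 records with hull volumes and known masses",
         call. = FALSE)
  }
  if (nrow(ss_rows) < 3) {
    stop("calibrate needs >= 3 records with circumference pairs and known ",
         "masses", call. = FALSE)
  }
  for (rows in list(mch_rows, ss_rows)) {
    if (length(unique(rows$clade)) == 1L) {
      warning("calibration sample contains a single clade (",
              rows$clade[1], "); cross-clade transfer is untested",
              call. = FALSE)
    }
  }
  mch_fit <- fit_loglog(mch_rows$mch_volume_m3 * density,
                        mch_rows$known_mass_kg)
  ss_fit <- fit_loglog(ss_rows$humerus_circ_mm + ss_rows$femur_circ_mm,
                       ss_rows$known_mass_kg)
  structure(list(mch_fit = mch_fit, ss_fit = ss_fit, density = density),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat("<calibration>\n volumetric (MCH): ")
  print(x$mch_fit)
  cat(" stylopodial (SS): ")
  print(x$ss_fit)
  invisible(x)
}

#' Estimate fossil body masses with both methods
#'
#' Applies the calibrated volumetric and stylopodial equations to fossil
#' records and tabulates both estimates with the SS/MCH ratio (the
#' method-discrepancy measure), sorted in descending ratio order. A
#' missing input leaves the corresponding estimate `NA` rather than
#' failing.
#'
#' @param records Fossil specimen tibble.
#' @param mch_fit,ss_fit `scaling_fit`s (e.g. from [calibrate()], or the
#'   published [mch_reference_fit()] / [ss_reference_fit()]).
#' @param density Assumed body density, kg/m^3.
#' @return Tibble: `species`, `log10_mch`, `mch_kg`, `log10_ss`, `ss_kg`,
#'   `ratio_ss_mch`, `mass_provenance`.
#' @export
estimate_fossils <- function(records, mch_fit = mch_reference_fit(),
                             ss_fit = ss_reference_fit(), density = 1000) {
  records <- tibble::as_tibble(records)
  out <- records |>
    dplyr::mutate(
      mch_kg = ifelse(is.na(.data$mch_volume_m3), NA_real_,
                      predict_mass_mch(dplyr::coalesce(.data$mch_volume_m3, 1),
                                       density, mch_fit)),
      ss_kg = ifelse(is.na(.data$humerus_circ_mm) | is.na(.data$femur_circ_mm),
                     NA_real_,
                     predict_mass_ss(dplyr::coalesce(.data$humerus_circ_mm, 1),
                                     dplyr::coalesce(.data$femur_circ_mm, 1),
                                     ss_fit)),
      log10_mch = log10(.data$mch_kg),
      log10_ss = log10(.data$ss_kg),
      ratio_ss_mch = .data$ss_kg / .data$mch_kg
    ) |>
    dplyr::select(dplyr::all_of(c("species", "log10_mch", "mch_kg", "log10_ss",
                                  "ss_kg", "ratio_ss_mch", "mass_provenance")))
  dplyr::arrange(out, dplyr::desc(.data$ratio_ss_mch))
}

#' Accuracy and precision report (PPE by method and group)
#'
#' Computes per-specimen percent prediction errors for both estimation
#' methods on the extant calibration records, then summarises precision as
#' mean absolute PPE with t-based 95% confidence intervals for the total
#' sample and per clade, and runs the subsampling comparison (the
#' stylopodial sample repeatedly subsampled to the volumetric sample size).
#'
#' @param records Extant specimen tibble with known masses.
#' @param mch_fit,ss_fit Calibrated `scaling_fit`s.
#' @param density Body density, kg/m^3.
#' @param subsample_n,iterations,seed Subsampling settings (defaults: the
#'   volumetric sample size, 1000 iterations).
#' @return List with `per_specimen` (tibble: species, clade, method,
#'   observed/predicted kg, ppe, signed_ppe, logged_ppe), `summary`
#'   (tibble: method, group, mean_ppe, ci95_halfwidth, n), and `subsample`
#'   (tibble from [subsample_mean_ppe()] on the stylopodial PPEs).
#' @export
accuracy_report <- function(records, mch_fit, ss_fit, density = 1000,
                            subsample_n = NULL, iterations = 1000, seed = 1) {
  records <- tibble::as_tibble(records)
  known <- dplyr::filter(records, !is.na(.data$known_mass_kg))
  mch_rows <- dplyr::filter(known, !is.na(.data$mch_volume_m3))
  ss_rows <- dplyr::filter(known, !is.na(.data$humerus_circ_mm),
                           !is.na(.data$femur_circ_mm))
  per_specimen <- dplyr::bind_rows(
    dplyr::bind_cols(
      mch_rows[, c("species", "clade")], method = "mch",
      ppe(mch_rows$known_mass_kg,
          predict_mass_mch(mch_rows$mch_volume_m3, density, mch_fit))),
    dplyr::bind_cols(
      ss_rows[, c("species", "clade")], method = "ss",
      ppe(ss_rows$known_mass_kg,
          predict_mass_ss(ss_rows$humerus_circ_mm, ss_rows$femur_circ_mm,
                          ss_fit)))
  ) |>
    dplyr::mutate(logged_ppe = logged_ppe(.data$signed_ppe))

  # singleton groups get a mean with an undefined CI rather than an error
  safe_ci <- function(v) {
    if (length(v) >= 2) {
      mean_ppe_ci(v)
    } else {
      tibble::tibble(mean_ppe = mean(v), ci95_halfwidth = NA_real_,
                     n = length(v))
    }
  }
  summarise_group <- function(d, group) {
    d |>
      dplyr::group_by(.data$method) |>
      dplyr::summarise(safe_ci(.data$ppe), .groups = "drop") |>
      dplyr::mutate(group = group, .after = "method")
  }
  summary <- dplyr::bind_rows(
    summarise_group(per_specimen, "total"),
    per_specimen |>
      dplyr::group_by(.data$clade) |>
      dplyr::group_map(~ summarise_group(.x, .y$clade)) |>
      dplyr::bind_rows()
  )
  ss_ppe <- per_specimen$ppe[per_specimen$method == "ss"]
  if (is.null(subsample_n)) subsample_n <- min(nrow(mch_rows), length(ss_ppe))
  subsample <- subsample_mean_ppe(ss_ppe, subsample_n = subsample_n,
                                  iterations = iterations, seed = seed)
  list(per_specimen = per_specimen, summary = summary, subsample = subsample)
}

#' Regression of stylopodial on volumetric fossil estimates
#'
#' Fits log10 stylopodial-estimated mass on log10 volumetric-estimated
#' mass across fossil taxa. A slope above 1 means the discrepancy between
#' methods grows with size.
#'
#' @param rows Output of [estimate_fossils()] (or any tibble with `mch_kg`
#'   and `ss_kg`).
#' @return A `scaling_fit`.
#' @export
method_discrepancy_fit <- function(rows) {
  cc <- dplyr::filter(rows, !is.na(.data$mch_kg), !is.na(.data$ss_kg))
  if (nrow(cc) < 3) {
    stop("need >= 3 fossils with both estimates", call. = FALSE)
  }
  fit_loglog(cc$mch_kg, cc$ss_kg)
}

#' Stylopod robustness allometry study
#'
#' Per group: (1) log10 combined circumference regressed on log10 combined
#' length, classified against a null slope of 1 (geometric similarity);
#' (2) log10 robustness (circumference/length) regressed on log10
#' volumetric-predicted body mass, classified against a null slope of 0.
#' Volumetric-predicted mass is used so fossils can be included.
#'
#' @param records Specimen tibble with circumference and length columns.
#' @param mch_fit Volumetric `scaling_fit` used to predict body mass from
#'   hull volume.
#' @param density Body density, kg/m^3.
#' @param by Grouping column, default `"clade"`.
#' @return Tibble: `group`, `analysis` (`circ_on_length` /
#'   `robustness_on_mass`), `n`, `slope`, `conf.low`, `conf.high`,
#'   `intercept`, `r.squared`, `p.value`, `verdict`.
#' @export
robustness_study <- function(records, mch_fit = mch_reference_fit(),
                             density = 1000, by = "clade") {
  records <- tibble::as_tibble(records)
  d <- records |>
    dplyr::filter(!is.na(.data$humerus_circ_mm), !is.na(.data$femur_circ_mm),
                  !is.na(.data$humerus_len_mm), !is.na(.data$femur_len_mm)) |>
    dplyr::mutate(
      comb_circ = .data$humerus_circ_mm + .data$femur_circ_mm,
      comb_len = .data$humerus_len_mm + .data$femur_len_mm,
      robust = robustness(.data$comb_circ, .data$comb_len),
      pred_mass = ifelse(
        is.na(.data$mch_volume_m3), NA_real_,
        predict_mass_mch(dplyr::coalesce(.data$mch_volume_m3, 1), density,
                         mch_fit)))
  one_fit <- function(x, y, null_slope, analysis, group) {
    f <- fit_loglog(x, y)
    dplyr::bind_cols(
      tibble::tibble(group = group, analysis = analysis, n = f$n,
                     slope = f$slope),
      classify_allometry(f, null_slope)[, c("conf.low", "conf.high", "verdict")],
      tibble::tibble(intercept = f$intercept, r.squared = f$r_squared,
                     p.value = f$p_value))
  }
  d |>
    dplyr::group_by(group = .data[[by]]) |>
    dplyr::group_map(function(g, key) {
      out <- one_fit(g$comb_len, g$comb_circ, 1, "circ_on_length", key$group)
      gm <- dplyr::filter(g, !is.na(.data$pred_mass))
      if (nrow(gm) >= 3) {
        out <- dplyr::bind_rows(
          out, one_fit(gm$pred_mass, gm$robust, 0, "robustness_on_mass",
                       key$group))
      }
      out
    }) |>
    dplyr::bind_rows()
}

#' Center-of-mass study across model variants
#'
#' For each model variant — the bare convex-hull models (`MCH`), segment
#' models inflated with expansion-factor tables (e.g. `MEF`, `SEF`), and
#' trunk-deflation variants (`trunk90`/`trunk80`/`trunk70`) — regresses
#' each positional metric (`pct_AG`, `dca_fl`) on log10 skull:tail volume
#' ratio within each clade group. Regressions are reported for every
#' group; the `significant` flag (two-sided slope t-test p < 0.05) marks
#' which regression lines would be drawn. Groups with fewer than 3 usable
#' models are skipped with a warning.
#'
#' @param models List of `body_model`s with landmarks.
#' @param expansion_tables Named list of `expansion_table`s; each becomes
#'   a variant (the names are the variant labels).
#' @param trunk_fractions Numeric vector of trunk deflation fractions.
#' @return List with `metrics` (per-specimen tibble: variant + the
#'   [com_metrics()] columns) and `regressions` (tibble: `group`,
#'   `variant`, `metric`, `n`, `slope`, `conf.low`, `conf.high`,
#'   `intercept`, `intercept_conf.low`, `intercept_conf.high`,
#'   `r.squared`, `p.value`, `significant`).
#' @export
com_study <- function(models,
                      expansion_tables = list(),
                      trunk_fractions = c(0.9, 0.8, 0.7)) {
  variants <- list(MCH = identity)
  for (nm in names(expansion_tables)) {
    tab <- expansion_tables[[nm]]
    variants[[nm]] <- local({
      tab <- tab
      function(m) apply_expansion(m, tab)
    })
  }
  for (fr in trunk_fractions) {
    nm <- paste0("trunk", round(100 * fr))
    variants[[nm]] <- local({
      fr <- fr
      function(m) deflate_trunk(m, fr)
    })
  }
  metrics <- purrr::imap_dfr(variants, function(fun, vname) {
    purrr::map_dfr(models, function(m) com_metrics(fun(m))) |>
      dplyr::mutate(variant = vname, .before = 1)
  })
  regressions <- metrics |>
    tidyr::pivot_longer(cols = c("pct_AG", "dca_fl"), names_to = "metric",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$log10_skull_tail), !is.na(.data$value)) |>
    dplyr::group_by(.data$clade, .data$variant, .data$metric) |>
    dplyr::group_map(function(g, key) {
      if (nrow(g) < 3) {
        warning("com_study: group ", key$clade, "/", key$variant, "/",
                key$metric, " has < 3 models; skipped", call. = FALSE)
        return(NULL)
      }
      # linear (not log-log) fit: the metrics can be <= 0
      fit <- stats::lm(value ~ log10_skull_tail, data = g)
      sf <- summary(fit)
      ci <- stats::confint(fit)
      p <- if (nrow(sf$coefficients) < 2 || is.na(sf$coefficients[2, 4])) {
        NA_real_
      } else {
        sf$coefficients[2, 4]
      }
      tibble::tibble(
        group = key$clade, variant = key$variant, metric = key$metric,
        n = nrow(g), slope = unname(stats::coef(fit)[2]),
        conf.low = ci[2, 1], conf.high = ci[2, 2],
        intercept = unname(stats::coef(fit)[1]),
        intercept_conf.low = ci[1, 1], intercept_conf.high = ci[1, 2],
        r.squared = sf$r.squared, p.value = p,
        significant = !is.na(p) && p < 0.05)
    }) |>
    dplyr::bind_rows()
  list(metrics = metrics, regressions = regressions)
}
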