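canonical_segments <- function() {
  limbs <- as.vector(outer(
    c("fore", "hind"),
    as.vector(outer(c("left", "right"), c("stylopod", "zeugopod", "autopod"),
                    paste, sep = "_")),
    paste, sep = "_"))
  c("skull", "neck", "trunk", "tail", limbs)
}

segment_vocabulary <- function() c(canonical_segments(), "sail")

is_valid_segment_name <- function(name) {
  name %in% segment_vocabulary() | grepl("^tail_sub_[0-9]+$", name)
}

#' Build a whole-body segment model
#'
#' Assembles per-segment hull volumes and centroids into a body model used
#' for mass, center-of-mass, and body-proportion computations. The standard
#' decomposition is 16 segments: skull, neck, trunk, tail, and stylopod /
#' zeugopod / autopod for each of the four limbs. A dorsal sail (as in
#' *Edaphosaurus* or *Dimetrodon*) is accepted as an additional optional
#' segment, and subdivided tails are supported as `tail_sub_1`,
#' `tail_sub_2`, ... whose volumes simply sum.
#'
#' @param segments A data frame with columns `name`, `volume` (m^3), `cx`,
#'   `cy`, `cz` (centroid, metres), and optionally `density` (kg/m^3,
#'   default 1000) and `expansion_factor` (default 1).
#' @param landmarks Optional list with `acetabulum` (xyz, m), `glenoid`
#'   (xyz, m), and `femur_length` (m); see [read_landmarks()]. Required for
#'   center-of-mass positional metrics, not for mass estimation.
#' @param clade One of `"mammal"`, `"crocodylian"`, `"other_reptile"`,
#'   `"fossil"`.
#' @param specimen Specimen identifier.
#' @param density Default segment density in kg/m^3 applied where the
#'   `density` column is absent. 1000 (water) is the standard assumption;
#'   measured whole-body densities span roughly 893 (horse) to 1080
#'   (crocodylian) kg/m^3.
#' @return A `body_model`: a tibble of segments with attributes `specimen`,
#'   `clade`, `landmarks`.
#' @examples
#' segs <- tibble::tibble(
#'   name = c("skull", "trunk", "tail"),
#'   volume = c(0.001, 0.006, 0.002),
#'   cx = c(0.5, 0.2, -0.3), cy = 0, cz = 0
#' )
#' m <- assemble_body(segs, clade = "fossil")
#' body_volume(m)       # 0.009
#' body_mass_direct(m)  # 9 kg at 1000 kg/m^3
#' @export
assemble_body <- function(segments, landmarks = NULL,
                          clade = c("mammal", "crocodylian", "other_reptile",
                                    "fossil"),
                          specimen = "specimen", density = 1000) {
  clade <- match.arg(clade)
  segments <- tibble::as_tibble(segments)
  req <- c("name", "volume", "cx", "cy", "cz")
  missing_cols <- setdiff(req, names(segments))
  if (length(missing_cols)) {
    stop("segments lack required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(segments) < 1L) stop("at least one segment is required", call. = FALSE)
  bad <- segments$name[!is_valid_segment_name(segments$name)]
  if (length(bad)) {
    stop("validation error: unknown segment name(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  non_tail <- segments$name[!grepl("^tail_sub_", segments$name)]
  if (anyDuplicated(non_tail)) {
    stop("validation error: duplicate segment name(s): ",
         paste(unique(non_tail[duplicated(non_tail)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(segments$volume <= 0)) {
    stop("validation error: segment volumes must be positive", call. = FALSE)
  }
  if (!"density" %in% names(segments)) segments$density <- density
  if (!"expansion_factor" %in% names(segments)) segments$expansion_factor <- 1
  if (any(segments$density <= 0)) {
    stop("validation error: segment densities must be positive", call. = FALSE)
  }
  if (any(segments$expansion_factor < 0)) {
    stop("validation error: expansion factors must be >= 0", call. = FALSE)
  }
  missing_canon <- setdiff(canonical_segments(),
                           c(segments$name,
                             if (any(grepl("^tail(_sub_[0-9]+)?$", segments$name))) "tail"))
  if (length(missing_canon)) {
    warning("model lacks ", length(missing_canon),
            " of the 16 canonical segments: ",
            paste(missing_canon, collapse = ", "), call. = FALSE)
  }
  if (!is.null(landmarks)) validate_landmarks(landmarks)
  structure(
    segments[, c("name", "volume", "cx", "cy", "cz", "density",
                 "expansion_factor")],
    specimen = specimen, clade = clade, landmarks = landmarks,
    class = c("body_model", class(segments))
  )
}

validate_landmarks <- function(lm) {
  if (!all(c("acetabulum", "glenoid", "femur_length") %in% names(lm))) {
    stop("landmarks need acetabulum, glenoid, femur_length", call. = FALSE)
  }
  if (length(lm$acetabulum) != 3L || length(lm$glenoid) != 3L) {
    stop("landmark points must be xyz triplets", call. = FALSE)
  }
  if (all(lm$acetabulum == lm$glenoid)) {
    stop("validation error: acetabulum and glenoid coincide", call. = FALSE)
  }
  if (lm$femur_length <= 0) {
    stop("validation error: femur_length must be positive", call. = FALSE)
  }
  invisible(lm)
}

#' Read landmark coordinates from JSON
#'
#' Expects `{"acetabulum": [x,y,z], "glenoid": [x,y,z], "femur_length_m": f}`.
#'
#' @param path Path to a JSON file.
#' @return A landmarks list as accepted by [assemble_body()].
#' @export
read_landmarks <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  lm <- list(acetabulum = as.numeric(j$acetabulum),
             glenoid = as.numeric(j$glenoid),
             femur_length = as.numeric(j$femur_length_m))
  validate_landmarks(lm)
}

model_landmarks <- function(model) attr(model, "landmarks")
model_clade <- function(model) attr(model, "clade")
model_specimen <- function(model) attr(model, "specimen")

#' Whole-body hull volume
#'
#' Exact sum of segment hull volumes. Expansion factors are deliberately
#' NOT applied here: this is the raw minimum-convex-hull body volume that
#' enters the volumetric mass prediction equation.
#'
#' @param model A `body_model`.
#' @return Volume in m^3.
#' @export
body_volume <- function(model) {
  stopifnot(inherits(model, "body_model"))
  sum(model$volume)
}

#' Direct (density-based) body mass
#'
#' Sum over segments of volume x expansion factor x density. With all
#' expansion factors 1 and a uniform 1000 kg/m^3 this is body volume in m^3
#' times 1000 — the baseline volumetric mass estimate.
#'
#' @param model A `body_model`.
#' @return Mass in kg.
#' @export
body_mass_direct <- function(model) {
  stopifnot(inherits(model, "body_model"))
  sum(model$volume * model$expansion_factor * model$density)
}

#' Average hull-to-skin expansion factors across reference specimens
#'
#' For each body segment, the expansion factor is the arithmetic mean over
#' reference specimens of skin volume divided by hull volume — the factor
#' that inflates a bare convex hull to an estimated fleshed volume.
#' Computed per reference group this yields mammal-specific (MEF) or
#' sauropsid-specific (SEF) tables.
#'
#' @param hull_volumes Data frame with columns `specimen`, `segment`,
#'   `volume` of convex-hull volumes.
#' @param skin_volumes Data frame with the same columns giving fleshed
#'   (skin) volumes for the same specimen-segment pairs.
#' @param label Table label, typically `"MEF"` or `"SEF"`.
#' @return An `expansion_table`: tibble with `segment`, `factor`, and a
#'   `label` attribute.
#' @export
compute_expansion_factors <- function(hull_volumes, skin_volumes,
                                      label = "EF") {
  hv <- tibble::as_tibble(hull_volumes)
  sv <- tibble::as_tibble(skin_volumes)
  joined <- dplyr::full_join(hv, sv, by = c("specimen", "segment"),
                             suffix = c("_hull", "_skin"))
  if (anyNA(joined$volume_hull) || anyNA(joined$volume_skin)) {
    stop("validation error: unpaired specimen-segment entries between hull ",
         "and skin tables", call. = FALSE)
  }
  if (any(joined$volume_hull <= 0) || any(joined$volume_skin <= 0)) {
    stop("validation error: volumes must be positive", call. = FALSE)
  }
  out <- joined |>
    dplyr::mutate(ratio = .data$volume_skin / .data$volume_hull) |>
    dplyr::group_by(.data$segment) |>
    dplyr::summarise(factor = mean(.data$ratio), .groups = "drop")
  new_expansion_table(out, label)
}

new_expansion_table <- function(tbl, label) {
  tbl <- tibble::as_tibble(tbl)[, c("segment", "factor")]
  if (any(tbl$factor <= 0)) {
    stop("validation error: expansion factors must be positive", call. = FALSE)
  }
  structure(tbl, label = label, class = c("expansion_table", class(tbl)))
}

#' Read an expansion-factor table from CSV or JSON
#'
#' CSV needs columns `segment`, `factor`; JSON needs fields `label` and
#' `factors` (an object mapping segment name to factor).
#'
#' @param path Path to the table.
#' @param label Label (`"MEF"`/`"SEF"`) for CSV input; JSON carries its own.
#' @return An `expansion_table`.
#' @export
read_expansion_table <- function(path, label = "EF") {
  if (tolower(tools::file_ext(path)) == "json") {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    new_expansion_table(
      tibble::tibble(segment = names(j$factors),
                     factor = as.numeric(unlist(j$factors))),
      label = j$label %||% label)
  } else {
    new_expansion_table(readr::read_csv(path, show_col_types = FALSE), label)
  }
}

#' Apply per-segment expansion factors to a body model
#'
#' Sets each segment's expansion factor from the table; segments absent
#' from the table keep factor 1. Expansion is modelled as uniform inflation
#' about the segment centroid, so centroids are unchanged and only
#' effective masses move.
#'
#' @param model A `body_model`.
#' @param table An `expansion_table` (see [compute_expansion_factors()]).
#' @return The updated `body_model`.
#' @export
apply_expansion <- function(model, table) {
  stopifnot(inherits(model, "body_model"))
  if (any(table$factor < 0)) {
    stop("validation error: negative expansion factor", call. = FALSE)
  }
  idx <- match(model$name, table$segment)
  fac <- ifelse(is.na(idx), 1, table$factor[idx])
  model$expansion_factor <- model$expansion_factor * fac
  model
}

#' Deflate the trunk segment
#'
#' Scales the trunk's effective volume to `fraction` of its convex-hull
#' volume (implemented as multiplying its expansion factor), emulating a
#' lower-density trunk. The study variants use 0.9, 0.8, and 0.7.
#'
#' @param model A `body_model` containing a `trunk` segment.
#' @param fraction A value in (0, 1].
#' @return The updated `body_model`.
#' @export
deflate_trunk <- function(model, fraction) {
  stopifnot(inherits(model, "body_model"))
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction <= 0 ||
      fraction > 1) {
    stop("validation error: fraction must be in (0, 1]", call. = FALSE)
  }
  i <- which(model$name == "trunk")
  if (!length(i)) {
    stop("validation error: model has no trunk segment", call. = FALSE)
  }
  model$expansion_factor[i] <- model$expansion_factor[i] * fraction
  model
}

#' Whole-body center of mass
#'
#' Mass-weighted mean of segment centroids with per-segment mass
#' volume x expansion factor x density. The result is a convex combination
#' of segment centroids; uniform rescaling of all densities leaves it
#' unchanged.
#'
#' @param model A `body_model`.
#' @return Length-3 numeric (metres).
#' @export
center_of_mass <- function(model) {
  stopifnot(inherits(model, "body_model"))
  m <- model$volume * model$expansion_factor * model$density
  total <- sum(m)
  if (total <= 0) {
    stop("degenerate input: total effective mass is zero", call. = FALSE)
  }
  c(sum(m * model$cx), sum(m * model$cy), sum(m * model$cz)) / total
}

#' Center-of-mass positional metrics
#'
#' Quantifies the cranio-caudal position of the center of mass with two
#' proxies: (1) `pct_AG`, the percentage cranial along the transect from
#' acetabulum to glenoid, and (2) `dca_fl`, the distance cranial of the
#' acetabulum divided by femur length (values of 1 or more have been read
#' as consistent with quadrupedal posture). The cranial direction is the
#' acetabulum-to-glenoid unit vector, so both metrics share one projected
#' distance `dca` and `pct_AG = 100 * dca / |AG|`. The body-proportion
#' covariate `log10_skull_tail` is log10 of skull volume over total tail
#' volume (all `tail`/`tail_sub_*` segments summed); it is `NA` when the
#' model lacks a skull or a tail.
#'
#' @param model A `body_model` with landmarks.
#' @return A one-row tibble: `specimen`, `clade`, `com_x/y/z`, `pct_AG`,
#'   `dca_fl`, `log10_skull_tail`.
#' @export
com_metrics <- function(model) {
  stopifnot(inherits(model, "body_model"))
  lm <- model_landmarks(model)
  if (is.null(lm)) {
    stop("landmarks are required for center-of-mass metrics", call. = FALSE)
  }
  com <- center_of_mass(model)
  ag <- lm$glenoid - lm$acetabulum
  ag_len <- sqrt(sum(ag^2))
  u <- ag / ag_len
  dca <- sum((com - lm$acetabulum) * u)
  skull_v <- sum(model$volume[model$name == "skull"])
  tail_v <- sum(model$volume[grepl("^tail(_sub_[0-9]+)?$", model$name)])
  ratio <- if (skull_v > 0 && tail_v > 0) log10(skull_v / tail_v) else NA_real_
  tibble::tibble(
    specimen = model_specimen(model),
    clade = model_clade(model),
    com_x = com[1], com_y = com[2], com_z = com[3],
    pct_AG = 100 * dca / ag_len,
    dca_fl = dca / lm$femur_length,
    log10_skull_tail = ratio
  )
}

#' @export
print.body_model <- function(x, ...) {
  cat(sprintf("<body_model> %s (%s): %d segments, volume %.6g m^3, mass %.6g kg\n",
              model_specimen(x), model_clade(x), nrow(x), body_volume(x),
              body_mass_direct(x)))
  NextMethod()
}
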