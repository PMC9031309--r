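# Immunoblot densitometry and degradation kinetics: band boxing with
# background subtraction, loading-control normalization, percent-of-control
# steady-state abundance, chase percent-remaining curves with SEM, free-GFP
# cleavage ratios and Welch-t fold-change comparisons.

#' Measure a boxed band on a blot scan
#'
#' Mean pixel intensity within the band box minus the mean within the
#' background box; the corrected value is floored at 0 (negative
#' densitometry is noise) and flagged when flooring occurred.
#'
#' @param image 2-D intensity matrix.
#' @param band_box,background_box `c(row_min, row_max, col_min, col_max)`,
#'   1-based inclusive, within the image.
#' @param loading_value Optional per-lane total-protein value (a.u.).
#' @param lane Optional lane identifier.
#' @return One-row tibble: `lane`, `band_mean`, `background_mean`,
#'   `corrected`, `floored`, `loading_value`.
#' @export
band_intensity <- function(image, band_box, background_box,
                           loading_value = NA_real_, lane = NA) {
  box_px <- function(b) {
    stopifnot(length(b) == 4L)
    if (b[1] > b[2] || b[3] > b[4]) stop("geometry error: empty box")
    if (b[1] < 1 || b[3] < 1 || b[2] > nrow(image) || b[4] > ncol(image)) {
      stop("geometry error: box outside image bounds")
    }
    image[b[1]:b[2], b[3]:b[4]]
  }
  band <- box_px(band_box)
  bg <- box_px(background_box)
  if (boxes_overlap(band_box, background_box)) {
    warning("band and background boxes overlap")
  }
  corrected <- mean(band) - mean(bg)
  floored <- corrected < 0
  if (floored) {
    warning("corrected intensity negative; floored at 0")
    corrected <- 0
  }
  tibble(lane = lane, band_mean = mean(band), background_mean = mean(bg),
         corrected = corrected, floored = floored,
         loading_value = loading_value)
}

boxes_overlap <- function(a, b) {
  a[1] <= b[2] && b[1] <= a[2] && a[3] <= b[4] && b[3] <= a[4]
}

#' Loading-corrected abundance relative to a reference lane
#'
#' `100 * (sample.corrected / sample.loading) / (reference.corrected /
#' reference.loading)` — the percent-of-control abundance after total-protein
#' loading correction. Invariant to common rescaling of a lane's band and
#' loading values.
#'
#' @param sample,reference One-row band measurements (see
#'   [band_intensity()]) or lists with `corrected` and `loading_value`.
#' @return Percent of reference (numeric scalar).
#' @examples
#' s <- list(corrected = 80, loading_value = 2)
#' r <- list(corrected = 100, loading_value = 1)
#' loading_normalize(s, r)  # 40
#' @export
loading_normalize <- function(sample, reference) {
  for (m in list(sample, reference)) {
    if (is.na(m$loading_value) || m$loading_value <= 0) {
      stop("loading_value must be positive for normalization")
    }
  }
  if (reference$corrected == 0) {
    stop("reference corrected intensity is 0; percent undefined")
  }
  100 * (sample$corrected / sample$loading_value) /
    (reference$corrected / reference$loading_value)
}

#' Percent-remaining chase curves
#'
#' Normalizes each replicate's (loading-corrected) band intensities to its
#' own t = 0 value — so t = 0 is exactly 100% in every replicate — and
#' summarizes across replicates with mean and SEM per timepoint. Replicates
#' whose t = 0 intensity is not positive are excluded with a warning.
#' Optional grouping columns (e.g. `treatment`, `construct`, `genotype`)
#' are preserved and summarized within.
#'
#' @param series Tibble with columns `replicate`, `timepoint`, and either
#'   `intensity` (already corrected) or `band_mean` + `background_mean`
#'   (corrected here, optionally divided by `loading_value` when present);
#'   plus optional grouping columns.
#' @param groups Character vector of grouping column names (default: the
#'   `treatment` column if present).
#' @return List of class `chase_series`: `percent` (per-replicate tibble
#'   with `percent_remaining`), `summary` (per group x timepoint:
#'   `mean_percent`, `sem`, `n`).
#' @export
chase_percent_remaining <- function(series,
                                    groups = intersect("treatment",
                                                       names(series))) {
  series <- as_tibble(series)
  if (!"intensity" %in% names(series)) {
    stopifnot(all(c("band_mean", "background_mean") %in% names(series)))
    series$intensity <- pmax(series$band_mean - series$background_mean, 0)
    if ("loading_value" %in% names(series)) {
      series$intensity <- series$intensity / series$loading_value
    }
  }
  stopifnot(all(c("replicate", "timepoint") %in% names(series)))
  if (!0 %in% series$timepoint) stop("t = 0 must be present")

  key_cols <- c(groups, "replicate")
  t0 <- series |>
    dplyr::filter(.data$timepoint == 0) |>
    dplyr::select(dplyr::all_of(key_cols), i0 = "intensity")
  pct <- dplyr::left_join(series, t0, by = key_cols)
  bad <- is.na(pct$i0) | pct$i0 <= 0
  if (any(bad)) {
    warning("replicate(s) without positive t = 0 intensity excluded")
    pct <- pct[!bad, , drop = FALSE]
  }
  pct$percent_remaining <- 100 * pct$intensity / pct$i0

  summary <- pct |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(groups, "timepoint")))) |>
    dplyr::summarise(
      mean_percent = mean(.data$percent_remaining),
      sem = if (dplyr::n() > 1L)
        stats::sd(.data$percent_remaining) / sqrt(dplyr::n()) else 0,
      n = dplyr::n(), .groups = "drop")
  structure(list(percent = pct, summary = summary), class = "chase_series")
}

#' Log-linear decay-rate fit on percent-remaining data
#'
#' Least-squares fit of `log(percent)` against time over the positive
#' percent-remaining values, returning the decay rate and `ln(2)/k`
#' half-life. The chase figures this pipeline feeds plot percent remaining
#' only; the fitted rate is an extension for parameter recovery and is
#' labeled as such in the output.
#'
#' @param chase A `chase_series` (from [chase_percent_remaining()]) or a
#'   tibble with `timepoint` and `percent_remaining`.
#' @param groups Grouping columns (default `treatment` if present).
#' @return Tibble per group: `k_per_hour`, `half_life_hours`, `r_squared`,
#'   `n_points`, `note`.
#' @export
fit_decay_rate <- function(chase, groups = NULL) {
  pct <- if (inherits(chase, "chase_series")) chase$percent else as_tibble(chase)
  if (is.null(groups)) groups <- intersect("treatment", names(pct))
  pct <- dplyr::filter(pct, .data$percent_remaining > 0)
  fit_one <- function(d) {
    fit <- stats::lm(log(percent_remaining) ~ timepoint, data = d)
    k <- -unname(stats::coef(fit)["timepoint"])
    tibble(k_per_hour = k,
           half_life_hours = ifelse(k > 0, log(2) / k, Inf),
           r_squared = summary(fit)$r.squared,
           n_points = nrow(d),
           note = "log-linear fit; extension beyond percent-remaining plots")
  }
  if (length(groups) == 0L) return(fit_one(pct))
  pct |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::group_modify(~ fit_one(.x)) |>
    dplyr::ungroup()
}

#' Free-GFP cleavage ratio
#'
#' Ratio of the corrected free-GFP breakdown-product band (the
#' vacuole-resistant fragment) over the corrected full-length fusion band —
#' a per-lane proxy for vacuolar delivery of the fusion.
#'
#' @param free_gfp,full_length Band measurements (rows from
#'   [band_intensity()]) or lists with a `corrected` field, or bare numbers.
#' @return Numeric ratio.
#' @export
cleavage_ratio <- function(free_gfp, full_length) {
  val <- function(x) if (is.numeric(x)) x else x$corrected
  free <- val(free_gfp); full <- val(full_length)
  if (is.na(free) || is.na(full)) stop("corrected values must be defined")
  if (full <= 0) stop("full-length corrected intensity must be positive")
  free / full
}

#' Steady-state fold change with Welch's t-test
#'
#' Fold change of group-b mean over group-a mean (e.g. t = 0 band
#' intensities of a deletion strain vs. its control), with Welch's
#' unequal-variance t-test on the raw intensities. When both groups have
#' zero variance the test is undefined; the fold change is still reported.
#'
#' @param group_a,group_b Numeric intensity vectors (n >= 2 each).
#' @return List: `fold_change`, `welch` (list `t`, `df`, `p`, or `NULL`
#'   when undefined), `tier` (significance symbol, `NA` when no test).
#' @export
steady_state_fold_change <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  fold <- mean(group_b) / mean(group_a)
  welch <- if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    message("both groups have zero variance; Welch test undefined")
    NULL
  } else {
    welch_t(group_a, group_b)
  }
  list(fold_change = fold, welch = welch,
       tier = if (is.null(welch)) NA_character_ else
         significance_tier(welch$p))
}
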