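# Seeded generators for immunoblot-style data: exponential-decay chase
# band series (translation-shutoff experiments) and rendered blot images
# with planted band amplitudes for the densitometry code.

#' Configuration for a simulated chase series
#'
#' Band intensity decays as `I0 * exp(-k * t)` under each treatment, with
#' multiplicative lognormal noise per measurement and a loading-control
#' value per lane.
#'
#' @param I0 Band intensity at t = 0 (a.u.).
#' @param decay_rates Named per-hour decay rate per treatment, all >= 0
#'   (e.g. `c(NT = 0, CHX = 0.35)`).
#' @param timepoints Sampling times in hours; must include 0.
#' @param loading_mean Loading-control lane value (a.u.).
#' @param background_mean Flat background level under each band (a.u.).
#' @param noise_cv Coefficient of variation of the band noise.
#' @param n_replicates Replicate chase experiments per treatment.
#' @param seed Integer seed.
#' @return List of class `chase_sim_config`.
#' @export
chase_sim_config <- function(I0 = 100,
                             decay_rates = c(CHX = 0.35),
                             timepoints = c(0, 1, 2, 4),
                             loading_mean = 100,
                             background_mean = 20,
                             noise_cv = 0.05,
                             n_replicates = 4,
                             seed = 1) {
  if (any(decay_rates < 0)) stop("parameter error: decay rates must be >= 0")
  if (!0 %in% timepoints) stop("timepoints must include 0")
  if (is.null(names(decay_rates))) {
    names(decay_rates) <- paste0("treatment", seq_along(decay_rates))
  }
  structure(list(I0 = I0, decay_rates = decay_rates,
                 timepoints = sort(timepoints),
                 loading_mean = loading_mean,
                 background_mean = background_mean,
                 noise_cv = noise_cv, n_replicates = n_replicates,
                 seed = as.integer(seed)),
            class = "chase_sim_config")
}

#' Simulate chase band-intensity series
#'
#' @param config A [chase_sim_config()].
#' @return List of class `chase_sim`: `measurements` (tibble: treatment,
#'   replicate, timepoint, band_mean, background_mean, loading_value —
#'   `band_mean` includes the background, as a densitometry box would
#'   measure it), `truth` (tibble: treatment, timepoint,
#'   percent_remaining_true), and `config`.
#' @examples
#' sim <- simulate_chase_series(chase_sim_config(decay_rates = c(CHX = log(2) / 2),
#'                                               noise_cv = 0))
#' # corrected intensity at t = 2 h is I0 / 2
#' @export
simulate_chase_series <- function(config) {
  stopifnot(inherits(config, "chase_sim_config"))
  rng <- local_seed(config$seed)
  grid <- tidyr::crossing(treatment = names(config$decay_rates),
                          replicate = seq_len(config$n_replicates),
                          timepoint = config$timepoints)
  k <- config$decay_rates[grid$treatment]
  signal <- config$I0 * exp(-k * grid$timepoint)
  if (config$noise_cv > 0) {
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    signal <- signal * stats::rlnorm(nrow(grid), -sdlog^2 / 2, sdlog)
  }
  grid$band_mean <- config$background_mean + signal
  grid$background_mean <- config$background_mean
  grid$loading_value <- config$loading_mean
  truth <- tidyr::crossing(treatment = names(config$decay_rates),
                           timepoint = config$timepoints)
  truth$percent_remaining_true <-
    100 * exp(-config$decay_rates[truth$treatment] * truth$timepoint)
  structure(list(measurements = grid, truth = truth, config = config),
            class = "chase_sim")
}

#' Render a synthetic blot image with planted bands
#'
#' Flat background plus rectangular bands of known amplitude, with optional
#' Gaussian pixel noise — a fixture for the band-boxing densitometry.
#'
#' @param band_amplitudes Amplitudes above background, one per lane.
#' @param shape Image `c(rows, cols)`.
#' @param background Background level.
#' @param band_height,band_width Band box size in pixels.
#' @param band_row Center row of the band stripe.
#' @param noise_sd Additive Gaussian noise SD.
#' @param seed Integer seed.
#' @return List: `image` (matrix), `boxes` (tibble: lane, row_min, row_max,
#'   col_min, col_max), `background`.
#' @export
simulate_blot_image <- function(band_amplitudes, shape = c(60, NA),
                                background = 20, band_height = 10,
                                band_width = 16, band_row = 30,
                                noise_sd = 0, seed = 1) {
  n <- length(band_amplitudes)
  lane_pitch <- band_width + 10
  if (is.na(shape[2])) shape[2] <- n * lane_pitch + 10
  rng <- local_seed(seed)
  img <- matrix(background, shape[1], shape[2])
  boxes <- vector("list", n)
  for (i in seq_len(n)) {
    r0 <- band_row - band_height %/% 2
    c0 <- 10 + (i - 1) * lane_pitch
    rows <- r0:(r0 + band_height - 1)
    cols <- c0:(c0 + band_width - 1)
    img[rows, cols] <- background + band_amplitudes[i]
    boxes[[i]] <- tibble(lane = i, row_min = min(rows), row_max = max(rows),
                         col_min = min(cols), col_max = max(cols))
  }
  if (noise_sd > 0) {
    img <- pmax(img + stats::rnorm(length(img), 0, noise_sd), 0)
  }
  list(image = img, boxes = dplyr::bind_rows(boxes), background = background)
}
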