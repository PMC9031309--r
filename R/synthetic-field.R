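# Seeded generator for multi-channel microscopy fields of yeast-like cells:
# disk cell bodies with a stained wall ring (trypan-blue channel), a stained
# interior vacuole disk (CMAC channel) and per-cell GFP, plus ground-truth
# label masks and planted per-cell values.

#' Per-cell GFP level model
#'
#' Cell GFP levels are drawn from a (mixture of) lognormal component(s):
#' component `i` has linear-scale median `means[i]` and log-scale SD
#' `sdlog[i]`. With `sdlog = 0` every cell of a component gets exactly the
#' component median, which is what the noise-free fixtures use. Two
#' components with distinct medians give a bimodal expression population.
#'
#' @param means Component medians (linear scale, a.u.).
#' @param sdlog Log-scale SD per component (recycled).
#' @param weights Mixing fractions (recycled, normalized to sum 1).
#' @return List of class `gfp_model`.
#' @export
gfp_model <- function(means, sdlog = 0, weights = 1) {
  k <- length(means)
  sdlog <- rep_len(sdlog, k)
  weights <- rep_len(weights, k)
  stopifnot(all(means > 0), all(sdlog >= 0), all(weights > 0))
  structure(list(means = means, sdlog = sdlog,
                 weights = weights / sum(weights)),
            class = "gfp_model")
}

draw_gfp_levels <- function(model, n) {
  comp <- sample.int(length(model$means), n, replace = TRUE,
                     prob = model$weights)
  stats::rlnorm(n, meanlog = log(model$means[comp]),
                sdlog = model$sdlog[comp])
}

#' Configuration for a simulated microscopy field
#'
#' Cells are non-overlapping disks. The trypan-blue (TB) channel stains a
#' ring of `wall_thickness` pixels at the cell perimeter; the CMAC channel
#' stains an interior vacuole disk of radius `vacuole_radius_fraction` times
#' the cell radius; GFP is uniform per compartment. When
#' `pm_vac_ratio_true` is set, the GFP level in the wall ring is that
#' multiple of the vacuole level (surface-retained cargo); otherwise GFP is
#' uniform across the whole cell.
#'
#' @param image_shape `c(rows, cols)` in pixels.
#' @param n_cells Number of cells to place.
#' @param cell_radius_range `c(min, max)` cell radius, pixels.
#' @param vacuole_radius_fraction Vacuole radius as a fraction of cell
#'   radius (default 0.45).
#' @param wall_thickness Wall ring thickness, pixels (default 2).
#' @param gfp_levels A [gfp_model()] for per-cell GFP (default median 100).
#' @param pm_vac_ratio_true Planted surface/vacuole GFP ratio, or `NULL`
#'   for uniform whole-cell GFP.
#' @param stain_level Intensity of the TB and CMAC stains above background.
#' @param background_level Background intensity of the stain channels.
#' @param gfp_background Background intensity of the GFP channel (default 0,
#'   so compartment means equal the planted levels exactly).
#' @param noise_sd SD of additive Gaussian noise (0 = noise-free).
#' @param border_margin Pixels from the image edge a cell must clear to
#'   count as interior.
#' @param border_fraction Fraction of cells deliberately placed so their
#'   disk crosses the image border.
#' @param min_gap Minimum gap between cell disks, pixels.
#' @param max_attempts Placement attempts before a geometry error.
#' @param seed Integer seed.
#' @return List of class `field_sim_config`.
#' @export
field_sim_config <- function(image_shape = c(256, 256),
                             n_cells = 25,
                             cell_radius_range = c(12, 18),
                             vacuole_radius_fraction = 0.45,
                             wall_thickness = 2,
                             gfp_levels = gfp_model(100),
                             pm_vac_ratio_true = NULL,
                             stain_level = 150,
                             background_level = 10,
                             gfp_background = 0,
                             noise_sd = 0,
                             border_margin = 2,
                             border_fraction = 0,
                             min_gap = 3,
                             max_attempts = 5000,
                             seed = 1) {
  stopifnot(length(image_shape) == 2L, n_cells >= 0,
            vacuole_radius_fraction > 0, vacuole_radius_fraction < 1,
            wall_thickness >= 1, noise_sd >= 0,
            border_fraction >= 0, border_fraction <= 1)
  if (!inherits(gfp_levels, "gfp_model")) gfp_levels <- gfp_model(gfp_levels)
  structure(list(
    image_shape = image_shape, n_cells = n_cells,
    cell_radius_range = cell_radius_range,
    vacuole_radius_fraction = vacuole_radius_fraction,
    wall_thickness = wall_thickness, gfp_levels = gfp_levels,
    pm_vac_ratio_true = pm_vac_ratio_true, stain_level = stain_level,
    background_level = background_level, gfp_background = gfp_background,
    noise_sd = noise_sd,
    border_margin = border_margin, border_fraction = border_fraction,
    min_gap = min_gap, max_attempts = max_attempts, seed = as.integer(seed)
  ), class = "field_sim_config")
}

#' Simulate a multi-channel microscopy field with ground truth
#'
#' Places non-overlapping disk cells (rejection sampling), paints the GFP,
#' CMAC and TB channels per [field_sim_config()], and returns them together
#' with ground-truth label masks (whole cell, wall ring, vacuole) and a
#' per-cell truth table.
#'
#' @param config A [field_sim_config()].
#' @return List of class `microscopy_field`: matrices `gfp`, `cmac`, `tb`;
#'   integer label matrices `labels`, `wall_labels`, `vacuole_labels`;
#'   tibble `truth` (cell_id, cx, cy, radius, border, gfp_level,
#'   true_mean_gfp, true_pm_vac_ratio); and `config`.
#' @examples
#' field <- simulate_microscopy_field(field_sim_config(n_cells = 5, seed = 3))
#' max(field$labels)  # 5
#' @export
simulate_microscopy_field <- function(config) {
  stopifnot(inherits(config, "field_sim_config"))
  rng <- local_seed(config$seed)
  nr <- config$image_shape[1]; nc <- config$image_shape[2]

  n_border <- round(config$border_fraction * config$n_cells)
  radii <- stats::runif(config$n_cells, config$cell_radius_range[1],
                        config$cell_radius_range[2])
  centers <- matrix(NA_real_, config$n_cells, 2)
  attempts <- 0L
  placed <- 0L
  while (placed < config$n_cells) {
    attempts <- attempts + 1L
    if (attempts > config$max_attempts) {
      stop("geometry error: could not place ", config$n_cells,
           " non-overlapping cells in ", config$max_attempts, " attempts")
    }
    i <- placed + 1L
    r <- radii[i]
    if (i <= n_border) {
      # center within one radius of an edge so the disk crosses the border
      edge <- sample.int(4L, 1L)
      off <- stats::runif(1, -r + 1, r * 0.5)
      if (edge == 1L) { cy <- off; cx <- stats::runif(1, 1, nc) }
      else if (edge == 2L) { cy <- nr - off; cx <- stats::runif(1, 1, nc) }
      else if (edge == 3L) { cx <- off; cy <- stats::runif(1, 1, nr) }
      else { cx <- nc - off; cy <- stats::runif(1, 1, nr) }
    } else {
      pad <- r + config$border_margin + 1
      if (pad * 2 >= min(nr, nc)) stop("geometry error: cells larger than image")
      cy <- stats::runif(1, pad, nr - pad)
      cx <- stats::runif(1, pad, nc - pad)
    }
    if (placed > 0L) {
      d <- sqrt((centers[seq_len(placed), 1] - cy)^2 +
                  (centers[seq_len(placed), 2] - cx)^2)
      if (any(d < radii[seq_len(placed)] + r + config$min_gap)) next
    }
    centers[i, ] <- c(cy, cx)
    placed <- i
  }

  gfp_level <- draw_gfp_levels(config$gfp_levels, config$n_cells)
  ratio <- config$pm_vac_ratio_true

  labels <- matrix(0L, nr, nc)
  wall_labels <- matrix(0L, nr, nc)
  vac_labels <- matrix(0L, nr, nc)
  gfp0 <- matrix(config$gfp_background, nr, nc)
  cmac0 <- matrix(config$background_level, nr, nc)
  tb0 <- matrix(config$background_level, nr, nc)

  row_idx <- matrix(seq_len(nr), nr, nc)
  col_idx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  truth <- vector("list", config$n_cells)

  for (i in seq_len(config$n_cells)) {
    cy <- centers[i, 1]; cx <- centers[i, 2]; r <- radii[i]
    d2 <- (row_idx - cy)^2 + (col_idx - cx)^2
    cell <- d2 <= r^2
    wall <- cell & d2 > (r - config$wall_thickness)^2
    vac <- d2 <= (config$vacuole_radius_fraction * r)^2
    labels[cell] <- i
    wall_labels[wall] <- i
    vac_labels[vac] <- i

    if (is.null(ratio)) {
      gfp0[cell] <- config$gfp_background + gfp_level[i]
    } else {
      # vacuole compartment carries the cell's base level, the surface ring
      # carries ratio x that level; cytoplasm matches the vacuole level
      gfp0[cell & !wall] <- config$gfp_background + gfp_level[i]
      gfp0[wall] <- config$gfp_background + ratio * gfp_level[i]
    }
    cmac0[vac] <- config$background_level + config$stain_level
    tb0[wall] <- config$background_level + config$stain_level

    on_border <- (cy - r) < (1 + config$border_margin) ||
      (cx - r) < (1 + config$border_margin) ||
      (cy + r) > (nr - config$border_margin) ||
      (cx + r) > (nc - config$border_margin)
    truth[[i]] <- tibble(
      cell_id = i, cy = cy, cx = cx, radius = r, border = on_border,
      gfp_level = gfp_level[i],
      true_mean_gfp = mean(gfp0[cell]) - config$gfp_background,
      true_pm_vac_ratio = if (is.null(ratio)) 1 else ratio
    )
  }

  add_noise <- function(m) {
    if (config$noise_sd == 0) return(m)
    pmax(m + stats::rnorm(length(m), 0, config$noise_sd), 0)
  }

  structure(list(
    gfp = add_noise(gfp0), cmac = add_noise(cmac0), tb = add_noise(tb0),
    labels = labels, wall_labels = wall_labels, vacuole_labels = vac_labels,
    truth = dplyr::bind_rows(truth), config = config
  ), class = "microscopy_field")
}

#' Write a simulated field to disk
#'
#' One 16-bit single-channel TIFF per channel, a 16-bit label-mask TIFF,
#' and a JSON sidecar with the per-cell ground truth.
#'
#' @param field A `microscopy_field`.
#' @param dir Output directory (created if missing).
#' @param max_intensity Intensity mapped to the 16-bit ceiling.
#' @return `dir`, invisibly.
#' @export
write_field <- function(field, dir, max_intensity = 4096) {
  stopifnot(inherits(field, "microscopy_field"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in c("gfp", "cmac", "tb")) {
    tiff::writeTIFF(pmin(field[[ch]] / max_intensity, 1),
                    file.path(dir, paste0(ch, ".tif")),
                    bits.per.sample = 16L)
  }
  tiff::writeTIFF(field$labels / 65535,
                  file.path(dir, "labels.tif"), bits.per.sample = 16L)
  jsonlite::write_json(field$truth, file.path(dir, "truth.json"),
                       digits = NA)
  invisible(dir)
}

#' Read a field written by [write_field()]
#'
#' @param dir Directory holding `gfp.tif`, `cmac.tif`, `tb.tif` and
#'   optionally `labels.tif` / `truth.json`.
#' @param max_intensity Intensity scale used when writing.
#' @return A `microscopy_field` (without `config`).
#' @export
read_field <- function(dir, max_intensity = 4096) {
  read_ch <- function(f) tiff::readTIFF(file.path(dir, f)) * max_intensity
  out <- list(gfp = read_ch("gfp.tif"), cmac = read_ch("cmac.tif"),
              tb = read_ch("tb.tif"))
  lab_path <- file.path(dir, "labels.tif")
  if (file.exists(lab_path)) {
    out$labels <- matrix(as.integer(round(tiff::readTIFF(lab_path) * 65535)),
                         nrow = nrow(out$gfp))
  }
  truth_path <- file.path(dir, "truth.json")
  if (file.exists(truth_path)) {
    out$truth <- as_tibble(jsonlite::read_json(truth_path,
                                               simplifyVector = TRUE))
  }
  structure(out, class = "microscopy_field")
}
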