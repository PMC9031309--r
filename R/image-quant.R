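# Per-cell fluorescence quantification: classical segmentation (smooth ->
# automatic threshold -> distance-transform watershed), border-cell removal,
# whole-cell GFP means, paired surface/vacuole compartment masks, PM/vacuole
# ratios, population summaries and bimodal-population splitting.

field_channels <- function(field) {
  if (inherits(field, "microscopy_field") || is.list(field)) {
    list(gfp = field$gfp, cmac = field$cmac, tb = field$tb)
  } else {
    stop("expected a microscopy_field or a list of channel matrices")
  }
}

norm01 <- function(m) {
  rng <- range(m)
  if (diff(rng) == 0) return(matrix(0, nrow(m), ncol(m)))
  (m - rng[1]) / diff(rng)
}

#' Segment cells in a multi-channel field
#'
#' Classical cell-body segmentation: the channels are combined into a single
#' support image (pixel-wise maximum of the normalized channels), smoothed
#' with a Gaussian, thresholded with Otsu's method, hole-filled (a closed
#' wall ring becomes a solid disk), and touching objects are split by a
#' watershed on the distance transform. Objects outside the area window are
#' discarded.
#'
#' @param field A `microscopy_field` or list with matrices `gfp`, `cmac`,
#'   `tb` (any subset; `NULL` channels are ignored).
#' @param min_area,max_area Object area window, pixels.
#' @param blur_sigma Gaussian smoothing SD, pixels.
#' @param watershed_tolerance Minimum object-separation depth for the
#'   distance-transform watershed.
#' @return Integer label matrix (0 = background), labels contiguous from 1.
#' @export
segment_cells <- function(field, min_area = 60, max_area = Inf,
                          blur_sigma = 2, watershed_tolerance = 1) {
  ch <- Filter(Negate(is.null), field_channels(field))
  if (length(ch) == 0L) stop("no channels supplied")
  support <- Reduce(pmax, lapply(ch, norm01))
  if (max(support) == 0) {
    warning("empty field: no signal above background")
    return(matrix(0L, nrow(support), ncol(support)))
  }
  img <- EBImage::Image(support)
  sm <- EBImage::gblur(img, sigma = blur_sigma)
  thr <- EBImage::otsu(sm, range = c(0, 1))
  mask <- EBImage::fillHull(sm > thr)
  if (sum(mask) == 0) {
    warning("empty field: threshold removed all pixels")
    return(matrix(0L, nrow(support), ncol(support)))
  }
  dm <- EBImage::distmap(mask)
  labels <- EBImage::watershed(dm, tolerance = watershed_tolerance)
  labels <- EBImage::imageData(labels)
  # the blur pushes bright rims past the threshold, inflating objects by a
  # pixel or two; refine boundaries against the unsmoothed support, then
  # refill interior holes (dim cytoplasm enclosed by a stained wall ring)
  refined <- (support > thr) & (labels > 0)
  refined <- EBImage::imageData(EBImage::fillHull(EBImage::Image(refined * 1))) > 0
  labels[!refined] <- 0L
  areas <- tabulate(labels[labels > 0])
  keep <- which(areas >= min_area & areas <= max_area)
  relabel_mask(ifelse(labels %in% keep, labels, 0L),
               dim = dim(support))
}

relabel_mask <- function(labels, dim = NULL) {
  if (!is.null(dim)) labels <- matrix(labels, dim[1], dim[2])
  ids <- sort(unique(labels[labels > 0]))
  out <- matrix(0L, nrow(labels), ncol(labels))
  for (k in seq_along(ids)) out[labels == ids[k]] <- k
  out
}

#' Remove cells touching the image border
#'
#' Drops every label with a pixel within `margin` pixels of the image edge
#' and relabels the survivors contiguously. Idempotent.
#'
#' @param mask Integer label matrix.
#' @param margin Border width, pixels (default 1: the outermost pixel row).
#' @return Filtered, relabeled label matrix.
#' @export
remove_border_cells <- function(mask, margin = 1) {
  stopifnot(margin >= 1)
  nr <- nrow(mask); nc <- ncol(mask)
  edge <- unique(c(mask[seq_len(min(margin, nr)), ],
                   mask[seq(nr - min(margin, nr) + 1L, nr), ],
                   mask[, seq_len(min(margin, nc))],
                   mask[, seq(nc - min(margin, nc) + 1L, nc)]))
  edge <- edge[edge > 0]
  relabel_mask(ifelse(mask %in% edge, 0L, mask), dim = dim(mask))
}

#' Whole-cell mean GFP per labeled cell
#'
#' @param mask Integer label matrix.
#' @param gfp GFP channel matrix, same shape.
#' @return Tibble with `cell_id`, `area` (pixels), `mean_gfp`.
#' @export
whole_cell_intensities <- function(mask, gfp) {
  if (!all(dim(mask) == dim(gfp))) {
    stop("shape error: mask and channel dimensions differ")
  }
  ids <- sort(unique(mask[mask > 0]))
  if (length(ids) == 0L) {
    return(tibble(cell_id = integer(), area = integer(),
                  mean_gfp = numeric()))
  }
  px <- mask > 0
  tibble(
    cell_id = as.integer(ids),
    area = as.integer(tabulate(mask[px])[ids]),
    mean_gfp = as.numeric(tapply(gfp[px], mask[px], mean)[as.character(ids)])
  )
}

#' Paired surface and vacuole masks per cell
#'
#' For each labeled cell, the surface mask is the set of trypan-blue-positive
#' pixels in a band of `band_width` pixels either side of the cell boundary
#' (inner band from the cell's distance transform; outer band from dilation,
#' never stealing pixels from a neighboring cell). The vacuole mask is the
#' set of CMAC-positive pixels in the cell interior (cell minus inner band).
#' Both stains are thresholded per field with Otsu's method. The two masks
#' are disjoint by construction. Cells whose vacuole mask comes out empty
#' are flagged: their ratio is undefined.
#'
#' @param field A `microscopy_field` (TB and CMAC channels required).
#' @param cell_mask Integer label matrix of whole cells (e.g. from
#'   [segment_cells()] or the generator's ground truth).
#' @param band_width Half-width of the perimeter band, pixels (default 2).
#' @return List with integer label matrices `surface` and `vacuole` and a
#'   tibble `flags` (`cell_id`, `vacuole_defined`).
#' @export
surface_and_vacuole_masks <- function(field, cell_mask, band_width = 2) {
  ch <- field_channels(field)
  if (is.null(ch$tb) || is.null(ch$cmac)) {
    stop("TB and CMAC channels are required")
  }
  tb_bin <- auto_threshold(ch$tb)
  cmac_bin <- auto_threshold(ch$cmac)

  ids <- sort(unique(cell_mask[cell_mask > 0]))
  surface <- matrix(0L, nrow(cell_mask), ncol(cell_mask))
  vacuole <- matrix(0L, nrow(cell_mask), ncol(cell_mask))
  brush <- EBImage::makeBrush(2L * as.integer(band_width) + 1L, "disc")
  flags <- logical(length(ids))
  for (k in seq_along(ids)) {
    region <- cell_mask == ids[k]
    dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(region * 1)))
    # half-pixel slack: the discrete Euclidean distance of a pixel sitting
    # band_width inside the boundary can exceed band_width by < 0.5
    inner_band <- region & dm <= band_width + 0.5
    outer <- EBImage::imageData(
      EBImage::dilate(EBImage::Image(region * 1), brush)) > 0
    outer_band <- outer & !region & cell_mask == 0L
    band <- inner_band | outer_band
    surf <- band & tb_bin
    vac <- region & !inner_band & cmac_bin
    surface[surf] <- ids[k]
    vacuole[vac] <- ids[k]
    flags[k] <- sum(vac) > 0L
  }
  list(surface = surface, vacuole = vacuole,
       flags = tibble(cell_id = as.integer(ids), vacuole_defined = flags))
}

auto_threshold <- function(m) {
  n <- norm01(m)
  if (max(n) == 0) return(matrix(FALSE, nrow(m), ncol(m)))
  thr <- EBImage::otsu(EBImage::Image(n), range = c(0, 1))
  n > thr
}

#' Quantify all cells of a field
#'
#' Convenience wrapper: whole-cell GFP means plus, when requested, surface
#' and vacuole compartment means and the PM/vacuole ratio per cell.
#'
#' @param field A `microscopy_field`.
#' @param cell_mask Label matrix; `NULL` runs [segment_cells()] +
#'   [remove_border_cells()].
#' @param compartments Compute surface/vacuole means and ratios?
#' @param band_width Passed to [surface_and_vacuole_masks()].
#' @param border_margin Passed to [remove_border_cells()] when segmenting.
#' @return Tibble with one row per cell: `cell_id`, `area`, `mean_gfp`, and
#'   (with `compartments`) `surface_mean`, `vacuole_mean`, `pm_vac_ratio`.
#' @export
quantify_cells <- function(field, cell_mask = NULL, compartments = FALSE,
                           band_width = 2, border_margin = 1) {
  if (is.null(cell_mask)) {
    cell_mask <- remove_border_cells(segment_cells(field),
                                     margin = border_margin)
  }
  ch <- field_channels(field)
  rec <- whole_cell_intensities(cell_mask, ch$gfp)
  if (!compartments) return(rec)
  cm <- surface_and_vacuole_masks(field, cell_mask, band_width = band_width)
  comp_mean <- function(lab) {
    m <- rep(NA_real_, nrow(rec))
    px <- lab > 0
    if (any(px)) {
      v <- tapply(ch$gfp[px], lab[px], mean)
      m[match(as.integer(names(v)), rec$cell_id)] <- as.numeric(v)
    }
    m
  }
  rec$surface_mean <- comp_mean(cm$surface)
  rec$vacuole_mean <- comp_mean(cm$vacuole)
  pm_vacuole_ratio(rec)
}

#' PM/vacuole fluorescence ratio per cell
#'
#' Ratio of the surface-compartment mean GFP over the vacuole-compartment
#' mean GFP. Cells without a positive vacuole mean have no defined ratio
#' (`NA`); the attribute `n_excluded` counts them.
#'
#' @param records Tibble with columns `surface_mean` and `vacuole_mean`.
#' @return `records` with a `pm_vac_ratio` column.
#' @export
pm_vacuole_ratio <- function(records) {
  stopifnot(all(c("surface_mean", "vacuole_mean") %in% names(records)))
  ok <- !is.na(records$vacuole_mean) & records$vacuole_mean > 0 &
    !is.na(records$surface_mean)
  records$pm_vac_ratio <- ifelse(ok, records$surface_mean /
                                   records$vacuole_mean, NA_real_)
  attr(records, "n_excluded") <- sum(!ok)
  records
}

#' Median with bootstrap confidence interval
#'
#' Population summary for per-cell intensity distributions: the median and
#' a seeded percentile-bootstrap confidence interval of the median.
#'
#' @param values Numeric vector, n >= 3.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed for the resampling.
#' @return List: `n_cells`, `median`, `ci_lower`, `ci_upper`, `conf`.
#' @export
population_summary <- function(values, n_boot = 2000, conf = 0.95, seed = 1) {
  values <- as.numeric(values[!is.na(values)])
  if (length(values) < 3L) {
    stop("insufficient data: need at least 3 values, got ", length(values))
  }
  rng <- local_seed(seed)
  n <- length(values)
  boots <- vapply(seq_len(n_boot), function(i)
    stats::median(values[sample.int(n, n, replace = TRUE)]), numeric(1))
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha), type = 7))
  list(n_cells = n, median = stats::median(values),
       ci_lower = ci[1], ci_upper = ci[2], conf = conf)
}

#' Split a fluorescence population into subpopulations
#'
#' Fits a k-component Gaussian mixture to log-intensities by EM with a
#' deterministic model-based-hierarchical-clustering initialization
#' (unequal variances), giving component fractions, linear-scale component
#' medians, and hard per-cell assignments. Components are reported sorted
#' by increasing mean so output is stable under relabeling. A BIC
#' comparison against a single-component fit reports whether the split is
#' warranted; when it is not, the fractions are flagged as unreliable.
#'
#' @param values Positive intensities, n >= 20.
#' @param k Number of components (default 2).
#' @param seed Integer seed (EM initialization is deterministic; the seed
#'   guards auxiliary randomness in the fitter).
#' @return List: `fractions`, `means` (linear scale), `meanlog`, `sdlog`,
#'   `assignment` (1 = dimmest component), `separation` (difference of
#'   component log-means over pooled log-SD), `split_warranted`, `bic`.
#' @export
split_subpopulations <- function(values, k = 2, seed = 1) {
  values <- as.numeric(values)
  if (length(values) < 20L) stop("need at least 20 values")
  if (any(values <= 0)) stop("values must be positive (log-scale fit)")
  rng <- local_seed(seed)
  x <- log(values)
  fit <- mclust::Mclust(x, G = k, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) stop("mixture fit did not converge")
  fit1 <- mclust::Mclust(x, G = 1, modelNames = "X", verbose = FALSE)

  ord <- order(fit$parameters$mean)
  meanlog <- fit$parameters$mean[ord]
  sdlog <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sdlog) == 1L) sdlog <- rep(sdlog, k)
  sdlog <- sdlog[ord]
  fractions <- fit$parameters$pro[ord]
  assignment <- match(fit$classification, ord)
  pooled_sd <- sqrt(sum(fractions * sdlog^2))
  separation <- if (k == 2L) abs(diff(meanlog)) / pooled_sd else NA_real_

  list(
    fractions = unname(fractions),
    means = unname(exp(meanlog)),
    meanlog = unname(meanlog),
    sdlog = unname(sdlog),
    assignment = assignment,
    separation = separation,
    split_warranted = fit$bic > fit1$bic,
    bic = c(one_component = fit1$bic, k_component = fit$bic)
  )
}

#' Jaccard index of two binary masks
#'
#' @param a,b Logical or 0/1 matrices of equal shape.
#' @return Intersection over union; 1 when both masks are empty.
#' @export
mask_jaccard <- function(a, b) {
  a <- a > 0; b <- b > 0
  stopifnot(all(dim(a) == dim(b)))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
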