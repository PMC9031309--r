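# Seeded generator for arrayed colony-size screens: a deletion library
# stamped across plates under several plasmids and media conditions, with
# planted modifier effects as ground truth for the scoring pipeline.

#' Configuration for a simulated colony-size screen
#'
#' Describes an arrayed deletion-library over-expression screen: `n_strains`
#' deletion strains laid out over 96-well plates, transformed with each
#' plasmid and stamped in technical replicate onto each medium condition.
#' Colony sizes follow a multiplicative model
#' `baseline * plate_effect * condition_effect * modifier * noise`
#' with lognormal noise (areas are positive and right-skewed), so a strain
#' with no planted modifier and no noise has the same size everywhere within
#' a plate x plasmid x condition stratum.
#'
#' @param n_strains Number of deletion strains (default 187, a two-plate
#'   kinase/phosphatase library).
#' @param plates Number of 96-well plates (default 2); `n_strains` must fit.
#' @param plasmids Plasmid labels; the first is treated as the empty-vector
#'   control by the scorer.
#' @param conditions Medium condition labels.
#' @param n_replicates Technical replicates per stamping (default 3).
#' @param baseline_mean Baseline colony area, pixels.
#' @param baseline_sd SD of optional strain-level baseline heterogeneity
#'   (lognormal, on the pixel scale); 0 (default) disables it.
#' @param plate_effects Named multiplicative factor per plate (default all 1).
#' @param condition_effects Named multiplicative factor per condition
#'   (default all 1). Must be strictly positive.
#' @param planted_modifiers Data frame with columns `gene`, `plasmid`,
#'   `condition`, `effect`: multiplicative effect on colony size for that
#'   strain/arm. Effects must be strictly positive. See [random_modifiers()].
#' @param noise_cv Coefficient of variation of the per-colony lognormal noise.
#' @param dead_strains Character vector of genes whose colonies are planted
#'   at size 0 in every arm (dead strains).
#' @param day Imaging day recorded in the table (default 1; the generator
#'   emits a single day).
#' @param seed Integer seed; fully determines the output.
#' @return A list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_strains = 187,
                              plates = 2,
                              plasmids = c("vector", "ALY1", "ALY2"),
                              conditions = c("control", "NaCl_0.8M",
                                             "NaCl_1.5M", "rapamycin_50ng_mL"),
                              n_replicates = 3,
                              baseline_mean = 500,
                              baseline_sd = 0,
                              plate_effects = NULL,
                              condition_effects = NULL,
                              planted_modifiers = NULL,
                              noise_cv = 0.05,
                              dead_strains = character(),
                              day = 1,
                              seed = 1) {
  if (n_strains > plates * 96) {
    stop("capacity error: ", n_strains, " strains exceed ", plates,
         " x 96 wells")
  }
  if (is.null(plate_effects)) {
    plate_effects <- stats::setNames(rep(1, plates), paste0("plate", seq_len(plates)))
  }
  if (is.null(condition_effects)) {
    condition_effects <- stats::setNames(rep(1, length(conditions)), conditions)
  }
  if (any(plate_effects <= 0) || any(condition_effects <= 0)) {
    stop("plate and condition effects must be strictly positive")
  }
  if (!is.null(planted_modifiers)) {
    planted_modifiers <- as_tibble(planted_modifiers)
    stopifnot(all(c("gene", "plasmid", "condition", "effect") %in%
                    names(planted_modifiers)))
    if (any(planted_modifiers$effect <= 0)) {
      stop("modifier effects must be strictly positive")
    }
  } else {
    planted_modifiers <- tibble(gene = character(), plasmid = character(),
                                condition = character(), effect = numeric())
  }
  structure(list(
    n_strains = n_strains, plates = plates, plasmids = plasmids,
    conditions = conditions, n_replicates = n_replicates,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    plate_effects = plate_effects, condition_effects = condition_effects,
    planted_modifiers = planted_modifiers, noise_cv = noise_cv,
    dead_strains = dead_strains, day = day, seed = as.integer(seed)
  ), class = "screen_sim_config")
}

#' Draw a random set of planted modifier effects
#'
#' Convenience builder for `planted_modifiers`: picks `n` distinct genes,
#' assigns each a random over-expression arm and an effect drawn from
#' `effects`, applied across all supplied conditions (a modifier of arrestin
#' function acts in every medium).
#'
#' @param genes Candidate gene names (e.g. from [strain_names()]).
#' @param n Number of modifier genes.
#' @param plasmids Arms a modifier may act in (never the vector control).
#' @param conditions Conditions the effect applies to.
#' @param effects Pool of multiplicative effects to sample from.
#' @param seed Integer seed.
#' @return Tibble with columns `gene`, `plasmid`, `condition`, `effect`.
#' @export
random_modifiers <- function(genes, n, plasmids = c("ALY1", "ALY2"),
                             conditions = c("control", "NaCl_0.8M",
                                            "NaCl_1.5M", "rapamycin_50ng_mL"),
                             effects = c(0.5, 2), seed = 1) {
  stopifnot(n <= length(genes))
  rng <- local_seed(seed)
  picked <- sample(genes, n)
  tidyr::crossing(
    tibble(gene = picked,
           plasmid = sample(plasmids, n, replace = TRUE),
           effect = sample(effects, n, replace = TRUE)),
    condition = conditions
  )[, c("gene", "plasmid", "condition", "effect")]
}

#' Deletion-strain names for a simulated library
#' @param n Number of strains.
#' @return Character vector like `"del001"`.
#' @export
strain_names <- function(n) sprintf("del%03d", seq_len(n))

#' Simulate an arrayed colony-size screen
#'
#' Generates one colony-size measurement per strain x plasmid x condition x
#' technical replicate, following the multiplicative model described in
#' [screen_sim_config()]. Strains are arrayed row-major over the plates
#' (96 per plate, wells A01..H12).
#'
#' @param config A [screen_sim_config()].
#' @return A list of class `screen_sim` with elements `measurements`
#'   (tibble: plate, row, col, gene, plasmid, condition, replicate, day,
#'   colony_px), `truth` (the planted-modifier tibble) and `config`.
#' @examples
#' sim <- simulate_screen_plates(screen_sim_config(n_strains = 8, seed = 1))
#' nrow(sim$measurements)  # 8 strains x 3 plasmids x 4 conditions x 3 reps
#' @export
simulate_screen_plates <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  rng <- local_seed(config$seed)

  genes <- strain_names(config$n_strains)
  idx <- seq_len(config$n_strains) - 1L
  layout <- tibble(
    gene = genes,
    plate = paste0("plate", idx %/% 96L + 1L),
    row = LETTERS[(idx %% 96L) %/% 12L + 1L],
    col = idx %% 12L + 1L
  )

  # per-strain baseline (heterogeneity off by default)
  if (config$baseline_sd > 0) {
    cv <- config$baseline_sd / config$baseline_mean
    sdlog <- sqrt(log(1 + cv^2))
    baseline <- config$baseline_mean *
      stats::rlnorm(config$n_strains, -sdlog^2 / 2, sdlog)
  } else {
    baseline <- rep(config$baseline_mean, config$n_strains)
  }
  layout$baseline <- baseline

  tbl <- tidyr::crossing(layout,
                         plasmid = config$plasmids,
                         condition = config$conditions,
                         replicate = seq_len(config$n_replicates))
  tbl <- dplyr::left_join(tbl, config$planted_modifiers,
                          by = c("gene", "plasmid", "condition"))
  tbl$effect[is.na(tbl$effect)] <- 1

  # lognormal noise with unit mean and the requested CV
  if (config$noise_cv > 0) {
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    noise <- stats::rlnorm(nrow(tbl), -sdlog^2 / 2, sdlog)
  } else {
    noise <- rep(1, nrow(tbl))
  }

  tbl$colony_px <- tbl$baseline *
    config$plate_effects[tbl$plate] *
    config$condition_effects[tbl$condition] *
    tbl$effect * noise
  tbl$colony_px[tbl$gene %in% config$dead_strains] <- 0
  tbl$day <- config$day

  measurements <- tbl |>
    dplyr::arrange(.data$plate, .data$row, .data$col, .data$plasmid,
                   .data$condition, .data$replicate) |>
    dplyr::select("plate", "row", "col", "gene", "plasmid", "condition",
                  "replicate", "day", "colony_px")

  structure(list(measurements = measurements,
                 truth = config$planted_modifiers,
                 config = config),
            class = "screen_sim")
}

# Seed an RNG for the duration of the calling function, restoring the
# caller's random state on exit.
local_seed <- function(seed, env = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  withr::defer({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, envir = env)
  invisible(seed)
}
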