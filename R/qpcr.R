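# Relative transcript quantification by the 2^-ddCt method with
# reference-gene normalization, plus a seeded Ct-table generator with
# known true relative expression.

#' Configuration for a simulated qPCR plate
#'
#' Ct values assume perfect doubling per cycle: the target Ct of a strain is
#' `reference_ct + target_offset - log2(true_rq)` plus Gaussian cycle noise,
#' so the unmodified 2^-ddCt analysis recovers `true_rq` exactly in the
#' noise-free limit.
#'
#' @param true_rq Named vector of true relative expression per strain; must
#'   contain the calibrator `"WT"` with value 1.
#' @param reference_ct_mean Reference-gene Ct, cycles.
#' @param target_offset Baseline target-minus-reference Ct offset, cycles.
#' @param ct_noise_sd SD of Gaussian Ct noise, cycles.
#' @param n_biological,n_technical Replicate structure (default 2 x 2).
#' @param target,reference Primer-set labels.
#' @param seed Integer seed.
#' @return List of class `qpcr_sim_config`.
#' @export
qpcr_sim_config <- function(true_rq = c(WT = 1),
                            reference_ct_mean = 15,
                            target_offset = 5,
                            ct_noise_sd = 0,
                            n_biological = 2,
                            n_technical = 2,
                            target = "GFP",
                            reference = "YEP3",
                            seed = 1) {
  if (!"WT" %in% names(true_rq)) {
    stop("configuration error: calibrator strain 'WT' missing from true_rq")
  }
  if (true_rq[["WT"]] != 1) stop("true_rq['WT'] must be 1")
  if (any(true_rq <= 0)) stop("true relative expression must be positive")
  structure(list(true_rq = true_rq, reference_ct_mean = reference_ct_mean,
                 target_offset = target_offset, ct_noise_sd = ct_noise_sd,
                 n_biological = n_biological, n_technical = n_technical,
                 target = target, reference = reference,
                 seed = as.integer(seed)),
            class = "qpcr_sim_config")
}

#' Simulate a qPCR Ct table
#'
#' @param config A [qpcr_sim_config()].
#' @return List of class `qpcr_sim`: `ct` (tibble: strain, primer, bio_rep,
#'   tech_rep, ct), `truth` (named true RQ vector), `config`.
#' @examples
#' sim <- simulate_qpcr_plate(qpcr_sim_config(true_rq = c(WT = 1, mut = 0.5)))
#' compute_rq(sim$ct)$summary
#' @export
simulate_qpcr_plate <- function(config) {
  stopifnot(inherits(config, "qpcr_sim_config"))
  rng <- local_seed(config$seed)
  grid <- tidyr::crossing(strain = names(config$true_rq),
                          primer = c(config$target, config$reference),
                          bio_rep = seq_len(config$n_biological),
                          tech_rep = seq_len(config$n_technical))
  base <- ifelse(grid$primer == config$reference,
                 config$reference_ct_mean,
                 config$reference_ct_mean + config$target_offset -
                   log2(config$true_rq[grid$strain]))
  noise <- if (config$ct_noise_sd > 0) {
    stats::rnorm(nrow(grid), 0, config$ct_noise_sd)
  } else 0
  grid$ct <- base + noise
  structure(list(ct = grid, truth = config$true_rq, config = config),
            class = "qpcr_sim")
}

#' Relative quantification by 2^-ddCt
#'
#' Per replicate, dCt = Ct(target) - Ct(reference); ddCt = dCt minus the
#' calibrator strain's mean dCt; RQ = 2^-ddCt. With `tech_reps = "pair"`
#' (default) the target and reference wells of each technical replicate are
#' paired, so a 2 biological x 2 technical design yields 4 replicate RQs per
#' strain; `tech_reps = "average"` first averages Ct over technical
#' replicates within each biological replicate, yielding one RQ per
#' biological replicate.
#'
#' @param ct Ct tibble with columns `strain`, `primer`, `bio_rep`,
#'   `tech_rep`, `ct` (as written by [simulate_qpcr_plate()]).
#' @param target,reference Primer-set labels (reference defaults to the
#'   cDNA-abundance control `YEP3`).
#' @param calibrator Calibrator strain (RQ == 1 by construction on its own
#'   mean dCt).
#' @param tech_reps `"pair"` or `"average"` (see above).
#' @return List of class `rq_result`: `replicates` (tibble: strain,
#'   bio_rep, [tech_rep,] d_ct, dd_ct, rq) and `summary` (per strain:
#'   mean_rq, sd_rq, n; see [summarize_rq()]).
#' @export
compute_rq <- function(ct, target = "GFP", reference = "YEP3",
                       calibrator = "WT",
                       tech_reps = c("pair", "average")) {
  tech_reps <- match.arg(tech_reps)
  ct <- as_tibble(ct)
  stopifnot(all(c("strain", "primer", "bio_rep", "tech_rep", "ct") %in%
                  names(ct)))
  if (!calibrator %in% ct$strain) {
    stop("calibrator strain '", calibrator, "' not present")
  }
  for (p in c(target, reference)) {
    if (!p %in% ct$primer) stop("primer '", p, "' not present")
  }

  keys <- if (tech_reps == "pair") c("strain", "bio_rep", "tech_rep") else
    c("strain", "bio_rep")
  wide <- ct |>
    dplyr::filter(.data$primer %in% c(target, reference)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "primer")))) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "primer", values_from = "ct")
  incomplete <- is.na(wide[[target]]) | is.na(wide[[reference]])
  if (any(incomplete)) {
    warning(sum(incomplete), " replicate(s) missing a target or reference ",
            "Ct; dropped")
    wide <- wide[!incomplete, , drop = FALSE]
  }
  wide$d_ct <- wide[[target]] - wide[[reference]]
  cal_dct <- mean(wide$d_ct[wide$strain == calibrator])
  wide$dd_ct <- wide$d_ct - cal_dct
  wide$rq <- 2^(-wide$dd_ct)

  replicates <- dplyr::select(wide, dplyr::all_of(keys), "d_ct", "dd_ct", "rq")
  structure(list(replicates = replicates,
                 summary = summarize_rq(replicates),
                 calibrator = calibrator),
            class = "rq_result")
}

#' Summarize replicate RQ values per strain
#'
#' Arithmetic mean and sample SD of the replicate RQs; strains with a
#' single replicate get `NA` SD with a warning.
#'
#' @param rq Tibble with columns `strain` and `rq` (e.g.
#'   `compute_rq(...)$replicates`).
#' @return Tibble per strain: `mean_rq`, `sd_rq`, `n`.
#' @export
summarize_rq <- function(rq) {
  out <- rq |>
    dplyr::group_by(.data$strain) |>
    dplyr::summarise(mean_rq = mean(.data$rq), sd_rq = stats::sd(.data$rq),
                     n = dplyr::n(), .groups = "drop")
  if (any(out$n < 2L)) {
    warning("strain(s) with a single replicate; SD undefined")
  }
  out
}

#' Compare strain RQ distributions against the calibrator
#'
#' Kruskal-Wallis omnibus test over the replicate RQ values grouped by
#' strain, with Dunn's post hoc comparisons against the calibrator
#' (delegates to [kruskal_dunn()]).
#'
#' @param rq An `rq_result` or a tibble with `strain` and `rq` columns.
#' @param reference Reference strain (default `WT`).
#' @param ... Passed to [kruskal_dunn()] (`adjust`, `tier_map`).
#' @return See [kruskal_dunn()].
#' @export
compare_rq_groups <- function(rq, reference = "WT", ...) {
  tbl <- if (inherits(rq, "rq_result")) rq$replicates else as_tibble(rq)
  kruskal_dunn(tbl$rq, tbl$strain, reference = reference, ...)
}
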