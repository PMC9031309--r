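# Scoring for arrayed over-expression screens: replicate summaries,
# per-plate Z-normalization, the change-from-vector (deltaV) statistic,
# candidate calling, cross-condition aggregation and Venn partitioning.

#' Average technical replicates of a colony-size table
#'
#' Collapses a long measurement table to one row per
#' (plate, gene, plasmid, condition): the mean and sample SD (n - 1
#' denominator) of the technical-replicate colony sizes on the chosen day.
#'
#' @param table Measurement tibble with columns `plate`, `gene`, `plasmid`,
#'   `condition`, `replicate`, `day`, `colony_px`.
#' @param day Imaging day to score; `NULL` (default) uses the latest day
#'   present.
#' @return Tibble with `plate`, `gene`, `plasmid`, `condition`, `mean_px`,
#'   `sd_px`, `n_reps`. Keys with a single replicate get `sd_px = NA` with
#'   a warning.
#' @export
summarize_replicates <- function(table, day = NULL) {
  stopifnot(all(c("plate", "gene", "plasmid", "condition", "colony_px") %in%
                  names(table)))
  if (!"day" %in% names(table)) table$day <- 1L
  if (is.null(day)) day <- max(table$day)
  tbl <- dplyr::filter(table, .data$day == !!day)
  if (nrow(tbl) == 0L) stop("no measurements on day ", day)
  out <- tbl |>
    dplyr::group_by(.data$plate, .data$gene, .data$plasmid, .data$condition) |>
    dplyr::summarise(mean_px = mean(.data$colony_px),
                     sd_px = stats::sd(.data$colony_px),
                     n_reps = dplyr::n(), .groups = "drop")
  if (any(out$n_reps < 2L)) {
    warning(sum(out$n_reps < 2L),
            " strain/arm combination(s) have a single replicate; SD undefined")
  }
  out
}

#' Z-score values within one normalization stratum
#'
#' Centers and scales with the stratum mean and sample SD. A stratum whose
#' SD is zero (all values identical) has no defined Z-scores; all values
#' come back `NA` with a warning so the caller can exclude the stratum from
#' candidate calling.
#'
#' @param values Numeric vector (e.g. per-strain mean colony sizes of one
#'   plate x plasmid x condition stratum).
#' @return Numeric vector of Z-scores (mean 0, sample SD 1), or all `NA`
#'   for a degenerate stratum.
#' @examples
#' plate_zscore(c(1, 2, 3))  # -1 0 1
#' @export
plate_zscore <- function(values) {
  values <- as.numeric(values)
  ok <- !is.na(values)
  if (sum(ok) < 2L) {
    warning("stratum has fewer than 2 values; Z undefined")
    return(rep(NA_real_, length(values)))
  }
  s <- stats::sd(values[ok])
  if (is.na(s) || s == 0) {
    warning("zero-SD stratum; Z undefined")
    return(rep(NA_real_, length(values)))
  }
  (values - mean(values[ok])) / s
}

#' Change-from-vector (deltaV) per gene
#'
#' Subtracts the vector-control value from the over-expression value for
#' each gene: positive deltaV means the strain grows better when the
#' arrestin is over-expressed than with empty vector. Inputs are normally
#' per-plate Z-scored means so the two arms are on a comparable scale.
#'
#' @param arrestin_values Named numeric vector (names = genes) for the
#'   over-expression arm.
#' @param vector_values Named numeric vector for the vector-control arm.
#' @return Named numeric vector of deltaV values, one per gene in
#'   `arrestin_values`; genes missing from the vector arm get `NA` with a
#'   warning.
#' @examples
#' compute_delta_v(c(a = -0.5), c(a = 1.0))  # -1.5
#' @export
compute_delta_v <- function(arrestin_values, vector_values) {
  stopifnot(!is.null(names(arrestin_values)), !is.null(names(vector_values)))
  missing <- setdiff(names(arrestin_values), names(vector_values))
  if (length(missing) > 0L) {
    warning("gene(s) missing from vector arm, deltaV undefined: ",
            paste(missing, collapse = ", "))
  }
  arrestin_values - vector_values[names(arrestin_values)]
}

#' Score an over-expression screen
#'
#' Full scoring pass over a colony-size measurement table: technical
#' replicates are averaged ([summarize_replicates()]); the per-strain means
#' are Z-scored within each plate x plasmid x condition stratum
#' ([plate_zscore()]); deltaV is computed per gene against the vector arm of
#' the same plate and condition ([compute_delta_v()]); and the deltaV values
#' are themselves Z-scored within each plate x plasmid x condition stratum.
#'
#' @param table Measurement tibble (see [summarize_replicates()]).
#' @param day Imaging day; `NULL` for the latest.
#' @param vector_plasmid Label of the empty-vector control arm.
#' @param dv_on_raw If `TRUE`, deltaV is computed on raw means instead of
#'   Z-scored means (the alternative reading of the normalization order).
#' @return A score tibble with one row per (plate, gene, plasmid, condition):
#'   `mean_px`, `sd_px`, `n_reps`, `plate_z`, `delta_v` (`NA` for the vector
#'   arm), `delta_v_z`.
#' @export
score_screen <- function(table, day = NULL, vector_plasmid = "vector",
                         dv_on_raw = FALSE) {
  summaries <- summarize_replicates(table, day = day)
  if (!vector_plasmid %in% summaries$plasmid) {
    stop("vector arm '", vector_plasmid, "' not present")
  }
  scored <- summaries |>
    dplyr::group_by(.data$plate, .data$plasmid, .data$condition) |>
    dplyr::mutate(plate_z = suppressWarnings(plate_zscore(.data$mean_px))) |>
    dplyr::ungroup()

  base_col <- if (dv_on_raw) "mean_px" else "plate_z"
  vec <- scored |>
    dplyr::filter(.data$plasmid == vector_plasmid) |>
    dplyr::select("plate", "condition", "gene",
                  vector_value = dplyr::all_of(base_col))
  scored <- scored |>
    dplyr::left_join(vec, by = c("plate", "condition", "gene")) |>
    dplyr::mutate(delta_v = ifelse(.data$plasmid == vector_plasmid,
                                   NA_real_,
                                   .data[[base_col]] - .data$vector_value)) |>
    dplyr::select(-"vector_value") |>
    dplyr::group_by(.data$plate, .data$plasmid, .data$condition) |>
    dplyr::mutate(delta_v_z = if (all(is.na(.data$delta_v))) NA_real_ else
      suppressWarnings(plate_zscore(.data$delta_v))) |>
    dplyr::ungroup()
  scored
}

#' Call per-condition candidate modifiers
#'
#' A gene is a candidate for a given over-expression arm and condition when
#' the magnitude of its deltaV Z-score exceeds `z_cutoff` and (when the size
#' filter is on) the magnitude of its plate Z-score exceeds `size_cutoff` —
#' i.e. the strain both deviates from the plate's typical colony size and
#' differs from its own vector control. Ties at a cutoff are non-candidates
#' (strict inequality). Genes with undefined Z in a stratum are excluded
#' from that stratum's calls with a warning.
#'
#' @param score_table Output of [score_screen()].
#' @param z_cutoff Threshold on `|delta_v_z|` (default 1.2).
#' @param require_size_deviation Apply the plate-size filter (default TRUE).
#' @param size_cutoff Threshold on `|plate_z|` (default 1.25).
#' @return The score table (vector-arm rows dropped) with logical columns
#'   `dv_flag`, `size_flag`, `candidate`.
#' @export
call_condition_candidates <- function(score_table, z_cutoff = 1.2,
                                      require_size_deviation = TRUE,
                                      size_cutoff = 1.25) {
  stopifnot(all(c("delta_v_z", "plate_z") %in% names(score_table)))
  calls <- dplyr::filter(score_table, .data$plasmid %in%
                           unique(score_table$plasmid[!is.na(score_table$delta_v)]))
  n_undef <- sum(is.na(calls$delta_v_z) |
                   (require_size_deviation & is.na(calls$plate_z)))
  if (n_undef > 0L) {
    warning(n_undef, " row(s) with undefined Z excluded from calling")
  }
  calls |>
    dplyr::mutate(
      dv_flag = !is.na(.data$delta_v_z) & abs(.data$delta_v_z) > z_cutoff,
      size_flag = !is.na(.data$plate_z) & abs(.data$plate_z) > size_cutoff,
      candidate = .data$dv_flag &
        (!require_size_deviation | .data$size_flag)
    )
}

#' Extract per-arm, per-condition candidate gene sets
#'
#' @param calls Output of [call_condition_candidates()].
#' @return Nested named list: `sets[[plasmid]][[condition]]` = character
#'   vector of candidate genes.
#' @export
candidate_sets <- function(calls) {
  stopifnot("candidate" %in% names(calls))
  hits <- dplyr::filter(calls, .data$candidate)
  out <- list()
  for (p in unique(calls$plasmid)) {
    out[[p]] <- list()
    for (cond in unique(calls$condition)) {
      out[[p]][[cond]] <-
        sort(unique(hits$gene[hits$plasmid == p & hits$condition == cond]))
    }
  }
  out
}

#' Default grouping of media conditions
#'
#' Collapses the two salt arms into a single "salt" condition, so the
#' screen's media form three condition groups: control, salt (hit in either
#' NaCl concentration) and rapamycin.
#'
#' @return Named character vector mapping condition label to group.
#' @export
default_condition_map <- function() {
  c(control = "control", NaCl_0.8M = "salt", NaCl_1.5M = "salt",
    rapamycin_50ng_mL = "rapamycin")
}

#' Aggregate candidate sets across conditions
#'
#' Returns the genes present in at least `min_conditions` of the supplied
#' per-condition candidate sets.
#'
#' @param condition_sets Named list of character vectors, one per condition
#'   (or condition group).
#' @param min_conditions Minimum number of distinct condition sets a gene
#'   must appear in (default 2).
#' @return Sorted character vector of aggregated candidate genes.
#' @examples
#' aggregate_candidates(list(control = "a", salt = c("a", "b"),
#'                           rapamycin = "b"))  # a and b
#' @export
aggregate_candidates <- function(condition_sets, min_conditions = 2) {
  if (length(condition_sets) < min_conditions) {
    stop("fewer condition sets (", length(condition_sets),
         ") than min_conditions (", min_conditions, ")")
  }
  tallies <- table(unlist(lapply(condition_sets, unique)))
  sort(names(tallies)[tallies >= min_conditions])
}

#' Build the full candidate report
#'
#' Maps conditions to condition groups, pools the two over-expression arms
#' per gene within each group (a gene counts as a hit for a group if it is a
#' candidate for either arrestin in any condition of the group), aggregates
#' across groups, and computes Venn partitions.
#'
#' @param calls Output of [call_condition_candidates()].
#' @param min_conditions Condition groups required for aggregation.
#' @param condition_map Named map condition -> group; defaults to
#'   [default_condition_map()] (unmapped conditions keep their own label).
#' @return List with `per_arm` (per plasmid x condition sets), `grouped`
#'   (per plasmid x condition-group sets), `pooled_grouped` (arms pooled),
#'   `aggregated` (pooled, >= min_conditions groups), `aggregated_per_arm`,
#'   and `venn` (exclusive-region counts; see [venn_partition()]).
#' @export
candidate_report <- function(calls, min_conditions = 2,
                             condition_map = default_condition_map()) {
  sets <- candidate_sets(calls)
  group_of <- function(cond) {
    ifelse(cond %in% names(condition_map), condition_map[cond], cond)
  }
  grouped <- lapply(sets, function(by_cond) {
    g <- split(by_cond, group_of(names(by_cond)))
    lapply(g, function(x) sort(unique(unlist(x))))
  })
  groups <- sort(unique(unlist(lapply(grouped, names))))
  pooled <- stats::setNames(lapply(groups, function(g) {
    sort(unique(unlist(lapply(grouped, function(x) x[[g]]))))
  }), groups)
  arms <- names(sets)
  list(
    per_arm = sets,
    grouped = grouped,
    pooled_grouped = pooled,
    aggregated = aggregate_candidates(pooled, min_conditions),
    aggregated_per_arm = lapply(grouped, aggregate_candidates,
                                min_conditions = min_conditions),
    venn = if (length(arms) == 2L) {
      venn_partition(grouped[[arms[1]]], grouped[[arms[2]]])
    } else {
      lapply(grouped, venn_regions)
    }
  )
}

#' Exclusive Venn regions of a list of sets
#'
#' Enumerates every membership pattern over the supplied sets and counts the
#' elements falling exclusively in each region; region counts sum to the
#' union's cardinality, and summing all regions containing a set recovers
#' that set's cardinality.
#'
#' @param sets Named list of character vectors.
#' @return Tibble with one row per non-empty region: `pattern` (set names
#'   joined by `&`), `count`, `members`.
#' @examples
#' venn_regions(list(A = c("a", "b"), B = c("b", "c")))
#' @export
venn_regions <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  universe <- sort(unique(unlist(sets)))
  if (length(universe) == 0L) {
    return(tibble(pattern = character(), count = integer(),
                  members = list()))
  }
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe),
                       dimnames = list(universe, names(sets)))
  pattern <- apply(membership, 1L, function(m)
    paste(names(sets)[m], collapse = "&"))
  regions <- split(universe, pattern)
  tibble(pattern = names(regions),
         count = lengths(regions),
         members = unname(regions))
}

#' Venn partition for two over-expression arms
#'
#' For each arm, the exclusive regions of its per-condition(-group) sets;
#' plus, per condition group, the overlap between the two arms' candidates.
#'
#' @param arm1_sets,arm2_sets Named lists of per-condition candidate gene
#'   vectors (same condition names).
#' @return List with per-arm region tibbles (named after nothing in
#'   particular: `arm1`, `arm2`) and `overlap`, a tibble with one row per
#'   condition: counts only-in-arm1, shared, only-in-arm2.
#' @export
venn_partition <- function(arm1_sets, arm2_sets) {
  conds <- union(names(arm1_sets), names(arm2_sets))
  overlap <- dplyr::bind_rows(lapply(conds, function(cond) {
    a <- arm1_sets[[cond]] %||% character()
    b <- arm2_sets[[cond]] %||% character()
    tibble(condition = cond,
           arm1_only = length(setdiff(a, b)),
           both = length(intersect(a, b)),
           arm2_only = length(setdiff(b, a)))
  }))
  list(arm1 = venn_regions(arm1_sets),
       arm2 = venn_regions(arm2_sets),
       overlap = overlap)
}

#' Recall and false-positive rate of candidate calls against planted truth
#'
#' Compares per-(gene, plasmid, condition) candidate calls with the
#' planted-modifier table of a [simulate_screen_plates()] run.
#'
#' @param calls Output of [call_condition_candidates()].
#' @param truth Planted-modifier tibble (`sim$truth`).
#' @return List with `recall` (fraction of planted arms called), `fpr`
#'   (fraction of unplanted arms called), `n_planted`, `n_null`.
#' @export
evaluate_screen_calls <- function(calls, truth) {
  key <- function(d) paste(d$gene, d$plasmid, d$condition, sep = "\r")
  planted <- unique(key(truth))
  calls <- dplyr::filter(calls, !is.na(.data$delta_v_z))
  is_planted <- key(calls) %in% planted
  list(
    recall = if (any(is_planted)) mean(calls$candidate[is_planted]) else NA_real_,
    fpr = if (any(!is_planted)) mean(calls$candidate[!is_planted]) else NA_real_,
    n_planted = sum(is_planted),
    n_null = sum(!is_planted)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
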