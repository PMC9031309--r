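# Shared statistics: Kruskal-Wallis omnibus + Dunn's post hoc z-tests,
# Welch's t, and the significance-tier symbol scheme used on all figures.

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Runs the Kruskal-Wallis rank-sum test across groups, then Dunn's z-tests
#' for pairwise comparisons (all pairs, or each group against a designated
#' reference), with a multiplicity adjustment over the comparisons actually
#' made. Ties are handled with mid-ranks and the standard tie correction both
#' in the omnibus H statistic and in Dunn's pooled variance.
#'
#' Dunn's z for groups \eqn{i, j} is
#' \deqn{z = (\bar R_i - \bar R_j) / \sqrt{\left(\frac{N(N+1)}{12} -
#'   \frac{\sum_t (t^3 - t)}{12(N-1)}\right)\left(\frac{1}{n_i} +
#'   \frac{1}{n_j}\right)}}
#' where \eqn{\bar R} are mean mid-ranks over the pooled sample of size
#' \eqn{N} and the sum runs over tie groups of size \eqn{t}. Two-sided
#' p-values use the normal approximation.
#'
#' @param x Either a named list of numeric vectors (one per group) or a
#'   numeric vector of values (then `g` is required).
#' @param g Group labels, parallel to `x`, when `x` is a vector.
#' @param reference Optional group label; if supplied only comparisons
#'   against this group are made (and adjusted over), otherwise all pairs.
#' @param adjust Multiplicity adjustment: `"bonferroni"` (default, the
#'   common reading of "Dunn's post hoc correction"), `"holm"`, `"sidak"`,
#'   or `"none"`.
#' @param tier_map Symbol scheme passed to [significance_tier()].
#' @return A list with elements `H` (tie-corrected statistic), `df`,
#'   `p_omnibus`, and `comparisons`, a tibble with columns `group1`,
#'   `group2`, `z`, `p`, `p_adj`, `tier`.
#' @examples
#' g <- list(WT = c(1, 2, 3), mutA = c(4, 5, 6), mutB = c(2, 3, 4))
#' kruskal_dunn(g, reference = "WT")
#' @export
kruskal_dunn <- function(x, g = NULL, reference = NULL,
                         adjust = c("bonferroni", "holm", "sidak", "none"),
                         tier_map = c("lenient", "conventional")) {
  adjust <- match.arg(adjust)
  groups <- as_grouped_values(x, g)
  ns <- lengths(groups)
  if (length(groups) < 2L) stop("at least 2 groups are required")
  small <- names(groups)[ns < 2L]
  if (length(small) > 0L) {
    stop("group(s) with fewer than 2 values: ", paste(small, collapse = ", "))
  }
  if (!is.null(reference) && !reference %in% names(groups)) {
    stop("reference group '", reference, "' not found")
  }

  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), ns), levels = names(groups))
  kw <- stats::kruskal.test(values, labels)

  r <- rank(values)          # mid-ranks
  n_tot <- length(values)
  mean_rank <- tapply(r, labels, mean)
  tie_sizes <- table(values)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (n_tot - 1))
  var_base <- n_tot * (n_tot + 1) / 12 - tie_term

  if (is.null(reference)) {
    pairs <- utils::combn(names(groups), 2L)
    g1 <- pairs[1L, ]
    g2 <- pairs[2L, ]
  } else {
    g1 <- setdiff(names(groups), reference)
    g2 <- rep(reference, length(g1))
  }
  if (var_base <= 0) {
    # every pooled value tied: no rank variation, nothing to compare
    z <- rep(0, length(g1))
  } else {
    z <- as.numeric((mean_rank[g1] - mean_rank[g2]) /
                      sqrt(var_base * (1 / ns[g1] + 1 / ns[g2])))
  }
  p <- 2 * stats::pnorm(-abs(z))
  p_adj <- adjust_p(p, adjust)

  # fully tied pooled sample: the tie correction degenerates; H is 0
  list(
    H = if (var_base <= 0) 0 else unname(kw$statistic),
    df = unname(kw$parameter),
    p_omnibus = if (var_base <= 0) 1 else kw$p.value,
    comparisons = tibble(
      group1 = g1, group2 = g2, z = z, p = p, p_adj = p_adj,
      tier = significance_tier(p_adj, map = tier_map)
    )
  )
}

as_grouped_values <- function(x, g = NULL) {
  if (is.list(x)) {
    if (is.null(names(x))) names(x) <- paste0("group", seq_along(x))
    groups <- lapply(x, as.numeric)
  } else {
    if (is.null(g)) stop("`g` is required when `x` is a vector")
    stopifnot(length(x) == length(g))
    groups <- split(as.numeric(x), factor(g, levels = unique(g)))
  }
  if (!all(vapply(groups, function(v) all(is.finite(v)), logical(1)))) {
    stop("all values must be finite")
  }
  groups
}

adjust_p <- function(p, method) {
  if (method == "sidak") {
    pmin(1, 1 - (1 - p)^length(p))
  } else {
    stats::p.adjust(p, method = if (method == "none") "none" else method)
  }
}

#' Welch's two-sample t-test
#'
#' Thin contract-checked wrapper around the unequal-variance t-test:
#' Welch statistic, Welch-Satterthwaite degrees of freedom, two-sided p.
#'
#' @param a,b Numeric vectors, each with at least 2 values; at least one
#'   group must have nonzero variance.
#' @return A list with `t`, `df`, `p`.
#' @examples
#' welch_t(c(10, 12, 11), c(20, 24, 22))
#' @export
welch_t <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 values")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("Welch test undefined: both groups have zero variance")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Map p-values to significance symbols
#'
#' The default (`"lenient"`) map reproduces the symbol scheme used on the
#' figures this pipeline feeds: `***` for p < 0.001, `**` for p < 0.01,
#' `*` for p < 0.1, `ns` otherwise. The `"conventional"` map uses the usual
#' 0.05/0.01/0.001 boundaries.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param map `"lenient"` (default) or `"conventional"`.
#' @return Character vector of symbols.
#' @examples
#' significance_tier(c(0.0005, 0.05, 0.5))
#' @export
significance_tier <- function(p, map = c("lenient", "conventional")) {
  map <- match.arg(map)
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  star_cut <- if (map == "lenient") 0.1 else 0.05
  out <- rep("ns", length(p))
  out[p < star_cut] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out
}
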