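# Shared fixtures: small, fast configurations used across test files.

tiny_screen <- function(seed = 1, ...) {
  simulate_screen_plates(screen_sim_config(n_strains = 24, seed = seed, ...))
}

small_field <- function(n_cells = 10, seed = 3, ...) {
  simulate_microscopy_field(field_sim_config(n_cells = n_cells,
                                             image_shape = c(192, 192),
                                             seed = seed, ...))
}

# exhaustive Welch t closed form (independent of stats::t.test)
welch_oracle <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  se2 <- va / length(a) + vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                   (vb / length(b))^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# brute-force Kruskal-Wallis H with tie correction, straight from ranks
kw_oracle <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  n <- length(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# exhaustive permutation distribution of the rank-mean difference between
# group 1 and group 2 of three equal-size groups (all assignments of the
# pooled values to the three groups)
dunn_permutation_p <- function(groups) {
  x <- unlist(groups)
  n <- lengths(groups)
  stopifnot(length(groups) == 3L)
  r <- rank(x)
  idx <- seq_along(x)
  obs <- abs(mean(r[seq_len(n[1])]) -
               mean(r[seq_len(n[2]) + n[1]]))
  first <- utils::combn(idx, n[1])
  count <- 0L; total <- 0L
  for (i in seq_len(ncol(first))) {
    g1 <- first[, i]
    rest <- setdiff(idx, g1)
    second <- utils::combn(rest, n[2])
    for (j in seq_len(ncol(second))) {
      g2 <- second[, j]
      stat <- abs(mean(r[g1]) - mean(r[g2]))
      total <- total + 1L
      if (stat >= obs - 1e-12) count <- count + 1L
    }
  }
  count / total
}
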