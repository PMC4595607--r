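# Independent oracles used across tests. These deliberately avoid the
# package's vectorised code paths: plain loops, combn enumeration, textbook
# formulas.

# All moderated statistics under exhaustive relabeling of a two-group design,
# computed per assignment with the scalar statistic. Returns a matrix
# proteins x assignments over ALL choose(n, n_a) assignments, with a logical
# attribute marking the trivial ones (identity / complement).
oracle_enumerated_null <- function(X, group, bait, s0) {
  idx_bait <- which(group == bait)
  n <- length(group); na <- length(idx_bait)
  assignments <- combn(n, na, simplify = FALSE)
  trivial <- vapply(assignments, function(a) {
    identical(a, idx_bait) ||
      (2 * na == n && identical(a, sort(setdiff(seq_len(n), idx_bait))))
  }, logical(1))
  d <- sapply(assignments, function(a) {
    apply(X, 1, function(row) {
      s0_statistic(row[a], row[setdiff(seq_len(n), a)], s0)
    })
  })
  attr(d, "trivial") <- trivial
  d
}

# Benjamini-Hochberg step-up, written from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# One-way ANOVA F from explicit sums of squares.
oracle_anova_f <- function(values, groups) {
  groups <- as.factor(groups)
  grand <- mean(values)
  ss_between <- sum(tapply(values, groups, function(v)
    length(v) * (mean(v) - grand)^2))
  ss_within <- sum(tapply(values, groups, function(v)
    sum((v - mean(v))^2)))
  df_b <- nlevels(groups) - 1
  df_w <- length(values) - nlevels(groups)
  (ss_between / df_b) / (ss_within / df_w)
}

# Paint a disk into a matrix (used to build image fixtures).
paint_disk <- function(m, cy, cx, radius, value) {
  rows <- seq_len(nrow(m)); cols <- seq_len(ncol(m))
  d2 <- outer((rows - cy)^2, (cols - cx)^2, `+`)
  m[d2 <= radius^2] <- value
  m
}

# Small helper: simulated two-group log2 matrix with optional spiked rows.
sim_log2_matrix <- function(n_bg, n_spiked = 0, effect = 0, nr = 3,
                            sd = 0.3, seed = 1) {
  set.seed(seed)
  n <- n_bg + n_spiked
  mu <- runif(n, 22, 32)
  X <- matrix(rnorm(n * 2 * nr, mu, sd), ncol = 2 * nr)
  if (n_spiked > 0)
    X[seq_len(n_spiked) + n_bg, seq_len(nr)] <-
      X[seq_len(n_spiked) + n_bg, seq_len(nr)] + effect
  rownames(X) <- sprintf("p%04d", seq_len(n))
  colnames(X) <- c(paste0("b", seq_len(nr)), paste0("c", seq_len(nr)))
  X
}

# Wrap a log2 matrix as an already-transformed intensity table.
as_log2_table <- function(X, nr = ncol(X) / 2) {
  intensity_table(X, group = rep(c("bait", "control"),
                                 c(nr, ncol(X) - nr)),
                  bait = "bait", log2_transformed = TRUE)
}
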