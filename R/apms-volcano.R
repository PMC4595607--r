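#' S0-moderated two-sample statistic
#'
#' The moderated statistic `d = (mean_a - mean_b) / (se_pooled + s0)`, where
#' `se_pooled` is the classical equal-variance two-sample standard error. The
#' constant `s0` damps the significance of tiny between-group differences that
#' happen to come with tiny variance; with `s0 = 0` the statistic reduces
#' exactly to Student's equal-variance t.
#'
#' @param group_a,group_b numeric vectors of at least 2 values each.
#' @param s0 non-negative moderation constant (default 0.1).
#' @return the moderated statistic (a single number).
#' @export
s0_statistic <- function(group_a, group_b, s0 = 0.1) {
  stopifnot(s0 >= 0)
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 values",
                               call. = FALSE)
  delta <- mean(group_a) - mean(group_b)
  sp2 <- ((na - 1) * var(group_a) + (nb - 1) * var(group_b)) / (na + nb - 2)
  se <- sqrt(sp2) * sqrt(1 / na + 1 / nb)
  denom <- se + s0
  if (denom == 0) return(if (delta == 0) 0 else sign(delta) * Inf)
  delta / denom
}

# Vectorised engine: moderated statistics for every protein under a set of
# group-A assignments. X is proteins x samples (log2 scale, NA allowed);
# assign is a logical matrix samples x K marking group-A membership.
# Returns list(d, delta, se, df) of proteins x K matrices.
d_stat_matrix <- function(X, assign, s0) {
  obs <- !is.na(X)
  # centre each protein row: d is invariant, and small magnitudes avoid
  # cancellation error in the sum-of-squares variance path
  ctr <- rowMeans(X, na.rm = TRUE)
  ctr[is.nan(ctr)] <- 0
  X <- X - ctr
  X0 <- X; X0[!obs] <- 0
  X2 <- X0^2
  W <- assign * 1
  SA <- X0 %*% W;  CA <- obs %*% W;  SSA <- X2 %*% W
  St <- rowSums(X0); Ct <- rowSums(obs); SSt <- rowSums(X2)
  SB <- St - SA; CB <- Ct - CA; SSB <- SSt - SSA
  ok <- CA >= 2 & CB >= 2
  mA <- SA / CA; mB <- SB / CB
  delta <- mA - mB
  sp2 <- (SSA - CA * mA^2 + SSB - CB * mB^2) / (CA + CB - 2)
  sp2[sp2 < 0] <- 0  # guard against negative rounding residue
  se <- sqrt(sp2) * sqrt(1 / CA + 1 / CB)
  denom <- se + s0
  d <- delta / denom
  d[denom == 0] <- sign(delta[denom == 0]) * Inf
  d[denom == 0 & delta == 0] <- 0
  d[!ok] <- NA_real_
  delta[!ok] <- NA_real_
  se[!ok] <- NA_real_
  list(d = d, delta = delta, se = se, df = CA + CB - 2)
}

# Group-A index sets for the permutation null. The identity assignment (and,
# for balanced designs, its complement) reproduces the observed statistics
# exactly and is excluded: keeping it would put a hard floor of 1/B (2/B when
# balanced) on every estimated FDR, which makes small designs such as 3v3
# unable to reach conventional thresholds. Enumerates all non-trivial
# assignments when there are at most n_permutations of them, otherwise samples
# uniformly (with possible repetition).
relabelings <- function(group, bait, n_permutations = 250L, seed = NULL) {
  n <- length(group)
  idx_bait <- which(group == bait)
  na <- length(idx_bait)
  n_distinct <- choose(n, na)
  balanced <- (2L * na == n)
  n_nontrivial <- n_distinct - 1L - as.integer(balanced)
  if (n_nontrivial < 2L)
    stop("fewer than 2 distinct non-trivial relabelings; cannot build a null",
         call. = FALSE)
  is_trivial <- function(a) {
    identical(a, idx_bait) ||
      (balanced && identical(a, setdiff(seq_len(n), idx_bait)))
  }
  if (n_nontrivial <= n_permutations) {
    all_a <- combn(n, na, simplify = FALSE)
    all_a <- Filter(function(a) !is_trivial(a), all_a)
    out <- all_a
  } else {
    out <- with_seed(seed, {
      res <- vector("list", n_permutations)
      b <- 1L
      while (b <= n_permutations) {
        a <- sort(sample.int(n, na))
        if (!is_trivial(a)) { res[[b]] <- a; b <- b + 1L }
      }
      res
    })
  }
  assign <- matrix(FALSE, n, length(out))
  for (j in seq_along(out)) assign[out[[j]], j] <- TRUE
  assign
}

#' Permutation-FDR volcano scoring of a bait-versus-control intensity table
#'
#' Computes, per protein, the log2 enrichment `delta` (bait minus control
#' group mean), the S0-moderated statistic, and a classical equal-variance
#' two-sided t-test p-value for the volcano y axis. A null distribution of
#' moderated statistics is built by recomputing all statistics under random
#' relabelings of the samples (all non-trivial relabelings are enumerated
#' exactly when there are at most `n_permutations` of them). The FDR at a
#' candidate cutoff `c` is estimated as
#' `(1 + mean null count of |d| >= c) / (observed count of |d| >= c)`,
#' clipped to `[0, 1]`; the add-one term regularises the estimate so a finite
#' permutation null can never report an FDR of exactly zero. Proteins at or
#' above the smallest candidate cutoff whose estimated FDR is at most `fdr_q`
#' are flagged significant. The reported `cutoff` attribute is the largest
#' non-significant |d| (so that significance is equivalent to strict
#' `|d| > cutoff`; a protein exactly at the reported cutoff is not
#' significant).
#'
#' @param table a filtered, log2-transformed (and optionally imputed)
#'   [intensity_table()].
#' @param s0 moderation constant (default 0.1).
#' @param fdr_q target FDR in (0, 1) (default 0.05).
#' @param n_permutations number of relabelings for the null (default 250).
#' @param seed seed for relabeling draws (only used when sampling).
#' @return a `data.frame` of class `volcano_records` with columns
#'   `protein_id`, `delta`, `d_s0`, `p_classic`, `significant`, `side`, and
#'   attributes `cutoff`, `fdr_at_cutoff`, `null_abs_d` (proteins x
#'   relabelings matrix), `params`.
#' @export
permutation_fdr <- function(table, s0 = 0.1, fdr_q = 0.05,
                            n_permutations = 250L, seed = NULL) {
  stopifnot(inherits(table, "intensity_table"),
            s0 >= 0, fdr_q > 0, fdr_q < 1, n_permutations >= 1)
  if (!table$log2_transformed)
    stop("log-transform the table first (log_transform_impute)", call. = FALSE)
  X <- table$intensities
  obs_assign <- matrix(table$group == table$bait, ncol = 1L)
  ob <- d_stat_matrix(X, obs_assign, s0)
  delta <- ob$delta[, 1L]; d <- ob$d[, 1L]; se <- ob$se[, 1L]
  dfree <- ob$df[, 1L]
  tstat <- ifelse(se > 0, delta / se, sign(delta) * Inf)
  tstat[se == 0 & delta == 0] <- 0
  p_classic <- 2 * pt(-abs(tstat), pmax(dfree, 1))

  assign <- relabelings(table$group, table$bait, n_permutations, seed)
  null_abs <- abs(d_stat_matrix(X, assign, s0)$d)
  B <- ncol(assign)

  obs_abs <- abs(d)
  usable <- !is.na(obs_abs)
  null_sorted <- sort(null_abs[!is.na(null_abs)])
  obs_sorted <- sort(obs_abs[usable])
  cand <- sort(unique(obs_abs[usable]), decreasing = TRUE)
  ge <- function(sorted, c) length(sorted) - findInterval(c * (1 - 1e-12),
                                                          sorted)
  n_null_ge <- vapply(cand, function(c) ge(null_sorted, c), numeric(1))
  n_obs_ge <- vapply(cand, function(c) ge(obs_sorted, c), numeric(1))
  est_fdr <- pmin(1, (1 + n_null_ge / B) / n_obs_ge)
  passing <- which(est_fdr <= fdr_q)
  if (length(passing)) {
    c_star <- min(cand[passing])
    significant <- usable & obs_abs >= c_star * (1 - 1e-12)
    fdr_at_cutoff <- est_fdr[passing[which.min(cand[passing])]]
  } else {
    significant <- rep(FALSE, length(d))
    fdr_at_cutoff <- NA_real_
  }
  cutoff <- if (any(!significant & usable))
    max(obs_abs[!significant & usable]) else 0
  if (!any(significant)) cutoff <- Inf

  side <- rep("none", length(d))
  side[significant & delta > 0] <- "enriched_in_bait"
  side[significant & delta < 0] <- "enriched_in_control"
  out <- data.frame(protein_id = rownames(X), delta = delta, d_s0 = d,
                    p_classic = p_classic, significant = significant,
                    side = side, stringsAsFactors = FALSE, row.names = NULL)
  structure(out,
            class = c("volcano_records", "data.frame"),
            cutoff = cutoff, fdr_at_cutoff = fdr_at_cutoff,
            null_abs_d = null_abs, se = se, df = dfree,
            params = list(s0 = s0, fdr_q = fdr_q,
                          n_permutations = n_permutations, B = B,
                          seed = seed, bait = table$bait,
                          n_bait = sum(table$group == table$bait),
                          n_control = sum(table$group != table$bait)))
}

#' Hyperbolic significance curve for volcano plots
#'
#' The locus in `(delta, -log10 p)` space on which the moderated statistic
#' equals the cutoff, for a given group design. Points above the curve (on
#' either side) are exactly the proteins with `|d_s0| > cutoff`. As `p -> 0`
#' the curve's `|delta|` asymptote approaches `cutoff * s0`; in the `s0 -> 0`
#' limit the curve flattens to a horizontal line of constant p.
#'
#' @param cutoff the |d_s0| cutoff (from [permutation_fdr()]).
#' @param s0 moderation constant used for the statistic.
#' @param n_a,n_b group sizes.
#' @param n_points number of curve samples per side.
#' @param se_max largest pooled standard error to trace out (controls how far
#'   the curve extends towards large p).
#' @return a `data.frame` with columns `delta`, `p_classic`, `neg_log10_p`,
#'   `side` (both branches).
#' @export
significance_curve <- function(cutoff, s0, n_a, n_b, n_points = 200L,
                               se_max = 5) {
  stopifnot(cutoff >= 0, s0 >= 0, n_a >= 2, n_b >= 2)
  dfree <- n_a + n_b - 2
  se <- seq(1e-9, se_max, length.out = n_points)
  delta <- cutoff * (se + s0)
  tval <- delta / se
  p <- 2 * pt(-abs(tval), dfree)
  pos <- data.frame(delta = delta, p_classic = p,
                    neg_log10_p = -log10(p), side = "enriched_in_bait")
  neg <- data.frame(delta = -delta, p_classic = p,
                    neg_log10_p = -log10(p), side = "enriched_in_control")
  rbind(pos, neg)
}

#' Classify volcano points by curve side
#'
#' Reconstructs, from `(delta, p_classic)` alone, whether a point lies above
#' the hyperbolic significance curve; agrees exactly with the significance
#' flags from [permutation_fdr()] for the same cutoff.
#'
#' @param delta log2 enrichment values.
#' @param p_classic classical two-sided equal-variance t p-values.
#' @param cutoff,s0 curve parameters.
#' @param n_a,n_b group sizes.
#' @return logical: above the curve (strictly)?
#' @export
curve_side <- function(delta, p_classic, cutoff, s0, n_a, n_b) {
  dfree <- n_a + n_b - 2
  tval <- stats::qt(1 - p_classic / 2, dfree)
  se <- ifelse(is.finite(tval) & tval > 0, abs(delta) / tval, 0)
  d <- ifelse(se + s0 > 0, abs(delta) / (se + s0),
              ifelse(abs(delta) > 0, Inf, 0))
  # small relative tolerance so the p -> se inversion cannot flip a point
  # sitting numerically on the curve
  d > cutoff + pmax(1e-12, cutoff * 1e-9)
}
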