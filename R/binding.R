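#' Normalized thermophoresis fluorescence from a trace
#'
#' `F_norm = F_hot / F_cold`, with the hot and cold fluorescence read from
#' the trace at the given time points (nearest sample; an optional symmetric
#' averaging window in seconds smooths instrument noise).
#'
#' @param time,fluorescence numeric vectors of equal length (seconds, counts).
#' @param hot_t,cold_t read-out times in seconds (defaults 34.5 and 5.5).
#' @param window full width of the averaging window in seconds (0 = single
#'   nearest sample).
#' @return the normalized fluorescence (a single number).
#' @export
compute_fnorm <- function(time, fluorescence, hot_t = 34.5, cold_t = 5.5,
                          window = 0) {
  stopifnot(length(time) == length(fluorescence), length(time) >= 2)
  if (hot_t > max(time) || hot_t < min(time))
    stop("trace does not cover hot_t", call. = FALSE)
  if (cold_t > max(time) || cold_t < min(time))
    stop("trace does not cover cold_t", call. = FALSE)
  at <- function(t0) {
    if (window > 0) {
      sel <- abs(time - t0) <= window / 2
      if (!any(sel)) sel <- which.min(abs(time - t0))
      mean(fluorescence[sel])
    } else fluorescence[which.min(abs(time - t0))]
  }
  f_cold <- at(cold_t)
  if (f_cold == 0) stop("zero cold fluorescence", call. = FALSE)
  at(hot_t) / f_cold
}

#' Post-mixing concentration grid of a twofold dilution series
#'
#' A twofold dilution series of the protein (n points, starting from
#' `start`), mixed in equal volumes with the labelled target, halving both:
#' the fitted ligand concentrations are `start/2, start/4, ...` and the
#' target sits at `target_stock/2` throughout.
#'
#' @param start pre-mix top protein concentration in uM (default 204).
#' @param n number of dilution points (default 16).
#' @param target_stock pre-mix labelled-target concentration in uM
#'   (default 0.1, i.e. 100 nM giving 50 nM final).
#' @return a `data.frame` with `ligand_pre_mix`, `ligand_total` (post-mix)
#'   and `target_total` (post-mix), all in uM, in decreasing concentration
#'   order.
#' @export
make_dilution_series <- function(start = 204, n = 16L, target_stock = 0.1) {
  stopifnot(start > 0, n >= 2, target_stock > 0)
  pre <- start / 2^(seq_len(n) - 1)
  data.frame(ligand_pre_mix = pre, ligand_total = pre / 2,
             target_total = target_stock / 2)
}

#' Bound fraction of the labelled target under 1:1 binding
#'
#' Exact solution of the 1:1 equilibrium at total concentrations (ligand
#' depletion form): the bound fraction is
#' `((L + T + Kd) - sqrt((L + T + Kd)^2 - 4 L T)) / (2 T)`, which stays in
#' `[0, 1]` and increases monotonically with ligand. For `T << Kd` it reduces
#' to the hyperbola `L / (L + Kd)`.
#'
#' @param ligand_total,target_total total concentrations (uM, vectorised over
#'   ligand).
#' @param kd dissociation constant (uM).
#' @return the bound fraction in `[0, 1]`.
#' @export
fraction_bound <- function(ligand_total, target_total, kd) {
  stopifnot(kd > 0, target_total > 0)
  s <- ligand_total + target_total + kd
  disc <- pmax(s^2 - 4 * ligand_total * target_total, 0)
  pmin(pmax((s - sqrt(disc)) / (2 * target_total), 0), 1)
}

#' Fit a dissociation constant to a normalized-fluorescence titration
#'
#' Least-squares fit of
#' `fnorm(L) = f_unbound + (f_bound - f_unbound) * fraction_bound(L, T, Kd)`
#' with the exact 1:1 (ligand-depletion) bound fraction; the simple hyperbola
#' `L / (L + Kd)` is available as `model = "hyperbolic"`. Starting values:
#' plateaus from the lowest/highest-concentration points, Kd from the
#' concentration closest to the half-transition. Fits that do not converge,
#' or whose Kd lands at a parameter bound, or where the series shows no
#' transition, are flagged.
#'
#' @param ligand_total ligand concentrations (uM, post-mixing).
#' @param fnorm normalized fluorescence per point.
#' @param target_total labelled-target concentration (uM, post-mixing;
#'   default 0.05).
#' @param model `"quadratic"` (default, ligand depletion) or `"hyperbolic"`.
#' @param kd_bounds admissible Kd range for the optimiser (uM).
#' @return an object of class `kd_estimate`: list with `kd`, `f_unbound`,
#'   `f_bound`, `converged`, `flagged`, `flag_reason`, `model`, `fitted`.
#' @export
fit_kd <- function(ligand_total, fnorm, target_total = 0.05,
                   model = c("quadratic", "hyperbolic"),
                   kd_bounds = c(1e-6, 1e6)) {
  model <- match.arg(model)
  stopifnot(length(ligand_total) == length(fnorm))
  if (length(ligand_total) < 6L)
    stop("need at least 6 titration points", call. = FALSE)
  ord <- order(ligand_total)
  L <- ligand_total[ord]; y <- fnorm[ord]
  flagged <- FALSE; reason <- NA_character_
  if (sd(y) < 1e-12 || abs(y[length(y)] - y[1]) < 1e-12) {
    return(structure(list(kd = NA_real_, f_unbound = mean(y),
                          f_bound = mean(y), converged = FALSE,
                          flagged = TRUE, flag_reason = "no transition",
                          model = model, fitted = rep(mean(y), length(y))),
                     class = "kd_estimate"))
  }
  f_u0 <- y[1]; f_b0 <- y[length(y)]
  half <- (f_u0 + f_b0) / 2
  kd0 <- L[which.min(abs(y - half))]
  kd0 <- min(max(kd0, kd_bounds[1] * 10), kd_bounds[2] / 10)
  frac <- function(Lv, kd) {
    if (model == "quadratic") fraction_bound(Lv, target_total, kd)
    else Lv / (Lv + kd)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ fu + (fb - fu) * frac(L, kd),
      start = list(fu = f_u0, fb = f_b0, kd = kd0),
      lower = c(-Inf, -Inf, kd_bounds[1]),
      upper = c(Inf, Inf, kd_bounds[2]),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(kd = NA_real_, f_unbound = f_u0, f_bound = f_b0,
                          converged = FALSE, flagged = TRUE,
                          flag_reason = "fit did not converge",
                          model = model, fitted = rep(NA_real_, length(y))),
                     class = "kd_estimate"))
  }
  est <- coef(fit)
  kd <- unname(est["kd"])
  at_bound <- kd <= kd_bounds[1] * (1 + 1e-6) || kd >= kd_bounds[2] * (1 - 1e-6)
  if (at_bound) { flagged <- TRUE; reason <- "kd at parameter bound" }
  structure(list(kd = kd, f_unbound = unname(est["fu"]),
                 f_bound = unname(est["fb"]), converged = TRUE,
                 flagged = flagged, flag_reason = reason, model = model,
                 fitted = unname(stats::fitted(fit))),
            class = "kd_estimate")
}

#' @export
print.kd_estimate <- function(x, ...) {
  if (is.na(x$kd)) cat("kd_estimate: flagged (", x$flag_reason, ")\n")
  else cat(sprintf(
    "kd_estimate: Kd = %.4g uM (plateaus %.4g -> %.4g, %s model)%s\n",
    x$kd, x$f_unbound, x$f_bound, x$model,
    if (x$flagged) paste0(" [flagged: ", x$flag_reason, "]") else ""))
  invisible(x)
}

#' Combine replicate Kd estimates
#'
#' The combined Kd is the mean of the replicate estimates; the uncertainty is
#' the standard error of that mean (`sd / sqrt(n)`).
#'
#' @param estimates a list of `kd_estimate` objects or a numeric vector of
#'   per-replicate Kd values (at least 2, all unflagged).
#' @return a list of class `kd_combined`: `kd`, `se`, `n`, `replicates`.
#' @export
combine_replicates <- function(estimates) {
  kds <- if (is.numeric(estimates)) estimates
         else vapply(estimates, function(e) e$kd, numeric(1))
  kds <- kds[!is.na(kds)]
  if (length(kds) < 2L)
    stop("need at least 2 replicate estimates for a standard error",
         call. = FALSE)
  structure(list(kd = mean(kds), se = sd(kds) / sqrt(length(kds)),
                 n = length(kds), replicates = kds),
            class = "kd_combined")
}

#' @export
print.kd_combined <- function(x, ...) {
  cat(sprintf("Kd = %.4g +/- %.4g uM (s.e., n = %d)\n", x$kd, x$se, x$n))
  invisible(x)
}

#' Fit every replicate series and combine
#'
#' @param series a `data.frame` with columns `ligand_total`, `fnorm`,
#'   `replicate`, or a list of such frames.
#' @param target_total labelled-target concentration (uM, post-mixing).
#' @param ... passed to [fit_kd()].
#' @return a list: `combined` (`kd_combined`), `fits` (per-replicate
#'   `kd_estimate`s).
#' @export
fit_binding_series <- function(series, target_total = 0.05, ...) {
  if (is.data.frame(series))
    series <- split(series, series$replicate)
  fits <- lapply(series, function(s)
    fit_kd(s$ligand_total, s$fnorm, target_total, ...))
  list(combined = combine_replicates(fits), fits = fits)
}
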