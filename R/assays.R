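# Quantitative channel-assay analysis: cumulative rubidium-86 efflux and
# rate-constant decomposition, Hill dose-response fitting, K(ATP) patch
# current extraction, and relative expression (2^-ddCt / Pfaffl).
#
# Efflux model: the cumulative released fraction follows
#   Efflux(t) = 1 - exp(-k1 * t)              (background, GFP-only cells)
#   Efflux(t) = 1 - exp(-(k1 + k2) * t)       (channel-expressing cells)
# with k1 the channel-independent and k2 the K(ATP)-dependent rate constant
# (per minute). Because the efflux diverges from a single exponential at late
# times, rates are fitted on the early window (2.5-12.5 min) only.

#' Cumulative efflux fractions from raw counts
#'
#' `fraction(t_i) = sum(released up to t_i) / (sum(all released) + lysate)`.
#'
#' @param released counts released per timepoint (same order as timepoints).
#' @param lysate residual intracellular counts recovered at lysis.
#' @return nondecreasing fractions in \[0, 1\].
#' @examples
#' cumulative_efflux(c(100, 50, 50), 800) # 0.10 0.15 0.20
#' @export
cumulative_efflux <- function(released, lysate) {
  stopifnot(all(released >= 0), lysate >= 0)
  total <- sum(released) + lysate
  if (total == 0) stop("all counts zero")
  cumsum(released) / total
}

# sum-of-squares fit of fraction = 1 - exp(-k * t) on a time window, with the
# rate bounded below at `k_floor`. One-parameter problem; initialized from the
# exact log-linearization and polished with bounded Levenberg-Marquardt.
fit_rate <- function(time, fraction, k_floor = 0, window = c(2.5, 12.5)) {
  keep <- time >= window[1] & time <= window[2]
  if (sum(keep) < 2) stop("need >= 2 timepoints inside the fit window")
  t <- time[keep]; y <- fraction[keep]
  if (all(y >= 1)) stop("degenerate data: all fractions >= 1")
  if (all(abs(y) < 1e-12))
    return(list(k = k_floor, window = window, residual_norm = 0,
                n_points = sum(keep)))
  y_ok <- pmin(y, 1 - 1e-12)
  k0 <- max(mean(-log(1 - y_ok) / t), k_floor)
  fit <- minpack.lm::nlsLM(
    y ~ 1 - exp(-k * t),
    start = list(k = max(k0, k_floor + 1e-9)),
    lower = k_floor,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  k <- unname(stats::coef(fit)["k"])
  list(k = k, window = window,
       residual_norm = sqrt(sum(stats::resid(fit)^2)),
       n_points = sum(keep))
}

#' Background efflux rate constant k1
#'
#' Least-squares fit of `Efflux = 1 - exp(-k1 t)` to pooled GFP-only
#' (channel-free) series, restricted to the early time window.
#'
#' @param time,fraction pooled timepoints (min) and cumulative fractions;
#'   replicates are concatenated.
#' @param window fit window in minutes (default 2.5-12.5).
#' @return list `k1`, `window`, `residual_norm`, `n_points`.
#' @export
fit_background_rate <- function(time, fraction, window = c(2.5, 12.5)) {
  f <- fit_rate(time, fraction, k_floor = 0, window = window)
  list(k1 = f$k, window = f$window, residual_norm = f$residual_norm,
       n_points = f$n_points)
}

#' K(ATP)-dependent efflux rate constant k2
#'
#' Fits `Efflux = 1 - exp(-(k1 + k2) t)` with `k1` held fixed at the
#' background estimate; the number of active channels is taken proportional
#' to k2.
#'
#' @param time,fraction pooled channel-expressing series.
#' @param k1 fixed background rate from [fit_background_rate()].
#' @param window fit window (default 2.5-12.5 min).
#' @return list `k2`, `k1`, `window`, `residual_norm`, `n_points`.
#' @export
fit_katp_rate <- function(time, fraction, k1, window = c(2.5, 12.5)) {
  stopifnot(k1 >= 0)
  f <- fit_rate(time, fraction, k_floor = k1, window = window)
  list(k2 = f$k - k1, k1 = k1, window = f$window,
       residual_norm = f$residual_norm, n_points = f$n_points)
}

#' Normalize currents and fit the Hill inhibition model
#'
#' Currents are divided by the basal (inhibitor-free) current, fixing
#' `Imax = 1`, and the three remaining parameters of
#' `I = Imin + (Imax - Imin) / (1 + ([X]/IC50)^H)`
#' are estimated by bounded least squares (`0 <= Imin <= 1`, `IC50 > 0`,
#' `H > 0`). IC50 is initialized at the geometric mean of the concentration
#' range and H at 1.
#'
#' @param concentration inhibitor concentrations (> 0, consistent units).
#' @param current raw currents at each concentration.
#' @param basal basal current used for normalization (default 1, i.e.
#'   `current` already normalized).
#' @return list `Imin`, `IC50`, `H`, `Imax` (= 1), `normalized`,
#'   `residual_norm`, `converged`.
#' @export
normalize_and_fit_hill <- function(concentration, current, basal = 1) {
  stopifnot(all(concentration > 0), basal > 0,
            length(concentration) == length(current))
  if (length(unique(concentration)) < 4)
    stop("need >= 4 distinct concentrations")
  y <- current / basal
  x <- concentration
  ic50_0 <- exp(mean(log(range(x))))
  imin_0 <- min(max(min(y), 0), 1)
  fit <- minpack.lm::nlsLM(
    y ~ imin + (1 - imin) / (1 + (x / ic50)^h),
    start = list(imin = imin_0, ic50 = ic50_0, h = 1),
    lower = c(0, .Machine$double.eps, .Machine$double.eps),
    upper = c(1, Inf, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  cf <- stats::coef(fit)
  conv <- fit$convInfo$isConv %||% TRUE
  if (!isTRUE(conv)) warning("Hill fit did not converge cleanly")
  list(Imin = unname(cf["imin"]), IC50 = unname(cf["ic50"]),
       H = unname(cf["h"]), Imax = 1, normalized = y,
       residual_norm = sqrt(sum(stats::resid(fit)^2)), converged = conv)
}

#' Hill model prediction (Imax fixed at 1)
#'
#' @param x concentration(s).
#' @param ic50,h,imin model parameters.
#' @return normalized current.
#' @export
hill_current <- function(x, ic50, h, imin = 0) {
  imin + (1 - imin) / (1 + (x / ic50)^h)
}

#' K(ATP) current from a patch record
#'
#' Difference between the current in nucleotide-free solution and the current
#' at a fully inhibiting nucleotide concentration (10 mM MgATP for mouse,
#' 5 mM ATP for zebrafish myocytes, both at -50 mV).
#'
#' @param i_free current without nucleotides (pA).
#' @param i_inhibited current at the fully inhibiting concentration (pA).
#' @param inhibitor_mm applied concentration (mM).
#' @param fully_inhibiting_mm declared threshold for full inhibition.
#' @return K(ATP) current in pA; negative values are returned with a warning.
#' @export
katp_current <- function(i_free, i_inhibited, inhibitor_mm = 10,
                         fully_inhibiting_mm = 10) {
  if (any(inhibitor_mm < fully_inhibiting_mm))
    stop("inhibitor concentration below the fully inhibiting level")
  out <- i_free - i_inhibited
  if (any(out < 0)) warning("inhibited current exceeds nucleotide-free current")
  out
}

#' Relative expression by the Pfaffl method
#'
#' `ratio = E_target^dCt_target / E_ref^dCt_ref`, with
#' `dCt = mean(WT Ct) - sample Ct` per gene. With both efficiencies equal to
#' 2 this reduces to the classical `2^-ddCt`.
#'
#' @param ct_target,ct_ref Ct values for the sample (scalars or vectors of
#'   technical replicates, averaged).
#' @param wt_ct_target,wt_ct_ref Ct values of the wild-type/calibrator pools.
#' @param e_target,e_ref amplification efficiencies in (1, 2\] (default 2).
#' @return fold change relative to the wild-type mean.
#' @examples
#' relative_expression(22, 18, 20, 18) # target 2 cycles later: 0.25
#' @export
relative_expression <- function(ct_target, ct_ref, wt_ct_target, wt_ct_ref,
                                e_target = 2, e_ref = 2) {
  stopifnot(e_target > 1, e_target <= 2, e_ref > 1, e_ref <= 2,
            all(c(ct_target, ct_ref, wt_ct_target, wt_ct_ref) > 0))
  d_target <- mean(wt_ct_target) - mean(ct_target)
  d_ref <- mean(wt_ct_ref) - mean(ct_ref)
  e_target^d_target / e_ref^d_ref
}

#' Two-group comparison
#'
#' Thin wrapper around the standard two-sided tests used throughout the
#' assay analyses.
#'
#' @param a,b numeric vectors (n >= 2 each).
#' @param test `"mann_whitney"` (exact where possible, ties handled) or
#'   `"t_two_tailed"`.
#' @param bonferroni_m optional number of comparisons; when given, the
#'   adjusted significance threshold `0.05 / m` is reported alongside.
#' @return list `statistic`, `p`, `test`, and optionally `threshold`.
#' @export
compare_groups <- function(a, b, test = c("mann_whitney", "t_two_tailed"),
                           bonferroni_m = NULL) {
  test <- match.arg(test)
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group")
  res <- if (test == "mann_whitney") {
    suppressWarnings(stats::wilcox.test(a, b, exact = NULL, correct = TRUE))
  } else {
    stats::t.test(a, b, var.equal = FALSE)
  }
  out <- list(statistic = unname(res$statistic), p = res$p.value, test = test)
  if (!is.null(bonferroni_m))
    out$threshold <- bonferroni_threshold(0.05, bonferroni_m)
  out
}
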