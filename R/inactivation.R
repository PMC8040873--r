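#' Construct a thermal-inactivation decay curve
#'
#' A decay curve is a time course of residual enzyme activity recorded
#' during incubation at an elevated temperature, typically followed for
#' more than two half-lives. Activities may be in any (relative) units;
#' all downstream fitting is scale-free.
#'
#' @param times Numeric vector of sampling times in minutes, strictly
#'   increasing, at least 4 points.
#' @param activities Numeric vector of enzyme activities (arbitrary
#'   units, >= 0), same length as `times`.
#' @param label Optional free-text label (condition, temperature, ion
#'   concentration).
#' @return An object of class `decay_curve`.
#' @export
decay_curve <- function(times, activities, label = "") {
  times <- as.numeric(times)
  activities <- as.numeric(activities)
  if (length(times) != length(activities))
    stop("'times' and 'activities' must have the same length")
  if (length(times) < 4L)
    stop("a decay curve needs at least 4 points")
  if (any(!is.finite(times)) || any(!is.finite(activities)))
    stop("times and activities must be finite")
  if (any(diff(times) <= 0))
    stop("'times' must be strictly increasing")
  if (any(activities < 0))
    stop("activities must be >= 0")
  structure(list(times = times, activities = activities,
                 label = as.character(label)[1L]),
            class = "decay_curve")
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf("Decay curve%s: %d points, t = %.3g..%.3g min\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Fit a mono-exponential inactivation decay
#'
#' Fits A(t) = A0 * exp(-k * t) by nonlinear least squares. The start
#' values are deterministic: A0 from the first activity and k from a
#' log-linear regression restricted to points above 5% of A0.
#'
#' @param curve A [decay_curve()] (or anything coercible via
#'   `decay_curve(times, activities)` when `activities` is given).
#' @param activities,label Optional; allow `fit_exponential_decay(times,
#'   activities)` shorthand.
#' @param plateau Logical; if `TRUE` an additive plateau term
#'   A(t) = A0 exp(-k t) + c is included. Off by default: the standard
#'   protocol follows decay to completion with no evidence of a floor.
#' @return An object of class `exp_decay_fit` with elements `k_obs`
#'   (min^-1), `A0`, `t_half` (= ln 2 / k_obs, minutes), `sse`,
#'   `plateau` (0 when disabled), `n`, and `label`.
#' @export
fit_exponential_decay <- function(curve, activities = NULL, label = "",
                                  plateau = FALSE) {
  if (!inherits(curve, "decay_curve"))
    curve <- decay_curve(curve, activities, label)
  t <- curve$times
  A <- curve$activities
  if (isTRUE(all(A == A[1L])))
    stop("no decay: activities are constant")

  ## deterministic start: log-linear regression on points > 5% of A0
  A0_start <- A[1L]
  keep <- A > 0.05 * A0_start & A > 0
  if (sum(keep) < 2L)
    stop("no decay: fewer than 2 usable points above 5% of initial activity")
  ll <- stats::lm(log(A[keep]) ~ t[keep])
  k_start <- -unname(stats::coef(ll)[2L])
  if (!is.finite(k_start) || k_start <= 0)
    stop("no decay: log-linear slope is non-negative")

  df <- data.frame(t = t, A = A)
  fit <- if (plateau) {
    minpack.lm::nlsLM(A ~ A0 * exp(-k * t) + c0, data = df,
                      start = list(A0 = A0_start, k = k_start, c0 = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    minpack.lm::nlsLM(A ~ A0 * exp(-k * t), data = df,
                      start = list(A0 = A0_start, k = k_start),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  cf <- stats::coef(fit)
  k <- unname(cf["k"])
  if (!is.finite(k) || k <= 0)
    stop("no decay: fitted rate constant is non-positive")
  structure(list(k_obs = k,
                 A0 = unname(cf["A0"]),
                 t_half = log(2) / k,
                 sse = sum(stats::residuals(fit)^2),
                 plateau = if (plateau) unname(cf["c0"]) else 0,
                 n = length(t),
                 label = curve$label),
            class = "exp_decay_fit")
}

#' @export
print.exp_decay_fit <- function(x, ...) {
  cat(sprintf("Mono-exponential decay fit%s:\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  cat(sprintf("  k_obs  = %.6g min^-1\n  t_half = %.6g min\n  sse    = %.4g (n = %d)\n",
              x$k_obs, x$t_half, x$sse, x$n))
  invisible(x)
}

#' Fold stabilization from two decay fits
#'
#' The fold increase in stability, in terms of half-life for loss of
#' activity, of a treated condition (e.g. + divalent ion) relative to a
#' reference condition: `treated$t_half / reference$t_half`.
#'
#' @param reference,treated Objects from [fit_exponential_decay()].
#' @return Dimensionless ratio of half-lives.
#' @export
fold_stabilization <- function(reference, treated) {
  stopifnot(inherits(reference, "exp_decay_fit"),
            inherits(treated, "exp_decay_fit"))
  treated$t_half / reference$t_half
}

#' Fit Michaelis-Menten kinetics
#'
#' Nonlinear least squares of v = kcat * S / (Km + S). Rates are assumed
#' pre-normalized per enzyme (so the plateau is kcat itself).
#'
#' @param substrate_mM Substrate concentrations, mM (>= 4 levels).
#' @param rate_per_min Rates, min^-1, same length.
#' @return Object of class `mm_fit` with `Km` (mM), `kcat` (min^-1),
#'   `kcat_over_Km` (M^-1 min^-1) and standard errors `se_Km`, `se_kcat`.
#' @export
fit_michaelis_menten <- function(substrate_mM, rate_per_min) {
  S <- as.numeric(substrate_mM)
  v <- as.numeric(rate_per_min)
  if (length(S) != length(v)) stop("substrate and rate lengths differ")
  if (length(unique(S)) < 4L) stop("need at least 4 substrate levels")
  if (any(S <= 0) || any(v < 0)) stop("substrate must be > 0 and rates >= 0")

  ## start values from the Lineweaver-Burk linearization (exact for
  ## noise-free data under any design, including saturating-only)
  pos <- v > 0
  lb <- stats::coef(stats::lm(y ~ x, data = data.frame(x = 1 / S[pos],
                                                       y = 1 / v[pos])))
  kcat_start <- 1 / lb[[1L]]
  Km_start <- lb[[2L]] * kcat_start
  if (!is.finite(kcat_start) || kcat_start <= 0 ||
      !is.finite(Km_start) || Km_start <= 0) {
    kcat_start <- max(v)
    Km_start <- S[which.min(abs(v - kcat_start / 2))]
  }
  df <- data.frame(S = S, v = v)
  fit <- minpack.lm::nlsLM(v ~ kcat * S / (Km + S), data = df,
                           start = list(kcat = kcat_start, Km = Km_start),
                           lower = c(kcat = 0, Km = 1e-12),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(kcat = NA_real_, Km = NA_real_))
  Km <- unname(cf["Km"]); kcat <- unname(cf["kcat"])
  if (min(S) > 5 * Km || max(S) < Km / 5)
    warning("substrate range shows little curvature (all S >> Km or all S << Km); ",
            "standard errors will be wide")
  structure(list(Km = Km, kcat = kcat,
                 kcat_over_Km = specificity_constant(Km, kcat),
                 se_Km = unname(se["Km"]), se_kcat = unname(se["kcat"]),
                 n = length(S)),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit (n = %d):\n", x$n))
  cat(sprintf("  Km      = %.4g mM (se %.3g)\n", x$Km, x$se_Km))
  cat(sprintf("  kcat    = %.4g min^-1 (se %.3g)\n", x$kcat, x$se_kcat))
  cat(sprintf("  kcat/Km = %.4g M^-1 min^-1\n", x$kcat_over_Km))
  invisible(x)
}

#' Specificity constant kcat/Km
#'
#' @param Km_mM Michaelis constant in mM (> 0).
#' @param kcat_per_min Turnover number in min^-1.
#' @return kcat/Km in M^-1 min^-1, i.e. `kcat / (Km * 1e-3)`.
#' @export
specificity_constant <- function(Km_mM, kcat_per_min) {
  if (any(Km_mM <= 0)) stop("Km must be > 0")
  kcat_per_min / (Km_mM * 1e-3)
}

#' Read a decay curve from CSV
#'
#' Expects columns `time_min,activity`.
#' @param path File path.
#' @param label Optional label for the curve.
#' @return A [decay_curve()].
#' @export
read_decay_csv <- function(path, label = basename(path)) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_min", "activity") %in% names(df)))
    stop("decay CSV must have columns 'time_min' and 'activity'")
  decay_curve(df$time_min, df$activity, label = label)
}

#' Read a Michaelis-Menten rate table from CSV
#'
#' Expects columns `substrate_mM,rate_per_min`.
#' @param path File path.
#' @return data.frame with the two columns.
#' @export
read_mm_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("substrate_mM", "rate_per_min") %in% names(df)))
    stop("kinetics CSV must have columns 'substrate_mM' and 'rate_per_min'")
  df
}
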