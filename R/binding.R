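#' Construct a binding model with independent site classes
#'
#' The isotherm is nu(c) = sum_i n_i K_i c / (1 + K_i c), the classical
#' independent-site-class model. Classes are stored sorted by descending
#' association constant.
#'
#' @param n Sites per catalytic subunit for each class (>= 0).
#' @param K Association constants, M^-1 (> 0), same length as `n`.
#' @return Object of class `binding_model` with element `classes`, a
#'   data.frame with columns `n` and `K`.
#' @export
binding_model <- function(n, K) {
  n <- as.numeric(n); K <- as.numeric(K)
  if (length(n) != length(K)) stop("'n' and 'K' must have the same length")
  if (any(n < 0)) stop("site counts must be >= 0")
  if (any(K <= 0)) stop("association constants must be > 0")
  ord <- order(K, decreasing = TRUE)
  structure(list(classes = data.frame(n = n[ord], K = K[ord])),
            class = "binding_model")
}

#' @export
print.binding_model <- function(x, ...) {
  cat("Independent-site binding model:\n")
  for (i in seq_len(nrow(x$classes)))
    cat(sprintf("  class %d: n = %.4g sites, K = %.4g M^-1\n",
                i, x$classes$n[i], x$classes$K[i]))
  invisible(x)
}

#' Bound ligand per subunit at given free-ligand concentrations
#'
#' @param model A [binding_model()].
#' @param c_free Free ligand concentration(s), M.
#' @return nu, moles bound per mole of catalytic subunit.
#' @export
nu_bound <- function(model, c_free) {
  stopifnot(inherits(model, "binding_model"))
  out <- numeric(length(c_free))
  for (i in seq_len(nrow(model$classes))) {
    Kc <- model$classes$K[i] * c_free
    out <- out + model$classes$n[i] * Kc / (1 + Kc)
  }
  out
}

#' Construct an EPR-style titration series
#'
#' A titration of protein with ligand observed through a signal that is
#' linear in the free-ion concentration, with the bound ion contributing
#' a fraction `alpha` of the free-ion amplitude:
#' I = gamma * (c_free + alpha * c_bound).
#'
#' @param ligand_total Total ligand concentrations, M, strictly increasing.
#' @param protein_total Catalytic-subunit concentration, M (scalar).
#' @param signal Observed signal intensities, arbitrary units.
#' @param alpha Bound-signal amplitude fraction (0 <= alpha < 1); the
#'   bound divalent ion typically retains ~5% of the free-ion amplitude.
#' @param gamma Signal per M of free ligand (calibration slope).
#' @return Object of class `titration_series`.
#' @export
titration_series <- function(ligand_total, protein_total, signal,
                             alpha = 0.05, gamma = 1) {
  ligand_total <- as.numeric(ligand_total)
  signal <- as.numeric(signal)
  if (length(signal) != length(ligand_total))
    stop("'signal' and 'ligand_total' must have the same length")
  if (any(ligand_total <= 0) || protein_total <= 0)
    stop("all concentrations must be > 0")
  if (any(diff(ligand_total) <= 0))
    stop("'ligand_total' must be strictly increasing")
  if (alpha < 0 || alpha > 1) stop("'alpha' must be in [0, 1]")
  if (gamma <= 0) stop("'gamma' must be > 0")
  structure(list(ligand_total = ligand_total,
                 protein_total = as.numeric(protein_total)[1L],
                 signal = signal, alpha = alpha, gamma = gamma),
            class = "titration_series")
}

#' Convert titration signals into bound/free ligand
#'
#' Inverts the linear signal model I = gamma*(c_free + alpha*c_bound)
#' with the mass balance c_free + c_bound = ligand_total:
#' c_free = (I/gamma - alpha*L) / (1 - alpha).
#' Tiny negative concentrations from noise (within `clamp_tol` of the
#' total) are clamped to zero with a warning; larger violations are a
#' data error.
#'
#' @param series A [titration_series()].
#' @param clamp_tol Relative tolerance for clamping small negatives
#'   (fraction of the total ligand at that point).
#' @return data.frame with columns `ligand_total`, `c_free`, `c_bound`,
#'   `nu` (= c_bound / protein_total).
#' @export
bound_from_signal <- function(series, clamp_tol = 0.02) {
  stopifnot(inherits(series, "titration_series"))
  if (series$alpha >= 1) stop("'alpha' must be < 1 to invert the signal")
  L <- series$ligand_total
  c_free <- (series$signal / series$gamma - series$alpha * L) /
    (1 - series$alpha)
  c_bound <- L - c_free
  tol <- clamp_tol * L
  if (any(c_free < -tol))
    stop("data error: implied free ligand is negative beyond tolerance")
  if (any(c_bound < -tol))
    stop("data error: implied bound ligand exceeds the total ligand")
  if (any(c_free < 0) || any(c_bound < 0)) {
    warning("small negative concentrations from noise clamped to 0")
    neg_f <- c_free < 0
    c_free[neg_f] <- 0; c_bound[neg_f] <- L[neg_f]
    neg_b <- c_bound < 0
    c_bound[neg_b] <- 0; c_free[neg_b] <- L[neg_b]
  }
  data.frame(ligand_total = L, c_free = c_free, c_bound = c_bound,
             nu = c_bound / series$protein_total)
}

#' Build Scatchard points (nu, nu/c)
#'
#' The Scatchard linearization nu/c = n*K - nu*K plots nu/c against nu;
#' for a single site class the points fall on a line with slope -K and
#' x-intercept n.
#'
#' @param bound data.frame from [bound_from_signal()] (needs columns
#'   `c_free` and `nu`).
#' @return data.frame of class `scatchard_data` with columns `nu` and
#'   `nu_over_c` (M^-1). Points with `c_free <= 0` are dropped with a
#'   warning.
#' @export
scatchard_points <- function(bound) {
  if (!all(c("c_free", "nu") %in% names(bound)))
    stop("'bound' must have columns 'c_free' and 'nu'")
  drop <- bound$c_free <= 0
  if (any(drop))
    warning(sprintf("dropping %d point(s) with non-positive free ligand",
                    sum(drop)))
  b <- bound[!drop, , drop = FALSE]
  out <- data.frame(nu = b$nu, nu_over_c = b$nu / b$c_free)
  class(out) <- c("scatchard_data", "data.frame")
  out
}

#' Fit a linear Scatchard segment
#'
#' Ordinary least squares of nu/c on nu over a nu window; for a
#' descending segment the association constant is the negated slope and
#' the site count the x-intercept. The classical high-affinity window
#' spans nu = 0.4-0.9.
#'
#' @param data Scatchard points from [scatchard_points()].
#' @param nu_range Length-2 numeric `(lo, hi)` window on nu.
#' @return Object of class `scatchard_segment_fit` with `n` (sites per
#'   subunit, x-intercept), `K` (M^-1), `nu_range`, `r2`, `n_points`.
#' @export
fit_scatchard_segment <- function(data, nu_range = c(0.4, 0.9)) {
  if (!all(c("nu", "nu_over_c") %in% names(data)))
    stop("'data' must have columns 'nu' and 'nu_over_c'")
  keep <- data$nu >= nu_range[1L] & data$nu <= nu_range[2L]
  if (sum(keep) < 3L)
    stop("need at least 3 points inside the nu window")
  fit <- stats::lm(nu_over_c ~ nu, data = data[keep, ])
  cf <- stats::coef(fit)
  slope <- unname(cf[2L]); intercept <- unname(cf[1L])
  if (slope >= 0)
    stop("not a binding segment: Scatchard slope is non-negative")
  y <- data$nu_over_c[keep]
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(n = -intercept / slope, K = -slope,
                 nu_range = nu_range,
                 r2 = r2,
                 n_points = sum(keep)),
            class = "scatchard_segment_fit")
}

#' @export
print.scatchard_segment_fit <- function(x, ...) {
  cat(sprintf("Scatchard segment fit (nu in [%.3g, %.3g], %d points):\n",
              x$nu_range[1L], x$nu_range[2L], x$n_points))
  cat(sprintf("  n = %.4g sites/subunit, K = %.4g M^-1, r^2 = %.4f\n",
              x$n, x$K, x$r2))
  invisible(x)
}

#' Fit a full multi-class binding model
#'
#' Nonlinear least squares of nu(c) = sum_i n_i K_i c / (1 + K_i c) for
#' one or two independent site classes, parameterized in log10(K) for
#' conditioning. Start values for the high-affinity class come from a
#' Scatchard segment fit on the lower-nu half of the data.
#'
#' @param c_free Free ligand concentrations, M.
#' @param nu Bound ligand per subunit, same length.
#' @param n_classes 1 or 2.
#' @return A [binding_model()] (classes sorted by descending K) with an
#'   `sse` attribute. Warns when the two fitted classes are separated by
#'   less than a 10-fold K ratio (weakly identifiable).
#' @export
fit_multisite <- function(c_free, nu, n_classes = 1L) {
  c_free <- as.numeric(c_free); nu <- as.numeric(nu)
  n_classes <- as.integer(n_classes)
  if (!n_classes %in% c(1L, 2L)) stop("'n_classes' must be 1 or 2")
  if (length(c_free) != length(nu)) stop("lengths differ")
  if (length(c_free) < 2L * n_classes + 1L)
    stop("need at least 2*n_classes + 1 points")
  if (any(c_free <= 0)) stop("free concentrations must be > 0")

  nu_max <- max(nu)
  ## seed the strong class from a segment fit on the lower-nu half
  sp <- data.frame(nu = nu, nu_over_c = nu / c_free)
  seg <- tryCatch(
    fit_scatchard_segment(sp, nu_range = c(0.2 * nu_max, 0.6 * nu_max)),
    error = function(e) NULL)
  n1 <- if (!is.null(seg) && seg$n > 0) seg$n else nu_max / 2
  K1 <- if (!is.null(seg)) seg$K else 1 / stats::median(c_free)
  df <- data.frame(c = c_free, nu = nu)

  if (n_classes == 1L) {
    fit <- minpack.lm::nlsLM(
      nu ~ n1 * 10^lk1 * c / (1 + 10^lk1 * c), data = df,
      start = list(n1 = n1, lk1 = log10(K1)),
      lower = c(n1 = 1e-9, lk1 = -6), upper = c(n1 = Inf, lk1 = 15),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    cf <- stats::coef(fit)
    model <- binding_model(n = cf[["n1"]], K = 10^cf[["lk1"]])
  } else {
    n2 <- max(nu_max - n1, 0.1)
    fit <- minpack.lm::nlsLM(
      nu ~ n1 * 10^lk1 * c / (1 + 10^lk1 * c) +
           n2 * 10^lk2 * c / (1 + 10^lk2 * c), data = df,
      start = list(n1 = n1, lk1 = log10(K1), n2 = n2, lk2 = log10(K1) - 2),
      lower = c(n1 = 1e-9, lk1 = -6, n2 = 1e-9, lk2 = -6),
      upper = c(n1 = Inf, lk1 = 15, n2 = Inf, lk2 = 15),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    cf <- stats::coef(fit)
    K <- 10^c(cf[["lk1"]], cf[["lk2"]])
    if (max(K) / min(K) < 10)
      warning("site classes separated by < 10-fold in K; ",
              "fit is weakly identifiable")
    model <- binding_model(n = c(cf[["n1"]], cf[["n2"]]), K = K)
  }
  attr(model, "sse") <- sum(stats::residuals(fit)^2)
  model
}

#' Read a titration series from CSV
#'
#' Expects columns `ligand_total_M,signal`; `protein_total`, `alpha` and
#' `gamma` are supplied as arguments (they are experiment-level
#' calibration constants, not per-point data).
#'
#' @param path File path.
#' @param protein_total Catalytic-subunit concentration, M.
#' @param alpha Bound-signal amplitude fraction.
#' @param gamma Signal per M free ligand.
#' @return A [titration_series()].
#' @export
read_titration_csv <- function(path, protein_total, alpha = 0.05, gamma = 1) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("ligand_total_M", "signal") %in% names(df)))
    stop("titration CSV must have columns 'ligand_total_M' and 'signal'")
  titration_series(df$ligand_total_M, protein_total, df$signal,
                   alpha = alpha, gamma = gamma)
}
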