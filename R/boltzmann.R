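#' Fit a Boltzmann (or double Boltzmann) function to a G-V curve
#'
#' Single model: `G = Gmax / (1 + exp((Vm - Vb) / kb))`, where `Vb` is the
#' potential of half-maximal block and `kb` the slope factor (mV per e-fold
#' change). The double model adds an equivalent term for voltage-dependent
#' permeation: `G = Gmax / (1 + exp((Vm - Vb) / kb)) + Gmax_p / (1 +
#' exp((Vm - Vp) / kp))`, with the permeation limb rising with voltage
#' (initialized with `kp < 0`). Slopes are left unconstrained.
#'
#' Fitting is Levenberg-Marquardt nonlinear least squares with up to
#' `restarts` jittered re-initializations on failure. Starting values:
#' `Vb` = voltage nearest half-maximal conductance, `kb` = +10 mV; for the
#' double model additionally `Vp = Vb + 60`, `kp = -10`,
#' `Gmax_p = 0.3 * Gmax`.
#'
#' @param gv A [gv_curve()].
#' @param model `"single"` or `"double"`.
#' @param restarts Maximum number of jittered restarts on non-convergence.
#' @return An object of class `boltzmann_fit`: a list with `model`, the
#'   coefficients (`g_max`, `v_b`, `k_b`, and for the double model `g_max_p`,
#'   `v_p`, `k_p`), `rss`, `converged`, `fitted` and `n`.
#' @export
fit_boltzmann <- function(gv, model = c("single", "double"), restarts = 5) {
  model <- match.arg(model)
  stopifnot(inherits(gv, "gv_curve"))
  v <- gv$voltages
  g <- gv$conductances
  ok <- is.finite(v) & is.finite(g)
  v <- v[ok]
  g <- g[ok]
  n_min <- if (model == "single") 6 else 10
  if (length(v) < n_min) stop("degenerate input: need at least ", n_min, " points")
  if (diff(range(v)) < 80) stop("degenerate input: voltage span must be >= 80 mV")
  if (stats::var(g) < 1e-12) stop("no-voltage-dependence: conductance variance below tolerance")

  gmax0 <- max(g)
  vb0 <- v[which.min(abs(g - 0.5 * gmax0))]
  start <- list(g_max = gmax0, v_b = vb0, k_b = 10)
  if (model == "double") {
    start <- c(start, list(g_max_p = 0.3 * gmax0, v_p = vb0 + 60, k_p = -10))
  }
  dat <- data.frame(v = v, g = g)
  formula <- if (model == "single") {
    g ~ g_max / (1 + exp((v - v_b) / k_b))
  } else {
    g ~ g_max / (1 + exp((v - v_b) / k_b)) + g_max_p / (1 + exp((v - v_p) / k_p))
  }

  fit <- NULL
  for (attempt in 0:restarts) {
    st <- start
    if (attempt > 0) {
      jit <- stats::rnorm(length(st), 0, 0.15)
      st <- mapply(function(x, j) x * (1 + j) + (x == 0) * j, st, jit, SIMPLIFY = FALSE)
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = dat, start = st,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10, ptol = 1e-10)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("non-convergence: Boltzmann fit failed after restarts")

  cf <- as.list(stats::coef(fit))
  out <- list(
    model = model,
    g_max = cf$g_max, v_b = cf$v_b, k_b = cf$k_b,
    g_max_p = cf$g_max_p, v_p = cf$v_p, k_p = cf$k_p,
    rss = sum(stats::resid(fit)^2),
    converged = TRUE,
    fitted = stats::fitted(fit),
    voltages = v,
    n = length(v)
  )
  class(out) <- "boltzmann_fit"
  out
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf(
    "<boltzmann_fit: %s> Gmax = %.4g, Vb = %.4g mV, kb = %.4g mV",
    x$model, x$g_max, x$v_b, x$k_b
  ))
  if (x$model == "double") {
    cat(sprintf(", Gmax_p = %.4g, Vp = %.4g mV, kp = %.4g mV", x$g_max_p, x$v_p, x$k_p))
  }
  cat(sprintf(" | RSS %.4g, n = %d\n", x$rss, x$n))
  invisible(x)
}

#' Evaluate a fitted Boltzmann model
#'
#' @param object A `boltzmann_fit`.
#' @param newdata Optional data frame / list with element `v` (mV).
#' @param ... Unused.
#' @return Predicted conductances.
#' @export
predict.boltzmann_fit <- function(object, newdata = NULL, ...) {
  v <- if (is.null(newdata)) object$voltages else newdata$v
  g <- object$g_max / (1 + exp((v - object$v_b) / object$k_b))
  if (object$model == "double") {
    g <- g + object$g_max_p / (1 + exp((v - object$v_p) / object$k_p))
  }
  g
}

#' Voltage-independent potency (IC50 at 0 mV) from Vb versus concentration
#'
#' Ordinary least squares of the Boltzmann midpoint `Vb` on
#' `log10(concentration)`. The x-axis intercept, where the fitted line
#' crosses `Vb = 0`, gives the concentration producing half-maximal block at
#' 0 mV: `IC50_0mV = 10^(-intercept / slope)`. The slope must be negative
#' (block deepens, so `Vb` shifts negative, with concentration); for the
#' non-permeant block model it equals `-h_block * log(10)` mV per decade.
#'
#' @param vb_by_concentration Data frame (or list) with numeric columns
#'   `concentration` (µM) and `v_b` (mV); at least 3 distinct concentrations.
#' @return An object of class `potency_fit`: `slope` (mV per decade),
#'   `intercept` (mV), `ic50_0mv` (µM), plus the points used.
#' @export
fit_potency <- function(vb_by_concentration) {
  conc <- vb_by_concentration$concentration
  vb <- vb_by_concentration$v_b
  stopifnot(length(conc) == length(vb))
  if (length(unique(conc)) < 3) stop("need at least 3 distinct concentrations")
  if (any(conc <= 0)) stop("invalid-parameter: concentrations must be positive")
  lc <- log10(conc)
  fit <- stats::lm(vb ~ lc)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope == 0) stop("zero slope: Vb does not depend on concentration")
  if (slope > 0) stop("positive slope: Vb must grow more negative with concentration")
  structure(
    list(
      slope = slope, intercept = intercept,
      ic50_0mv = 10^(-intercept / slope),
      concentrations = conc, v_b = vb,
      rss = sum(stats::resid(fit)^2)
    ),
    class = "potency_fit"
  )
}

#' @export
print.potency_fit <- function(x, ...) {
  cat(sprintf(
    "<potency_fit> slope = %.4g mV/decade, IC50(0 mV) = %.4g uM (n = %d concentrations)\n",
    x$slope, x$ic50_0mv, length(x$concentrations)
  ))
  invisible(x)
}
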