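#' Normalize tail-current amplitudes into a GV dataset
#'
#' Conductance is proportional to the tail-current amplitude measured at
#' a fixed repolarization voltage, so dividing by the global maximum
#' gives G/Gmax directly.
#'
#' @param voltages test-pulse voltages (mV).
#' @param amplitudes tail-current amplitudes (pA), one per voltage.
#' @param sem optional per-point SEM on the same scale as `amplitudes`
#'   (scaled along with them).
#' @return a `gv_dataset`.
#' @export
normalize_gv <- function(voltages, amplitudes, sem = NULL) {
  if (length(voltages) != length(amplitudes))
    stop("voltages and amplitudes must have equal length")
  mx <- max(amplitudes)
  if (mx <= 0) stop("maximum amplitude must be positive")
  out <- data.frame(voltage_mV = voltages, g_norm = amplitudes / mx,
                    sem = if (is.null(sem)) NA_real_ else sem / mx)
  class(out) <- c("gv_dataset", "data.frame")
  out
}

#' Fit the Boltzmann activation curve to GV data
#'
#' Weighted nonlinear least squares of
#' \eqn{G/G_{max} = g_{max}/(1 + \exp((V_{1/2} - V)/b))} with weights
#' \eqn{1/SEM^2} when per-point SEMs are available. Starting values are
#' derivative-free: \eqn{V_{1/2}} from linear interpolation of the
#' half-maximum crossing and \eqn{b} from the 25--75% voltage span
#' divided by \eqn{\ln 9}. Standard errors come from parametric
#' Monte-Carlo resampling: each draw perturbs every point by Gaussian
#' noise at its SEM, refits, and the SE is the SD of the refitted
#' parameters. The equivalent gating charge is reported as
#' \eqn{z = kT/(e_0 b)} at 22 C.
#'
#' @param gv a `gv_dataset` (columns `voltage_mV`, `g_norm`, optional
#'   `sem`).
#' @param fix_gmax fix the maximal conductance at 1 (the default, since
#'   the response is already normalized to Gmax); set `FALSE` to fit a
#'   free amplitude, e.g. for un-normalized tail currents. With a free
#'   amplitude and a protocol that does not reach saturation, `g_max`
#'   and `v_half` are strongly confounded and the Monte-Carlo SEs grow
#'   accordingly.
#' @param weighted use 1/SEM^2 weights when SEMs are present.
#' @param mc_draws Monte-Carlo draws for SEs (0 skips them).
#' @param seed RNG seed for the Monte-Carlo resampling.
#' @return object of class `boltzmann_fit`: list with `v_half`,
#'   `slope_b`, `g_max`, `se_v_half`, `se_slope`, `se_g_max`, `z`,
#'   `converged`, `fitted`, `data`.
#' @export
fit_boltzmann <- function(gv, fix_gmax = TRUE, weighted = TRUE,
                          mc_draws = 500, seed = 1) {
  d <- as.data.frame(gv)
  stopifnot(all(c("voltage_mV", "g_norm") %in% names(d)))
  if (nrow(d) < 4) stop("need >= 4 GV points")
  wts <- .fit_weights(d$sem, weighted, nrow(d))

  init <- .boltzmann_init(d$voltage_mV, d$g_norm)
  est <- .boltzmann_nls(d, wts, init, fix_gmax)
  if (is.null(est)) stop("Boltzmann fit did not converge")

  # pinned at the edge of the voltage range = no transition in range
  converged <- est["v_half"] > min(d$voltage_mV) &&
    est["v_half"] < max(d$voltage_mV)

  se <- c(v_half = NA_real_, slope = NA_real_, g_max = NA_real_)
  if (mc_draws > 0) {
    draws <- .mc_refit(d, wts, mc_draws, seed, function(dd)
      .boltzmann_nls(dd, wts, est, fix_gmax))
    if (nrow(draws)) {
      se <- c(v_half = stats::sd(draws[, "v_half"]),
              slope = stats::sd(draws[, "slope"]),
              g_max = stats::sd(draws[, "g_max"]))
    }
  }
  structure(list(v_half = unname(est["v_half"]),
                 slope_b = unname(est["slope"]),
                 g_max = unname(est["g_max"]),
                 se_v_half = unname(se["v_half"]),
                 se_slope = unname(se["slope"]),
                 se_g_max = unname(se["g_max"]),
                 z = .kT_e0(295) / unname(est["slope"]),
                 converged = converged,
                 fitted = boltzmann(d$voltage_mV, est["v_half"],
                                    est["slope"], est["g_max"]),
                 data = d),
            class = "boltzmann_fit")
}

## kT/e0 in mV at temperature T (K); 295 K ~ room temperature
.kT_e0 <- function(T) 1000 * 1.380649e-23 * T / 1.602176634e-19

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("<boltzmann_fit> V1/2 = %.1f +/- %.1f mV, b = %.1f +/- %.1f mV, gmax = %.3f%s\n",
              x$v_half, x$se_v_half, x$slope_b, x$se_slope, x$g_max,
              if (x$converged) "" else " [non-converged]"))
  invisible(x)
}

.boltzmann_init <- function(v, g) {
  gmax <- max(g)
  half <- gmax / 2
  v_half <- .crossing(v, g, half)
  v25 <- .crossing(v, g, 0.25 * gmax)
  v75 <- .crossing(v, g, 0.75 * gmax)
  b <- (v75 - v25) / log(9)
  if (!is.finite(b) || b == 0) b <- diff(range(v)) / 4
  c(v_half = v_half, slope = b, g_max = gmax)
}

## first linear-interpolated crossing of level by (x, y)
.crossing <- function(x, y, level) {
  s <- sign(y - level)
  ix <- which(s[-1] * s[-length(s)] <= 0)
  if (!length(ix)) return(x[which.min(abs(y - level))])
  i <- ix[1]
  if (y[i + 1] == y[i]) return(x[i])
  x[i] + (level - y[i]) * (x[i + 1] - x[i]) / (y[i + 1] - y[i])
}

.boltzmann_nls <- function(d, wts, init, fix_gmax) {
  form <- if (fix_gmax) {
    g_norm ~ 1 / (1 + exp((v_half - voltage_mV) / slope))
  } else {
    g_norm ~ g_max / (1 + exp((v_half - voltage_mV) / slope))
  }
  start <- as.list(init[if (fix_gmax) c("v_half", "slope")
                        else c("v_half", "slope", "g_max")])
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = d, start = start, weights = wts,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  c(v_half = unname(cf["v_half"]), slope = unname(cf["slope"]),
    g_max = if (fix_gmax) 1 else unname(cf["g_max"]))
}

.fit_weights <- function(sem, weighted, n) {
  if (weighted && !is.null(sem) && all(is.finite(sem)) && all(sem > 0))
    1 / sem^2
  else rep(1, n)
}

## parametric Monte-Carlo: perturb each response by N(0, sem), refit
.mc_refit <- function(d, wts, draws, seed, refit) {
  sem <- d$sem
  if (is.null(sem) || !all(is.finite(sem))) {
    return(matrix(numeric(0), 0, 3,
                  dimnames = list(NULL, c("v_half", "slope", "g_max"))))
  }
  ycol <- intersect(c("g_norm", "theta"), names(d))[1]
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  out <- vector("list", draws)
  for (b in seq_len(draws)) {
    dd <- d
    dd[[ycol]] <- d[[ycol]] + stats::rnorm(nrow(d), 0, sem)
    out[[b]] <- refit(dd)
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' GV shift between two Boltzmann fits
#'
#' \eqn{\Delta V_{1/2} = V_{1/2}(a) - V_{1/2}(b)} with the SE combined
#' in quadrature.
#'
#' @param fit_a,fit_b `boltzmann_fit` objects.
#' @return list with `delta_v_half` (mV) and `se` (mV).
#' @export
delta_v_half <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "boltzmann_fit"),
            inherits(fit_b, "boltzmann_fit"))
  list(delta_v_half = fit_a$v_half - fit_b$v_half,
       se = sqrt(fit_a$se_v_half^2 + fit_b$se_v_half^2))
}

#' Fit the Hill equation to a dose-response dataset
#'
#' Weighted nonlinear least squares of
#' \eqn{\theta = \theta_{max}/(1 + (EC_{50}/X)^n)}. The Hill
#' coefficient is fixed at 1 by default (freed with `fix_n = FALSE`);
#' starting values come from the half-maximal crossing of the response.
#' SEs use the same parametric Monte-Carlo resampling as
#' [fit_boltzmann()]. Works identically for activation (EC50, signed
#' maximal GV shift in mV) and inhibition (IC50, fractional block).
#'
#' @param dr a `dose_response` (columns `conc_uM`, `theta`, optional
#'   `sem`).
#' @param fix_n keep the Hill coefficient at 1.
#' @param weighted use 1/SEM^2 weights when SEMs are present.
#' @param mc_draws Monte-Carlo draws for SEs.
#' @param seed RNG seed for the resampling.
#' @return object of class `hill_fit`: list with `ec50`,
#'   `max_response`, `hill_n`, `se_ec50`, `se_max`, `converged`,
#'   `fitted`, `data`.
#' @export
fit_hill <- function(dr, fix_n = TRUE, weighted = TRUE, mc_draws = 500,
                     seed = 1) {
  d <- as.data.frame(dr)
  stopifnot(all(c("conc_uM", "theta") %in% names(d)))
  if (nrow(d) < 3) stop("need >= 3 concentrations")
  wts <- .fit_weights(d$sem, weighted, nrow(d))

  if (!all(diff(abs(d$theta)) + 3 * max(d$sem, 0, na.rm = TRUE) >= 0))
    warning("response magnitude not monotone beyond noise")

  init <- .hill_init(d$conc_uM, d$theta)
  est <- .hill_nls(d, wts, init, fix_n)
  if (is.null(est)) stop("Hill fit did not converge")
  converged <- est["ec50"] > 0 && is.finite(est["ec50"])

  se <- c(ec50 = NA_real_, max = NA_real_)
  if (mc_draws > 0) {
    draws <- .mc_refit(d, wts, mc_draws, seed, function(dd)
      .hill_nls(dd, wts, est, fix_n))
    if (nrow(draws)) {
      se <- c(ec50 = stats::sd(draws[, "ec50"]),
              max = stats::sd(draws[, "max_response"]))
    }
  }
  structure(list(ec50 = unname(est["ec50"]),
                 max_response = unname(est["max_response"]),
                 hill_n = unname(est["hill_n"]),
                 se_ec50 = unname(se["ec50"]),
                 se_max = unname(se["max"]),
                 converged = converged,
                 fitted = hill(d$conc_uM, est["ec50"],
                               est["max_response"], est["hill_n"]),
                 data = d),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> EC50 = %.3g +/- %.2g uM, max = %.3g +/- %.2g (n = %g)%s\n",
              x$ec50, x$se_ec50, x$max_response, x$se_max, x$hill_n,
              if (x$converged) "" else " [non-converged]"))
  invisible(x)
}

.hill_init <- function(x, theta) {
  mx <- theta[which.max(abs(theta))]
  ec50 <- .crossing(x, abs(theta), abs(mx) / 2)
  if (!is.finite(ec50) || ec50 <= 0) ec50 <- stats::median(x)
  c(ec50 = ec50, max_response = mx, hill_n = 1)
}

.hill_nls <- function(d, wts, init, fix_n) {
  form <- if (fix_n) {
    theta ~ max_response / (1 + ec50 / conc_uM)
  } else {
    theta ~ max_response / (1 + (ec50 / conc_uM)^hill_n)
  }
  start <- as.list(init[if (fix_n) c("ec50", "max_response")
                        else c("ec50", "max_response", "hill_n")])
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = d, start = start, weights = wts,
                      lower = if (fix_n) c(1e-9, -Inf)
                              else c(1e-9, -Inf, 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- stats::coef(fit)
  c(ec50 = unname(cf["ec50"]),
    max_response = unname(cf["max_response"]),
    hill_n = if (fix_n) 1 else unname(cf["hill_n"]))
}

#' NPo from a current trace
#'
#' Integrates the (baseline-subtracted) current rectangularly and
#' divides by the unitary current and the total time:
#' \eqn{NP_O = \int I\,dt / (i\,T)}. A batch-means SE (20 batches) is
#' attached for convenience.
#'
#' @param trace a `current_trace` (or bare numeric vector of pA
#'   samples, in which case `interval` must be given).
#' @param unitary_current single-channel current i (pA, > 0).
#' @param interval sampling interval (s) when `trace` is a bare vector.
#' @return object of class `npo_estimate`: list with `npo`, `se`,
#'   `unitary_pA`, `duration`.
#' @export
estimate_npo <- function(trace, unitary_current, interval = NULL) {
  if (inherits(trace, "current_trace")) {
    samples <- trace$samples
    interval <- trace$interval
  } else {
    samples <- as.numeric(trace)
    if (is.null(interval)) stop("interval required for bare sample vectors")
  }
  if (unitary_current <= 0) stop("unitary current must be positive")
  duration <- length(samples) * interval
  npo <- sum(samples) * interval / (unitary_current * duration)

  nb <- min(20L, length(samples))
  batch <- split(samples, cut(seq_along(samples), nb, labels = FALSE))
  bm <- vapply(batch, mean, numeric(1)) / unitary_current
  se <- stats::sd(bm) / sqrt(length(bm))
  structure(list(npo = npo, se = se, unitary_pA = unitary_current,
                 duration = duration),
            class = "npo_estimate")
}

#' Channel count from macroscopic current
#'
#' \eqn{N = I / (\gamma (V - E_K) P_O)}, the standard estimate of how
#' many channels a macropatch contains, evaluated at a voltage where
#' the open probability is known (near 1 at strongly activating
#' conditions).
#'
#' @param i_macro macroscopic current (pA).
#' @param gamma single-channel conductance (pS, default 273).
#' @param v test voltage (mV).
#' @param e_k reversal potential (mV).
#' @param p_open open probability in (0, 1].
#' @return object of class `channel_count`: list with `N` (rounded),
#'   `N_raw`, and the inputs.
#' @export
estimate_channel_count <- function(i_macro, gamma = 273, v = 100,
                                   e_k = 0, p_open = 1) {
  if (v == e_k) stop("V must differ from E_K")
  if (p_open <= 0 || p_open > 1) stop("p_open must be in (0, 1]")
  unitary <- gamma * (v - e_k) / 1000   # pA
  n_raw <- i_macro / (unitary * p_open)
  structure(list(N = round(n_raw), N_raw = n_raw,
                 inputs = list(i_macro = i_macro, gamma = gamma, v = v,
                               e_k = e_k, p_open = p_open,
                               unitary_pA = unitary)),
            class = "channel_count")
}

#' Fractional inhibition of macroscopic current
#'
#' \eqn{1 - I_{treated}/I_{control}} per voltage or concentration; 0
#' means no block, 1 means complete block.
#'
#' @param i_control control current(s).
#' @param i_treated current(s) in the presence of the blocker, matched
#'   elementwise.
#' @return numeric vector of fractional inhibition values.
#' @export
fractional_inhibition <- function(i_control, i_treated) {
  if (length(i_control) != length(i_treated))
    stop("control and treated currents must be matched")
  if (any(i_control == 0)) stop("control current must be nonzero")
  1 - i_treated / i_control
}
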