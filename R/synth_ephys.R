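#' Synthetic conductance-voltage (GV) dataset
#'
#' Evaluates the two-state Boltzmann activation curve
#' \deqn{G/G_{max} = 1/(1 + \exp((V_{1/2} - V)/b))}
#' at the requested voltages and adds i.i.d. Gaussian noise per
#' replicate; the reported `g_norm` is the replicate mean and `sem` is
#' `noise_sd / sqrt(n_reps)`. With `noise_sd = 0` the generator is an
#' exact evaluation of the Boltzmann curve.
#'
#' @param v_half half-activation voltage (mV).
#' @param slope slope factor b (mV, nonzero).
#' @param voltages strictly increasing voltage vector (mV).
#' @param noise_sd per-replicate Gaussian noise SD (dimensionless
#'   conductance units, >= 0).
#' @param n_reps replicates per point (scalar or per-voltage vector).
#' @param seed RNG seed.
#' @param condition free-form description (e.g. Ca/ligand condition).
#' @return object of class `gv_dataset`: data.frame `voltage_mV`,
#'   `g_norm`, `sem`, with attributes `condition` and `truth`.
#' @export
make_gv_dataset <- function(v_half, slope, voltages, noise_sd = 0,
                            n_reps = 1, seed = 1, condition = "") {
  if (slope == 0) stop("slope must be nonzero")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.unsorted(voltages, strictly = TRUE))
    stop("voltages must be strictly increasing")
  n_reps <- rep_len(as.integer(n_reps), length(voltages))
  truth <- boltzmann(voltages, v_half, slope)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  g <- vapply(seq_along(voltages), function(i) {
    mean(truth[i] + stats::rnorm(n_reps[i], 0, noise_sd))
  }, numeric(1))
  out <- data.frame(voltage_mV = voltages, g_norm = g,
                    sem = noise_sd / sqrt(n_reps))
  attr(out, "condition") <- condition
  attr(out, "truth") <- c(v_half = v_half, slope = slope)
  class(out) <- c("gv_dataset", "data.frame")
  out
}

#' Boltzmann activation curve
#'
#' @param v voltage (mV).
#' @param v_half half-activation voltage (mV).
#' @param slope slope factor b (mV).
#' @param g_max maximal conductance (default 1).
#' @return normalized conductance.
#' @export
boltzmann <- function(v, v_half, slope, g_max = 1) {
  g_max / (1 + exp((v_half - v) / slope))
}

#' Hill dose-response curve (activation or inhibition)
#'
#' @param x dose (concentration, same units as `ec50`).
#' @param ec50 half-maximal dose (> 0).
#' @param max_response response at infinite dose.
#' @param n Hill coefficient (default 1).
#' @return expected response \eqn{\theta = max/(1 + (EC_{50}/X)^n)}.
#' @export
hill <- function(x, ec50, max_response, n = 1) {
  max_response / (1 + (ec50 / x)^n)
}

#' Synthetic dose-response dataset
#'
#' Evaluates the Hill curve at the requested concentrations and adds
#' per-replicate Gaussian noise; `theta` is the replicate mean, `sem`
#' is `noise_sd / sqrt(n_reps)`. Used both for GV-shift activation
#' responses (theta in mV) and fractional-inhibition responses
#' (dimensionless).
#'
#' @param ec50 half-maximal concentration (> 0, uM).
#' @param max_response maximal response.
#' @param concentrations strictly increasing positive dose vector (uM).
#' @param hill_n Hill coefficient (default 1).
#' @param noise_sd per-replicate noise SD (>= 0).
#' @param n_reps replicates per point (scalar or vector).
#' @param seed RNG seed.
#' @return object of class `dose_response`: data.frame `conc_uM`,
#'   `theta`, `sem`, attribute `truth`.
#' @export
make_dose_response <- function(ec50, max_response, concentrations,
                               hill_n = 1, noise_sd = 0, n_reps = 1,
                               seed = 1) {
  if (ec50 <= 0) stop("ec50 must be positive")
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (is.unsorted(concentrations, strictly = TRUE))
    stop("concentrations must be strictly increasing")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  n_reps <- rep_len(as.integer(n_reps), length(concentrations))
  truth <- hill(concentrations, ec50, max_response, hill_n)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  th <- vapply(seq_along(concentrations), function(i) {
    mean(truth[i] + stats::rnorm(n_reps[i], 0, noise_sd))
  }, numeric(1))
  out <- data.frame(conc_uM = concentrations, theta = th,
                    sem = noise_sd / sqrt(n_reps))
  attr(out, "truth") <- c(ec50 = ec50, max_response = max_response,
                          hill_n = hill_n)
  class(out) <- c("dose_response", "data.frame")
  out
}

#' Simulate a multi-channel current trace
#'
#' `N` independent two-state Markov channels, each with stationary open
#' probability `p_open` and mean open dwell `mean_open` (the closed
#' dwell follows from detailed balance:
#' `mean_closed = mean_open (1 - p_open)/p_open`). The aggregate open
#' count evolves by exact binomial transitions per sampling step, and
#' the summed current is `(open count) * gamma * (V - E_K)` with the
#' unitary current in pA for `gamma` in pS and voltages in mV.
#'
#' @param N channel count (>= 1).
#' @param p_open stationary open probability in (0, 1]; `p_open = 1`
#'   gives a constant fully-open trace.
#' @param gamma single-channel conductance (pS; 273 pS is typical of a
#'   large-conductance K+ channel).
#' @param v membrane voltage (mV).
#' @param e_k K+ reversal potential (mV).
#' @param mean_open mean open dwell time (ms).
#' @param duration trace length (s); must cover at least 100 expected
#'   gating events.
#' @param interval sampling interval (s); must not exceed the shorter
#'   mean dwell time.
#' @param seed RNG seed.
#' @return object of class `current_trace`: list with `samples` (pA),
#'   `time` (s), `interval`, `duration`, `voltage`, `unitary_pA`, and
#'   hidden `true_params`.
#' @export
simulate_channel_trace <- function(N, p_open, gamma = 273, v = 100,
                                   e_k = 0, mean_open = 10,
                                   duration = 5, interval = 1e-3,
                                   seed = 1) {
  if (N < 1) stop("N must be >= 1")
  if (p_open <= 0 || p_open > 1) stop("p_open must be in (0, 1]")
  if (gamma <= 0) stop("gamma must be positive")
  unitary <- gamma * (v - e_k) / 1000   # pS * mV -> pA
  n_samp <- round(duration / interval)

  if (p_open == 1) {
    samples <- rep(N * unitary, n_samp)
  } else {
    mo <- mean_open / 1000                       # s
    mc <- mo * (1 - p_open) / p_open             # s
    if (interval > min(mo, mc)) stop("undersampled: interval exceeds mean dwell time")
    expected_events <- duration * N / (mo + mc)
    if (expected_events < 100)
      stop("duration too short: fewer than 100 expected gating events")
    p_close <- interval / mo                     # open -> closed per step
    p_open_step <- interval / mc                 # closed -> open per step
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
    n_open <- stats::rbinom(1, N, p_open)        # stationary start
    samples <- numeric(n_samp)
    for (i in seq_len(n_samp)) {
      samples[i] <- n_open * unitary
      closes <- stats::rbinom(1, n_open, p_close)
      opens <- stats::rbinom(1, N - n_open, p_open_step)
      n_open <- n_open - closes + opens
    }
  }
  structure(list(samples = samples,
                 time = seq(0, by = interval, length.out = n_samp),
                 interval = interval, duration = n_samp * interval,
                 voltage = v, unitary_pA = unitary,
                 true_params = list(N = N, p_open = p_open,
                                    gamma = gamma, e_k = e_k)),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat("<current_trace> ", length(x$samples), " samples over ",
      x$duration, " s at ", x$voltage, " mV (unitary ",
      signif(x$unitary_pA, 4), " pA)\n", sep = "")
  invisible(x)
}

#' Write/read electrophysiology tables
#'
#' CSV round-trip helpers with the column conventions used throughout:
#' `voltage_mV, g_norm, sem` for GV data and `conc_uM, theta, sem` for
#' dose-response data.
#'
#' @param x a `gv_dataset` or `dose_response`.
#' @param path CSV path.
#' @return `path` invisibly (writers); the reconstructed object
#'   (readers).
#' @export
write_ephys_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ephys_csv
#' @export
read_gv_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("voltage_mV", "g_norm")
  if (!all(need %in% names(d)))
    stop("GV csv must have columns voltage_mV, g_norm")
  if (is.null(d$sem)) d$sem <- NA_real_
  class(d) <- c("gv_dataset", "data.frame")
  d
}

#' @rdname write_ephys_csv
#' @export
read_dose_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("conc_uM", "theta")
  if (!all(need %in% names(d)))
    stop("dose-response csv must have columns conc_uM, theta")
  if (is.null(d$sem)) d$sem <- NA_real_
  class(d) <- c("dose_response", "data.frame")
  d
}
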