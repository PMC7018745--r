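#' Gating rate constants for the three-state GABA-A channel scheme
#'
#' The channel is described by C0 <-> C1 <-> O: an unbound closed state, a
#' bound closed state and an open state. Transitions are governed by the
#' binding rate `k1` (per mM per ms; it always multiplies the GABA
#' concentration in mM, even though rate tables often quote it in ms^-1),
#' the unbinding rate `k2`, the opening rate `k3` and the closing rate `k4`
#' (all per ms).
#'
#' @param k1 binding rate, per mM per ms.
#' @param k2 unbinding rate, per ms.
#' @param k3 opening rate, per ms.
#' @param k4 closing rate, per ms.
#' @param label optional condition name (e.g. "sham", "pni").
#' @return An object of class `gating_params`.
#' @export
gating_params <- function(k1, k2, k3, k4, label = "") {
  rates <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4)
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("all gating rates must be positive and finite")
  structure(list(k1 = k1, k2 = k2, k3 = k3, k4 = k4, label = label),
            class = "gating_params")
}

#' Built-in gating parameter presets
#'
#' Rate constants for uninjured ("sham") and nerve-injured ("pni")
#' conditions of spinal dorsal horn GABA-A receptors. The injured preset
#' has a lower binding rate (lower GABA affinity, consistent with a shift
#' toward alpha2/alpha3-containing receptors) and slower opening/closing.
#'
#' @param name `"sham"` or `"pni"`.
#' @return A [gating_params()] object.
#' @export
gating_preset <- function(name = c("sham", "pni")) {
  name <- match.arg(name)
  switch(name,
    sham = gating_params(k1 = 40,   k2 = 0.8, k3 = 1,    k4 = 0.15, label = "sham"),
    pni  = gating_params(k1 = 11.2, k2 = 0.8, k3 = 0.43, k4 = 0.06, label = "pni"))
}

#' Synaptic GABA concentration transient
#'
#' A single-exponential cleft transient `[GABA](t) = g_max * exp(-t / tau)`.
#' Defaults are the standard cleft estimate: 0.63 mM peak, 1 ms decay.
#'
#' @param g_max peak concentration, mM.
#' @param tau decay time constant, ms; `Inf` holds the concentration
#'   constant (agonist bath application).
#' @return An object of class `transmitter_pulse`.
#' @export
transmitter_pulse <- function(g_max = 0.63, tau = 1) {
  if (g_max < 0) stop("g_max must be >= 0")
  if (tau <= 0) stop("tau must be > 0")
  structure(list(g_max = g_max, tau = tau), class = "transmitter_pulse")
}

#' Simulate the three-state gating scheme during a synaptic event
#'
#' Integrates
#' \deqn{dC0/dt = -k1 [G] C0 + k2 C1}
#' \deqn{dC1/dt =  k1 [G] C0 - (k2 + k3) C1 + k4 O}
#' \deqn{dO/dt  =  k3 C1 - k4 O}
#' with \eqn{[G](t) = g_{max} e^{-t/\tau}} and all channels in C0 at t = 0.
#' A stiff-capable integrator (lsoda) is used; fractions are sampled every
#' `dt` ms.
#'
#' @param params a [gating_params()] object.
#' @param pulse a [transmitter_pulse()] object.
#' @param duration total simulated time, ms. Must cover at least 10 pulse
#'   time constants so the transmitter has fully decayed.
#' @param dt output sampling step, ms.
#' @param rtol,atol integrator tolerances.
#' @return A `gating_trajectory`: data.frame with columns `time`, `c0`,
#'   `c1`, `o` plus the generating parameters as attributes.
#' @export
simulate_gating <- function(params, pulse = transmitter_pulse(),
                            duration = 100, dt = 0.05,
                            rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "gating_params"), inherits(pulse, "transmitter_pulse"))
  if (is.finite(pulse$tau) && duration < 10 * pulse$tau)
    stop("duration must be at least 10 pulse time constants")
  times <- seq(0, duration, by = dt)
  deriv <- function(t, y, p) {
    g <- pulse$g_max * exp(-t / pulse$tau)
    with(as.list(y), {
      dc0 <- -params$k1 * g * c0 + params$k2 * c1
      dc1 <-  params$k1 * g * c0 - (params$k2 + params$k3) * c1 + params$k4 * o
      do  <-  params$k3 * c1 - params$k4 * o
      list(c(dc0, dc1, do))
    })
  }
  out <- deSolve::lsoda(c(c0 = 1, c1 = 0, o = 0), times, deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("gating integration did not converge at the requested tolerance")
  traj <- as.data.frame(out)
  names(traj)[1] <- "time"
  # clip tiny negative overshoot from the integrator, then check conservation
  bad <- abs(traj$c0 + traj$c1 + traj$o - 1) > 1e-6
  if (any(bad)) stop("state conservation violated beyond 1e-6")
  attr(traj, "params") <- params
  attr(traj, "pulse") <- pulse
  class(traj) <- c("gating_trajectory", "data.frame")
  traj
}

#' Steady-state open fraction at constant GABA
#'
#' Closed form for the C0 <-> C1 <-> O scheme held at a constant agonist
#' concentration `g_const`:
#' \deqn{O_\infty = \frac{k_1 G k_3}{k_2 k_4 + k_1 G (k_3 + k_4)}.}
#'
#' @param params a [gating_params()] object.
#' @param g_const constant GABA concentration, mM (scalar or vector).
#' @return Open fraction(s) in `[0, 1)`.
#' @export
steady_state_open_fraction <- function(params, g_const) {
  stopifnot(inherits(params, "gating_params"))
  if (any(g_const < 0)) stop("g_const must be >= 0")
  num <- params$k1 * g_const * params$k3
  num / (params$k2 * params$k4 + params$k1 * g_const * (params$k3 + params$k4))
}

#' Steady-state GABA dose-response curve of the open fraction
#'
#' Evaluates [steady_state_open_fraction()] on a concentration grid and
#' returns the curve together with its closed-form EC50,
#' \eqn{EC_{50} = k_2 k_4 / (k_1 (k_3 + k_4))}, and saturation level
#' \eqn{O_{max} = k_3 / (k_3 + k_4)}.
#'
#' @param params a [gating_params()] object.
#' @param grid positive, sorted concentration grid, mM.
#' @return A list of class `gaba_dose_curve` with `concentration`,
#'   `open_fraction`, `ec50` (mM) and `o_max`.
#' @export
gaba_dose_response <- function(params, grid = 10^seq(-4, 1, length.out = 200)) {
  if (length(grid) == 0) stop("empty concentration grid")
  if (any(grid <= 0) || is.unsorted(grid)) stop("grid must be positive and sorted")
  structure(list(
    concentration = grid,
    open_fraction = steady_state_open_fraction(params, grid),
    ec50 = params$k2 * params$k4 / (params$k1 * (params$k3 + params$k4)),
    o_max = params$k3 / (params$k3 + params$k4)),
    class = "gaba_dose_curve")
}

#' Summarize a simulated synaptic event
#'
#' Extracts the peak open fraction, time to peak, 10-90% rise time and the
#' decay time constant. The decay constant comes from a single-exponential
#' fit (zero offset, since all states relax to zero) on the open fraction
#' from the peak down to the last sample above 5% of peak.
#'
#' @param traj a `gating_trajectory` from [simulate_gating()], or any
#'   data.frame with `time` and `o` columns.
#' @return A list of class `event_summary` with `peak_open_fraction`,
#'   `time_to_peak`, `rise_10_90` and `decay_tau` (all times in ms).
#' @export
summarize_event <- function(traj) {
  t <- traj$time; o <- traj$o
  ipk <- which.max(o)
  if (ipk == 1L || ipk == length(o)) stop("trajectory has no interior peak")
  pk <- o[ipk]
  # 10-90% rise from linear interpolation of threshold crossings
  t10 <- stats::approx(o[1:ipk], t[1:ipk], xout = 0.1 * pk, ties = "ordered")$y
  t90 <- stats::approx(o[1:ipk], t[1:ipk], xout = 0.9 * pk, ties = "ordered")$y
  # decay window: peak -> last point above 5% of peak
  post <- seq(ipk, length(o))
  above <- which(o[post] >= 0.05 * pk)
  iend <- post[max(above)]
  tw <- t[ipk:iend] - t[ipk]
  ow <- o[ipk:iend]
  fit <- minpack.lm::nlsLM(ow ~ a * exp(-tw / tau),
                           start = list(a = pk, tau = max(tw) / 3),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  structure(list(
    peak_open_fraction = pk,
    time_to_peak = t[ipk],
    rise_10_90 = t90 - t10,
    decay_tau = stats::coef(fit)[["tau"]]),
    class = "event_summary")
}

#' Slow relaxation constant of the post-transmitter subsystem
#'
#' After the transmitter has decayed ([G] -> 0) the occupied states obey
#' the linear 2x2 system in (C1, O), whose eigenvalues solve
#' \eqn{\lambda^2 + (k_2 + k_3 + k_4)\lambda + k_2 k_4 = 0}. The decay of
#' the open fraction is dominated by the slow eigenvalue; this returns
#' \eqn{-1/\lambda_{slow}} in ms. It is the analytic counterpart of the
#' fitted `decay_tau` and is useful as an independent check.
#'
#' @param params a [gating_params()] object.
#' @return Slow decay time constant, ms.
#' @export
decay_tau_eigen <- function(params) {
  b <- params$k2 + params$k3 + params$k4
  c0 <- params$k2 * params$k4
  lam_slow <- (-b + sqrt(b^2 - 4 * c0)) / 2
  -1 / lam_slow
}

#' Conductance time course from a gating trajectory
#'
#' The macroscopic conductance is proportional to the open fraction times
#' the (relative) number of channels. The injured condition carries 37.2%
#' more receptors at synapses, hence `relative_channel_number = 1.372`
#' reproduces its conductance scaling against a sham reference of 1.
#'
#' @param traj a `gating_trajectory`.
#' @param relative_channel_number positive scale factor.
#' @return data.frame with `time` and `conductance` (arbitrary units).
#' @export
conductance_timecourse <- function(traj, relative_channel_number = 1) {
  if (relative_channel_number <= 0) stop("relative_channel_number must be > 0")
  data.frame(time = traj$time, conductance = traj$o * relative_channel_number)
}

#' Fit gating constants of two conditions to kinetic constraints
#'
#' Recovers the seven free rates (k1, k3, k4 per condition plus one shared
#' unbinding rate k2) by weighted least squares against seven targets:
#' rise and decay times of both conditions (from simulated events), a lower
#' bound on the reference peak open fraction (hinge penalty), the relative
#' peak reduction of the second condition, and the steady-state GABA EC50
#' of the reference condition.
#'
#' @param targets list with elements `rise` (length-2: reference, altered;
#'   ms), `decay` (length-2, ms), `peak_min` (fraction, lower bound on the
#'   reference peak), `peak_reduction` (fractional reduction of the altered
#'   peak relative to reference, e.g. 0.372) and `ec50` (mM, reference).
#' @param start optional list of two [gating_params()] starting points;
#'   defaults to the built-in presets.
#' @param pulse transmitter pulse used for the event simulations.
#' @param shared_k2 share the unbinding rate across conditions (default
#'   TRUE).
#' @param weights residual weights after normalization (length 7).
#' @param maxit optimizer iteration cap.
#' @return list with `params_a`, `params_b`, `residuals` (named, per
#'   constraint) and `convergence` info from [stats::optim()].
#' @export
fit_gating_constraints <- function(targets, start = NULL,
                                   pulse = transmitter_pulse(),
                                   shared_k2 = TRUE,
                                   weights = rep(1, 7), maxit = 2000) {
  stopifnot(is.list(targets),
            length(targets$rise) == 2, length(targets$decay) == 2)
  if (is.null(start)) start <- list(gating_preset("sham"), gating_preset("pni"))
  th0 <- log(c(start[[1]]$k1, start[[1]]$k2, start[[1]]$k3, start[[1]]$k4,
               start[[2]]$k1, start[[2]]$k3, start[[2]]$k4,
               if (!shared_k2) start[[2]]$k2))
  unpack <- function(th) {
    th <- exp(th)
    pa <- gating_params(th[1], th[2], th[3], th[4], label = "fit_a")
    k2b <- if (shared_k2) th[2] else th[8]
    pb <- gating_params(th[5], k2b, th[6], th[7], label = "fit_b")
    list(pa, pb)
  }
  resid_fun <- function(th) {
    p <- unpack(th)
    sa <- summarize_event(simulate_gating(p[[1]], pulse, duration = 120, dt = 0.1))
    sb <- summarize_event(simulate_gating(p[[2]], pulse, duration = 120, dt = 0.1))
    red <- 1 - sb$peak_open_fraction / sa$peak_open_fraction
    ec50 <- p[[1]]$k2 * p[[1]]$k4 / (p[[1]]$k1 * (p[[1]]$k3 + p[[1]]$k4))
    c(rise_a  = (sa$rise_10_90 - targets$rise[1]) / targets$rise[1],
      rise_b  = (sb$rise_10_90 - targets$rise[2]) / targets$rise[2],
      decay_a = (sa$decay_tau - targets$decay[1]) / targets$decay[1],
      decay_b = (sb$decay_tau - targets$decay[2]) / targets$decay[2],
      peak_min = max(0, targets$peak_min - sa$peak_open_fraction) / targets$peak_min,
      peak_reduction = (red - targets$peak_reduction) / targets$peak_reduction,
      ec50 = (ec50 - targets$ec50) / targets$ec50)
  }
  obj <- function(th) sum(weights * resid_fun(th)^2)
  opt <- stats::optim(th0, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
  if (opt$convergence != 0)
    warning("constraint fit did not fully converge (code ", opt$convergence, ")")
  p <- unpack(opt$par)
  list(params_a = p[[1]], params_b = p[[2]],
       residuals = resid_fun(opt$par), convergence = opt$convergence,
       objective = opt$value)
}

#' Fit one-phase depression of an evoked IPSC train
#'
#' Amplitudes are normalized to the mean of the first three pulses, then
#' fitted with \eqn{A(n) = plateau + (1 - plateau) e^{-n/\tau_n}} where n
#' is the pulse index. Constant input returns plateau 1 with a flag.
#'
#' @param amplitudes numeric vector of per-pulse peak amplitudes (>= 5).
#' @return list of class `train_depression_fit` with `normalized`,
#'   `plateau`, `tau_n` (in pulses) and `degenerate` flag.
#' @export
fit_train_depression <- function(amplitudes) {
  if (length(amplitudes) < 5) stop("need at least 5 pulses")
  norm <- amplitudes / mean(amplitudes[1:3])
  n <- seq_along(norm)
  if (stats::sd(norm) < 1e-12) {
    return(structure(list(normalized = norm, plateau = 1, tau_n = NA_real_,
                          degenerate = TRUE), class = "train_depression_fit"))
  }
  fit <- minpack.lm::nlsLM(
    norm ~ plateau + (1 - plateau) * exp(-n / tau_n),
    start = list(plateau = max(min(norm), 1e-3), tau_n = length(norm) / 4),
    lower = c(0, 1e-3), upper = c(2, 10 * length(norm)))
  co <- stats::coef(fit)
  structure(list(normalized = norm, plateau = co[["plateau"]],
                 tau_n = co[["tau_n"]], degenerate = FALSE),
            class = "train_depression_fit")
}
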