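#' Conductance-based LIF neuron parameters
#'
#' Parameter container for the leaky integrate-and-fire neuron with a single
#' excitatory conductance. The membrane obeys
#' \deqn{\tau_m \frac{dV}{dt} = -(V - V_L) - \frac{g_E}{g_L}(V - V_E)}
#' and the conductance decays with \eqn{\tau_E}, jumping by
#' \eqn{\eta \sum_j w_{j,i}} on presynaptic spikes. When \eqn{V > V_{th}} the
#' neuron emits a spike, resets to \eqn{V_L} and stays refractory for
#' `t_ref` ms.
#'
#' Numeric values are not dictated by the behavioural claims the package
#' reproduces; the defaults are standard cortical-neuron values and every one
#' is configurable.
#'
#' @param tau_m Membrane time constant (ms).
#' @param tau_e Excitatory conductance decay constant (ms).
#' @param g_l Leak conductance (dimensionless base for the conductance ratio).
#' @param v_l Leak/reset potential (mV).
#' @param v_e Excitatory reversal potential (mV).
#' @param v_th Firing threshold (mV).
#' @param t_ref Refractory duration (ms).
#' @param eta Conductance learning/scaling rate (dimensionless).
#' @param dt Simulation step (ms).
#' @return An object of class `lif_params`.
#' @export
#' @examples
#' p <- lif_params()
#' p$v_th
lif_params <- function(tau_m = 20, tau_e = 5, g_l = 1, v_l = -70, v_e = 0,
                       v_th = -54, t_ref = 2, eta = 0.5, dt = 0.1) {
  stopifnot(tau_m > 0, tau_e > 0, g_l > 0, t_ref >= 0, dt > 0)
  if (!(v_l < v_th && v_th < v_e)) {
    stop("LIF parameters must satisfy v_l < v_th < v_e", call. = FALSE)
  }
  structure(list(tau_m = tau_m, tau_e = tau_e, g_l = g_l, v_l = v_l,
                 v_e = v_e, v_th = v_th, t_ref = t_ref, eta = eta, dt = dt),
            class = "lif_params")
}

#' Initial state of a single LIF neuron
#'
#' @param params A [lif_params()] object.
#' @return A list with components `v` (membrane potential, mV), `g_e`
#'   (excitatory conductance), `t_ref` (remaining refractory time, ms) and
#'   `spiked` (logical flag for the current step).
#' @export
lif_state <- function(params = lif_params()) {
  list(v = params$v_l, g_e = 0, t_ref = 0, spiked = FALSE)
}

#' Advance a single LIF neuron by one time step
#'
#' Reference single-neuron implementation of the membrane and conductance
#' dynamics: the conductance decays with `tau_e` and jumps by
#' `eta * sum(weights_row * presyn_spikes)` on presynaptic spikes; the
#' membrane integrates the leak and conductance currents; crossing `v_th`
#' emits a spike, resets `v` to `v_l` and starts the refractory period,
#' during which `v` is clamped at `v_l`.
#'
#' @param state Neuron state as returned by [lif_state()] or a previous call.
#' @param params A [lif_params()] object.
#' @param presyn_spikes Binary vector of presynaptic spike indicators.
#' @param weights_row Synaptic weights from each presynaptic neuron.
#' @param dt Time step (ms); defaults to `params$dt`.
#' @return The updated state list.
#' @export
#' @examples
#' s <- lif_state()
#' s <- lif_step(s, lif_params(), presyn_spikes = 1, weights_row = 2)
lif_step <- function(state, params, presyn_spikes = numeric(0),
                     weights_row = numeric(0), dt = params$dt) {
  stopifnot(dt > 0)
  if (!all(is.finite(c(state$v, state$g_e, state$t_ref))) ||
      !all(is.finite(weights_row)) || !all(is.finite(presyn_spikes))) {
    stop("non-finite neuron state, spikes or weights", call. = FALSE)
  }
  if (length(presyn_spikes) != length(weights_row)) {
    stop("spike train and weight row lengths differ", call. = FALSE)
  }
  if (!all(presyn_spikes %in% c(0, 1))) {
    stop("spike indicators must be 0 or 1", call. = FALSE)
  }
  g <- state$g_e + dt / params$tau_e * (-state$g_e) +
    params$eta * sum(weights_row * presyn_spikes)
  g <- max(g, 0)
  v <- state$v
  t_rem <- state$t_ref
  spiked <- FALSE
  if (t_rem > 0) {
    v <- params$v_l
    t_rem <- max(t_rem - dt, 0)
  } else {
    v <- v + dt / params$tau_m *
      (-(v - params$v_l) - g / params$g_l * (v - params$v_e))
    if (v > params$v_th) {
      spiked <- TRUE
      v <- params$v_l
      t_rem <- params$t_ref
    }
  }
  list(v = v, g_e = g, t_ref = t_rem, spiked = spiked)
}

#' Subthreshold steady-state potential for a fixed conductance
#'
#' Fixed point of the membrane equation when the conductance is held
#' constant: `(v_l + (g_e / g_l) * v_e) / (1 + g_e / g_l)`.
#'
#' @param g_e Excitatory conductance.
#' @param params A [lif_params()] object.
#' @return Steady-state membrane potential (mV).
#' @export
lif_steady_state <- function(g_e, params = lif_params()) {
  r <- g_e / params$g_l
  (params$v_l + r * params$v_e) / (1 + r)
}

# normalised potential: 0 at rest, 1 at threshold
norm_potential <- function(v, params) {
  (v - params$v_l) / (params$v_th - params$v_l)
}
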