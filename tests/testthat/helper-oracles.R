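# Independent fine-step integration oracle for the conductance-based LIF
# subthreshold dynamics (no spiking): Euler at dt/100, written without any
# package internals.
oracle_lif_trajectory <- function(params, g_drive, t_end, dt_fine) {
  n <- as.integer(round(t_end / dt_fine))
  v <- params$v_l
  g <- 0
  traj_t <- seq_len(n) * dt_fine
  traj_v <- numeric(n)
  for (i in seq_len(n)) {
    g <- g + dt_fine / params$tau_e * (-g + g_drive)
    v <- v + dt_fine / params$tau_m *
      (-(v - params$v_l) - g / params$g_l * (v - params$v_e))
    traj_v[i] <- v
  }
  list(t = traj_t, v = traj_v, g = g)
}

# Coupled 2-2-2 feed-forward ODE system integrated with deSolve (independent
# of the package's stepping code). Subthreshold regime, no feedback.
oracle_toy_net <- function(w1, w2, input, params, eta, t_end) {
  span <- params$v_th - params$v_l
  deriv <- function(t, y, p) {
    gh <- y[1:2]; vh <- y[3:4]; go <- y[5:6]; vo <- y[7:8]
    vhn <- pmax((vh - params$v_l) / span, 0)
    dgh <- (-gh + eta * as.numeric(t(w1) %*% input)) / params$tau_e
    dvh <- (-(vh - params$v_l) - gh / params$g_l * (vh - params$v_e)) /
      params$tau_m
    dgo <- (-go + eta * as.numeric(t(w2) %*% vhn)) / params$tau_e
    dvo <- (-(vo - params$v_l) - go / params$g_l * (vo - params$v_e)) /
      params$tau_m
    list(c(dgh, dvh, dgo, dvo))
  }
  y0 <- c(0, 0, params$v_l, params$v_l, 0, 0, params$v_l, params$v_l)
  out <- deSolve::ode(y0, times = c(0, t_end), func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-10)
  list(v_hidden = out[2, 4:5], v_output = out[2, 8:9])
}

# a tiny linearly separable two-pattern task for the training fixture
toy_samples <- function() {
  list(list(input = c(1, 0), target = 1L),
       list(input = c(0, 1), target = 2L))
}

toy_net <- function(seed = 1L, epochs = 30) {
  # two samples per epoch need a larger consolidation step than the
  # 320-sample task defaults
  vpsnn_network(2, 2, 2, labels = c("a", "b"),
                schedule = vpsnn_schedule(epochs = epochs,
                                          max_epochs = epochs + 20,
                                          window = 50, kappa = 0.1,
                                          seed = seed),
                seed = seed)
}
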