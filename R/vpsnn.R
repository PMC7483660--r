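#' Training schedule for a voltage-driven plasticity network
#'
#' Bundles the time course and learning rates for the four-step training
#' scheme (feed-forward propagation, homeostatic potential learning,
#' supervised last-layer teaching, STDP consolidation). The blending weight
#' `t/T` ramps linearly from purely homeostatic dynamics at the start of
#' training to purely feed-forward dynamics at the end, where `t` counts
#' sample presentations and `T = epochs * n_samples`.
#'
#' @param epochs Scheduled number of passes over the training set during the
#'   blend ramp.
#' @param max_epochs Hard cap on total passes; after the ramp, training
#'   continues in feed-forward mode until the training set is classified
#'   perfectly or this cap is reached.
#' @param eta_i Homeostatic learning rate.
#' @param eta_c Teacher learning rate.
#' @param kappa STDP proportionality constant.
#' @param window Stimulus presentation window per sample (ms).
#' @param dt Simulation step (ms).
#' @param theta Normalised homeostatic target threshold.
#' @param spike_boost Rate-code weight: milliseconds of threshold-level
#'   activity credited per emitted spike in the activity average.
#' @param decay Per-sample multiplicative decay of the input weights,
#'   pruning synapses the task never recruits (input channels that carry no
#'   information about the target, such as object identity, shrink toward
#'   zero instead of injecting initialisation noise).
#' @param margin_min Minimum winner-vs-runner-up activity margin required on
#'   every training sample before training counts as converged; razor-thin
#'   fits generalise erratically, so training continues (or restarts) until
#'   the fit is comfortable.
#' @param seed Random seed for sample shuffling.
#' @return An object of class `vpsnn_schedule`.
#' @export
vpsnn_schedule <- function(epochs = 60, max_epochs = 200, eta_i = 0.1,
                           eta_c = 0.5, kappa = 0.01, window = 100, dt = 0.1,
                           theta = 1, spike_boost = 10, decay = 1e-4,
                           margin_min = 0.15, seed = 1L) {
  stopifnot(epochs >= 1, max_epochs >= epochs, window >= dt, dt > 0)
  structure(list(epochs = epochs, max_epochs = max_epochs, eta_i = eta_i,
                 eta_c = eta_c, kappa = kappa, window = window, dt = dt,
                 theta = theta, spike_boost = spike_boost, decay = decay,
                 margin_min = margin_min, seed = as.integer(seed)),
            class = "vpsnn_schedule")
}

#' Construct a three-layer voltage-driven plasticity spiking network
#'
#' Shallow feed-forward spiking network with analog clamped inputs, spiking
#' LIF hidden units and non-resetting output integrators whose time-averaged
#' normalised potential is the decision variable. Weight matrices are
#' initialised uniformly and bounded during learning (`w1` in `[0, w1_max]`,
#' `w2` in `[-w2_max, w2_max]`); the hidden projection stays excitatory while
#' the supervised readout may become inhibitory.
#'
#' @param n_in,n_hidden,n_out Layer sizes.
#' @param labels Output labels, length `n_out`.
#' @param params A [lif_params()] object.
#' @param schedule A [vpsnn_schedule()] object.
#' @param w1_max,w2_max Weight bounds.
#' @param init_range Range of the uniform weight initialisation.
#' @param fb Feedback scale of the reciprocal output-to-hidden connections
#'   (same synapses used backwards); the teaching signal reaches the hidden
#'   layer through them.
#' @param seed Random seed for initialisation.
#' @return An object of class `vpsnn`.
#' @export
#' @examples
#' net <- vpsnn_network(24, 3, 3, labels = c("left", "right", "unseen"))
vpsnn_network <- function(n_in, n_hidden, n_out, labels = NULL,
                          params = lif_params(), schedule = vpsnn_schedule(),
                          w1_max = 1.5, w2_max = 4,
                          init_range = c(0.02, 0.15), fb = 0.3, seed = 1L) {
  stopifnot(n_in >= 1, n_hidden >= 1, n_out >= 1)
  if (is.null(labels)) labels <- paste0("out", seq_len(n_out))
  stopifnot(length(labels) == n_out)
  set.seed(as.integer(seed))
  w1 <- matrix(runif(n_in * n_hidden, init_range[1], init_range[2]),
               n_in, n_hidden)
  w2 <- matrix(runif(n_hidden * n_out, init_range[1], init_range[2]),
               n_hidden, n_out)
  structure(list(n_in = n_in, n_hidden = n_hidden, n_out = n_out,
                 labels = labels, w1 = w1, w2 = w2, params = params,
                 schedule = schedule, w1_max = w1_max, w2_max = w2_max,
                 fb = fb, trained = FALSE, converged = NA, history = NULL,
                 seed = as.integer(seed)),
            class = "vpsnn")
}

#' @export
print.vpsnn <- function(x, ...) {
  cat(sprintf("<vpsnn %d-%d-%d  labels: %s  trained: %s>\n",
              x$n_in, x$n_hidden, x$n_out,
              paste(x$labels, collapse = "/"),
              if (isTRUE(x$trained)) "yes" else "no"))
  invisible(x)
}

#' Run a feed-forward presentation window
#'
#' Drives the input layer with constant currents for `window` ms and
#' integrates the hidden and output layers (pure feed-forward dynamics; the
#' homeostatic correction is off). Returns per-layer activity and spike
#' counts together with the first output threshold-crossing times.
#'
#' @param net A [vpsnn_network()].
#' @param input Numeric input currents (binary percepts, possibly with
#'   working-memory superposition).
#' @param window Presentation window (ms); default from the schedule.
#' @param blend Blending weight `t/T` between feed-forward and homeostatic
#'   dynamics (1 = pure feed-forward, used at inference).
#' @param clamp Optional teacher clamp: normalised output potentials held
#'   fixed for the whole window (training only).
#' @param fb Feedback scale; defaults to the network's.
#' @return A list with `act_hidden`, `act_output` (time-averaged normalised
#'   potentials), `v_hidden_final`, `v_output_final` (mV), `spikes_hidden`,
#'   `spikes_output`, `imbalance_hidden`, `imbalance_output` (mean
#'   homeostatic imbalance) and `decision_ms` (first crossing per output).
#' @export
feed_forward_pass <- function(net, input, window = net$schedule$window,
                              blend = 1, clamp = NULL, fb = net$fb) {
  stopifnot(inherits(net, "vpsnn"))
  if (window < net$schedule$dt) {
    stop("presentation window shorter than one time step", call. = FALSE)
  }
  if (!all(is.finite(net$w1)) || !all(is.finite(net$w2))) {
    stop("non-finite synaptic weights", call. = FALSE)
  }
  n_steps <- as.integer(round(window / net$schedule$dt))
  prm <- net$params
  prm$dt <- net$schedule$dt
  sim_window_cpp(net$w1, net$w2, as.numeric(input), unclass(prm), n_steps,
                 blend, net$schedule$eta_i, net$schedule$theta,
                 net$schedule$spike_boost, fb, clamp)
}

#' Homeostatic input-output imbalance of one neuron
#'
#' `delta_e = v_i - (sum(weights_col * presyn_v) - v_th_i)`: zero when the
#' neuron's potential matches its weighted input drive less the threshold.
#'
#' @param v_i Postsynaptic potential.
#' @param weights_col Incoming synaptic weights.
#' @param presyn_v Presynaptic potentials.
#' @param v_th_i Postsynaptic threshold.
#' @return The scalar imbalance.
#' @export
homeostatic_imbalance <- function(v_i, weights_col, presyn_v, v_th_i) {
  stopifnot(is.finite(v_i), all(is.finite(weights_col)),
            all(is.finite(presyn_v)), is.finite(v_th_i))
  stopifnot(length(weights_col) == length(presyn_v))
  v_i - (sum(weights_col * presyn_v) - v_th_i)
}

#' Homeostatic membrane-potential update
#'
#' `-eta_i * (v_i - (sum(w v_j) - sum_j v_th_i)) - (v_i - v_l)
#'  - (g_e / g_l) * (v_i - v_e)`: the unsupervised potential correction that
#' drives each neuron toward input-output balance while keeping the leak and
#' conductance terms of the membrane equation.
#'
#' @param v_i Postsynaptic potential.
#' @param weights_col Incoming synaptic weights.
#' @param presyn_v Presynaptic potentials.
#' @param params A [lif_params()] object supplying `v_l`, `v_e`, `g_l`,
#'   `v_th`.
#' @param eta_i Homeostatic learning rate.
#' @param g_e Current excitatory conductance of the neuron.
#' @return The potential change.
#' @export
homeostatic_update <- function(v_i, weights_col, presyn_v, params, eta_i,
                               g_e = 0) {
  stopifnot(is.finite(v_i), all(is.finite(weights_col)),
            all(is.finite(presyn_v)), is.finite(g_e))
  n <- length(presyn_v)
  -eta_i * (v_i - (sum(weights_col * presyn_v) - n * params$v_th)) -
    (v_i - params$v_l) - g_e / params$g_l * (v_i - params$v_e)
}

#' Blend feed-forward and homeostatic potential updates
#'
#' Convex combination `(t/T) * dv_ff + (1 - t/T) * dv_homeo`, the training
#' course that starts from homeostatic dynamics and ends at pure
#' feed-forward dynamics.
#'
#' @param dv_ff Feed-forward potential change.
#' @param dv_homeo Homeostatic potential change.
#' @param t Current training step.
#' @param t_total Total training steps.
#' @return The blended change.
#' @export
blended_update <- function(dv_ff, dv_homeo, t, t_total) {
  stopifnot(t_total > 0)
  if (t < 0 || t > t_total) {
    stop("training step t must lie in [0, T]", call. = FALSE)
  }
  (t / t_total) * dv_ff + (1 - t / t_total) * dv_homeo
}

#' Supervised teacher update for output neurons
#'
#' Moves each output potential toward its teacher signal:
#' `dv = -eta_c * (v_i - v_t)`. Only the last (output) layer receives a
#' teaching signal, and only during training.
#'
#' @param v_i Output potentials.
#' @param v_t Teacher potentials, same length.
#' @param eta_c Teacher learning rate.
#' @param layer Which layer the update targets; anything but `"output"` is
#'   rejected.
#' @return Potential changes.
#' @export
teacher_update <- function(v_i, v_t, eta_c, layer = "output") {
  if (!identical(layer, "output")) {
    stop("teaching signals apply to the output layer only", call. = FALSE)
  }
  stopifnot(length(v_i) == length(v_t))
  -eta_c * (v_i - v_t)
}

#' STDP weight consolidation
#'
#' Adds `kappa * v_j * dv_i` to every synapse: presynaptic potential times
#' postsynaptic potential change, the rate-based reading of spike-timing-
#' dependent plasticity used to consolidate potential changes into weights.
#'
#' @param presyn_v Presynaptic potentials (length `nrow(weights)`).
#' @param postsyn_dv Postsynaptic potential derivatives (length
#'   `ncol(weights)`).
#' @param weights Weight matrix, presynaptic neurons in rows.
#' @param kappa Proportionality constant.
#' @return The updated weight matrix.
#' @export
stdp_consolidate <- function(presyn_v, postsyn_dv, weights, kappa) {
  if (length(presyn_v) != nrow(weights) ||
      length(postsyn_dv) != ncol(weights)) {
    stop("potential vectors do not match the weight matrix shape",
         call. = FALSE)
  }
  weights + kappa * outer(presyn_v, postsyn_dv)
}

#' Winner-take-all decode of output activity
#'
#' @param activity Spike counts or time-averaged output potentials.
#' @param labels Output labels; defaults to indices.
#' @param tol Tie tolerance: a winning margin at or below `tol` yields
#'   `"no-decision"` so that downstream circuits can observe ambiguous
#'   responses instead of a silent coin flip.
#' @return A single label or `"no-decision"`.
#' @export
#' @examples
#' decode_output(c(5, 0, 0), c("left", "right", "unseen"))
decode_output <- function(activity, labels = NULL, tol = 1e-6) {
  if (is.null(labels)) labels <- as.character(seq_along(activity))
  stopifnot(length(labels) == length(activity))
  ord <- order(activity, decreasing = TRUE)
  if (length(activity) > 1 &&
      activity[ord[1]] - activity[ord[2]] <= tol) {
    return("no-decision")
  }
  labels[ord[1]]
}

#' Classify one input with a trained network
#'
#' @param net A trained [vpsnn_network()].
#' @param input Input currents.
#' @param tol Decode tie tolerance.
#' @return A list with `label`, `activity` (mean output potentials) and
#'   `decision_ms` (first threshold crossing of the winner, `NA` if the
#'   winner never crossed).
#' @export
vpsnn_infer <- function(net, input, tol = 1e-6) {
  res <- feed_forward_pass(net, input)
  lab <- decode_output(res$act_output, net$labels, tol)
  dm <- NA_real_
  if (lab != "no-decision") {
    dm <- res$decision_ms[match(lab, net$labels)]
  }
  list(label = lab, activity = res$act_output, decision_ms = dm)
}

#' Train a network with the four-step voltage-driven scheme
#'
#' For every sample each epoch: (1) a free feed-forward presentation with
#' the homeostatic correction blended in at weight `1 - t/T`; (2) the
#' teacher signal applied to the output layer — a second presentation with
#' the output potentials clamped to the teacher state, whose influence
#' reaches the hidden layer through the reciprocal synapses; (3) STDP
#' consolidation of the teaching-induced potential changes into the
#' weights: the readout weights integrate presynaptic activity times the
#' teacher displacement of the outputs, the hidden weights integrate input
#' currents times the teaching-induced displacement of the hidden
#' potentials (free vs clamped difference). After the scheduled ramp,
#' training continues in pure feed-forward mode until the training set is
#' perfectly classified or `max_epochs` is reached.
#'
#' @param net A [vpsnn_network()].
#' @param samples List of samples, each `list(input = , target = )` with
#'   `target` an index into the output labels.
#' @param schedule Optional [vpsnn_schedule()] overriding the network's.
#' @param teacher_hi Teacher potential for the target neuron (mV); default
#'   4 mV above threshold.
#' @return The trained network, with `converged` (logical), `epochs_run` and
#'   `history` (a data frame with per-epoch teacher loss, mean absolute
#'   layer imbalance and blend weight). Non-convergence is reported in the
#'   returned object, never masked.
#' @export
train_vpsnn <- function(net, samples, schedule = NULL, teacher_hi = NULL) {
  stopifnot(inherits(net, "vpsnn"), length(samples) >= 1)
  if (!is.null(schedule)) net$schedule <- schedule
  sch <- net$schedule
  prm <- net$params
  if (is.null(teacher_hi)) teacher_hi <- prm$v_th + 4
  v_t_hi <- norm_potential(teacher_hi, prm)
  n <- length(samples)
  for (s in samples) {
    if (length(s$input) != net$n_in) {
      stop("sample input length does not match the input layer",
           call. = FALSE)
    }
    if (s$target < 1 || s$target > net$n_out) {
      stop("sample target outside the output layer", call. = FALSE)
    }
  }
  t_total <- sch$epochs * n
  set.seed(sch$seed)
  t_glob <- 0
  hist <- list()
  converged <- FALSE
  epochs_run <- 0
  x <- do.call(rbind, lapply(samples, function(s) as.numeric(s$input)))
  tgt <- vapply(samples, function(s) as.integer(s$target), integer(1))
  n_steps <- as.integer(round(sch$window / sch$dt))
  prm <- net$params
  prm$dt <- sch$dt
  ema1 <- NULL
  ema2 <- NULL
  best_acc <- -Inf
  best_margin <- -Inf
  best_w <- NULL
  for (ep in seq_len(sch$max_epochs)) {
    ord <- sample.int(n)
    blend_ep <- min(t_glob / t_total, 1)
    res <- train_epoch_cpp(net$w1, net$w2, x, tgt, ord, unclass(prm),
                           n_steps, t_glob, t_total, sch$eta_i, sch$theta,
                           sch$spike_boost, net$fb, sch$eta_c, sch$kappa,
                           v_t_hi, net$w1_max, net$w2_max, sch$decay)
    net$w1 <- res$w1
    net$w2 <- res$w2
    t_glob <- res$t_glob
    # late in training, track a smoothed weight trajectory: the per-sample
    # updates keep jittering around the fit, and the averaged synapses are
    # the consolidated long-term state
    if (blend_ep > 0.8) {
      if (is.null(ema1)) {
        ema1 <- net$w1
        ema2 <- net$w2
      } else {
        ema1 <- 0.8 * ema1 + 0.2 * net$w1
        ema2 <- 0.8 * ema2 + 0.2 * net$w2
      }
    }
    hist[[ep]] <- c(epoch = ep, loss = res$loss,
                    imbalance_hidden = res$imbalance_hidden,
                    imbalance_output = res$imbalance_output,
                    blend = blend_ep)
    epochs_run <- ep
    check <- ep == sch$epochs || ep == sch$max_epochs ||
      (ep > sch$epochs && (ep - sch$epochs) %% 5 == 0)
    if (check) {
      # keep the best-fitting state seen at any checkpoint: extended
      # training does not improve monotonically (the synaptic decay slowly
      # erodes a converged fit once the error pressure vanishes)
      for (cand in list(list(w1 = ema1, w2 = ema2),
                        list(w1 = net$w1, w2 = net$w2))) {
        if (is.null(cand$w1)) next
        probe <- net
        probe$w1 <- cand$w1
        probe$w2 <- cand$w2
        st <- vpsnn_fit_stats(probe, samples)
        if (st$accuracy > best_acc ||
            (st$accuracy == best_acc && st$margin > best_margin)) {
          best_acc <- st$accuracy
          best_margin <- st$margin
          best_w <- cand
        }
      }
      if (best_acc == 1 && best_margin >= sch$margin_min) break
    }
  }
  if (!is.null(best_w)) {
    net$w1 <- best_w$w1
    net$w2 <- best_w$w2
  }
  converged <- best_acc == 1
  net$trained <- TRUE
  net$converged <- converged
  net$fit_accuracy <- best_acc
  net$fit_margin <- best_margin
  net$epochs_run <- epochs_run
  net$history <- as.data.frame(do.call(rbind, hist))
  net
}

#' Training-set accuracy of a network
#'
#' @param net A [vpsnn_network()].
#' @param samples Samples as in [train_vpsnn()].
#' @return Fraction of samples whose decoded label index matches the target.
#' @export
vpsnn_accuracy <- function(net, samples) {
  act <- vpsnn_batch_activity(net, samples)
  ok <- vapply(seq_along(samples), function(k) {
    identical(decode_output(act[k, ], net$labels),
              net$labels[samples[[k]]$target])
  }, logical(1))
  mean(ok)
}

#' Training-set fit statistics
#'
#' Accuracy and the smallest winner-vs-runner-up margin over a training set
#' (negative when any sample is misclassified). Fits are ranked by accuracy
#' first and margin second: a confident fit with one bad row beats a
#' collapsed near-tie fit.
#'
#' @param net A [vpsnn_network()].
#' @param samples Samples as in [train_vpsnn()].
#' @return A list with `accuracy` and `margin`.
#' @export
vpsnn_fit_stats <- function(net, samples) {
  act <- vpsnn_batch_activity(net, samples)
  margins <- vapply(seq_along(samples), function(k) {
    tgt <- samples[[k]]$target
    act[k, tgt] - max(act[k, -tgt])
  }, numeric(1))
  list(accuracy = mean(margins > 0), margin = min(margins))
}

#' Smallest decision margin over a training set
#'
#' @param net A [vpsnn_network()].
#' @param samples Samples as in [train_vpsnn()].
#' @return The scalar margin (negative when any sample is misclassified).
#' @export
vpsnn_fit_margin <- function(net, samples) {
  vpsnn_fit_stats(net, samples)$margin
}

vpsnn_batch_activity <- function(net, samples) {
  x <- do.call(rbind, lapply(samples, function(s) as.numeric(s$input)))
  sch <- net$schedule
  prm <- net$params
  prm$dt <- sch$dt
  infer_batch_cpp(net$w1, net$w2, x, unclass(prm),
                  as.integer(round(sch$window / sch$dt)), sch$theta,
                  sch$spike_boost, net$fb)
}

#' Write a network checkpoint to JSON
#'
#' @param net A [vpsnn_network()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vpsnn <- function(net, path) {
  stopifnot(inherits(net, "vpsnn"))
  obj <- list(format = "spiketom-vpsnn", version = "1.0",
              n_in = net$n_in, n_hidden = net$n_hidden, n_out = net$n_out,
              labels = net$labels,
              w1 = as.numeric(net$w1), w2 = as.numeric(net$w2),
              params = unclass(net$params),
              schedule = unclass(net$schedule),
              w1_max = net$w1_max, w2_max = net$w2_max,
              trained = net$trained, converged = net$converged,
              seed = net$seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a network checkpoint from JSON
#'
#' @param path File written by [write_vpsnn()].
#' @return A [vpsnn_network()] object.
#' @export
read_vpsnn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "spiketom-vpsnn")) {
    stop("not a network checkpoint file", call. = FALSE)
  }
  net <- vpsnn_network(obj$n_in, obj$n_hidden, obj$n_out,
                       labels = obj$labels,
                       params = do.call(lif_params, as.list(obj$params)),
                       schedule = do.call(vpsnn_schedule,
                                          as.list(obj$schedule)),
                       w1_max = obj$w1_max, w2_max = obj$w2_max,
                       seed = obj$seed)
  net$w1 <- matrix(unlist(obj$w1), net$n_in, net$n_hidden)
  net$w2 <- matrix(unlist(obj$w2), net$n_hidden, net$n_out)
  net$trained <- obj$trained
  net$converged <- obj$converged
  net
}
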