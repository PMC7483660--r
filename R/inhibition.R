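#' Inhibitory-control circuit with maturation flags
#'
#' The perspective and belief selection gates: per-channel inhibitory
#' neurons carry the other-relevant pattern as inhibitory current against
#' the self-relevant pattern, temporary neurons hold the uninhibited
#' pattern for a second output (perspective gate only), and inhibit-result
#' neurons fire when inhibition fails, engaging the frontal gate if the
#' corresponding connection has matured. Maturation weights are binary:
#' 0 = immature, 1 = mature.
#'
#' Inhibition is per-channel subtractive with rectification
#' (`residual = max(self - other, 0)`), which reproduces both the
#' identical-pattern (silent) and conflicting-pattern (firing) regimes on
#' binary patterns. Full suppression of the other-relevant pattern on the
#' self-first path uses a current 10x the maximum stimulus current, enough
#' to silence every valid binary pattern.
#'
#' Stage latencies (ms of simulated time) are configurable; the defaults
#' place each stage in the tens-of-milliseconds range typical of cortical
#' processing stages, and only their orderings carry meaning.
#'
#' @param n_channels Channels of the gated population (same count as the
#'   gated store).
#' @param ifg_tpj Maturation of the frontal connection to the perspective
#'   gate (0 or 1).
#' @param ifg_vmpfc Maturation of the frontal connection to the self-belief
#'   store (0 or 1).
#' @param big_current Suppression current for the self-first path.
#' @param tpj_self_ms,tpj_other_ms Base gate latencies for self-first and
#'   other-first output ordering.
#' @param ifg_perspective_ms Added latency of frontal self-perspective
#'   inhibition.
#' @param ifg_belief_ms Added latency of frontal self-belief inhibition.
#' @param mpfc_export_ms Belief export latency.
#' @param conflict_settle_ms Extra settling latency when the inner
#'   inhibition must cancel a conflicting pattern.
#' @param ambiguity Resolution of the immature-belief-gate ambiguity:
#'   `"self"` (deterministic self-belief preference, the default) or
#'   `"stochastic"` (self-belief with probability `self_bias`).
#' @param self_bias Probability of the self-directed action under
#'   `ambiguity = "stochastic"`.
#' @return An object of class `inhibition_circuit`.
#' @export
inhibition_circuit <- function(n_channels = 24, ifg_tpj = 1, ifg_vmpfc = 1,
                               big_current = 10,
                               tpj_self_ms = 5.0, tpj_other_ms = 6.0,
                               ifg_perspective_ms = 53.8,
                               ifg_belief_ms = 17.5,
                               mpfc_export_ms = 10.0,
                               conflict_settle_ms = 0.4,
                               ambiguity = c("self", "stochastic"),
                               self_bias = 0.8) {
  stopifnot(ifg_tpj %in% c(0, 1), ifg_vmpfc %in% c(0, 1), big_current > 0)
  structure(list(n_channels = n_channels, ifg_tpj = ifg_tpj,
                 ifg_vmpfc = ifg_vmpfc, big_current = big_current,
                 tpj_self_ms = tpj_self_ms, tpj_other_ms = tpj_other_ms,
                 ifg_perspective_ms = ifg_perspective_ms,
                 ifg_belief_ms = ifg_belief_ms,
                 mpfc_export_ms = mpfc_export_ms,
                 conflict_settle_ms = conflict_settle_ms,
                 ambiguity = match.arg(ambiguity), self_bias = self_bias),
            class = "inhibition_circuit")
}

#' Detect a self/other representation conflict
#'
#' The inhibitory neurons receive the other-relevant pattern and apply it as
#' subtractive inhibition to the self-relevant pattern. When the patterns
#' are identical the inhibition succeeds and the inhibit-result population
#' stays silent; any positive residual makes it fire.
#'
#' @param self_pattern,other_pattern Same-length numeric patterns (percepts
#'   or belief codes).
#' @param circuit An [inhibition_circuit()].
#' @return A list with `residual` (per-channel rectified difference) and
#'   `inr_fired` (logical).
#' @export
conflict_detect <- function(self_pattern, other_pattern, circuit) {
  if (length(self_pattern) != length(other_pattern)) {
    stop("self and other patterns must have the same channel count",
         call. = FALSE)
  }
  residual <- pmax(self_pattern - other_pattern, 0)
  list(residual = residual, inr_fired = any(residual > 0))
}

#' Gate perspective output, other-relevant pattern first
#'
#' Reasoning-about-other mode. When the patterns conflict and the frontal
#' connection is mature, the gate suppresses the inhibit-result firing, the
#' other-relevant pattern is emitted first and the temporary neurons
#' re-drive the self-relevant pattern as the second output, at the cost of
#' added latency. With an immature connection the self-perspective
#' inhibition fails: the first output is the (invalid) superposition of the
#' two patterns. Without conflict the other pattern passes through with no
#' frontal involvement.
#'
#' @param self_pattern,other_pattern Same-length numeric patterns.
#' @param circuit An [inhibition_circuit()].
#' @return A gating outcome: `first` / `second` (each
#'   `list(pattern, source, valid)`), `inr_fired`, `ifg_activated`,
#'   `latency_ms`.
#' @export
gate_other_first <- function(self_pattern, other_pattern, circuit) {
  cd <- conflict_detect(self_pattern, other_pattern, circuit)
  if (!cd$inr_fired) {
    return(list(
      first = list(pattern = other_pattern, source = "pSTS", valid = TRUE),
      second = list(pattern = self_pattern, source = "IPL", valid = TRUE),
      inr_fired = FALSE, ifg_activated = FALSE,
      latency_ms = circuit$tpj_other_ms))
  }
  if (circuit$ifg_tpj == 1) {
    list(
      first = list(pattern = other_pattern, source = "pSTS", valid = TRUE),
      second = list(pattern = self_pattern, source = "IPL", valid = TRUE),
      inr_fired = TRUE, ifg_activated = TRUE,
      latency_ms = circuit$tpj_other_ms + circuit$ifg_perspective_ms)
  } else {
    # failed self-perspective inhibition: the predominant self-relevant
    # activity wins the conflicting channels, with residual other-relevant
    # activity superposed — the first output matches neither stored pattern
    corrupted <- pmax(self_pattern, 0.1 * other_pattern)
    list(
      first = list(pattern = corrupted, source = "superposition",
                   valid = FALSE),
      second = list(pattern = self_pattern, source = "IPL", valid = TRUE),
      inr_fired = TRUE, ifg_activated = FALSE,
      latency_ms = circuit$tpj_other_ms)
  }
}

#' Gate perspective output, self-relevant pattern first
#'
#' Reasoning-about-self mode. The inhibitory current is large enough to
#' suppress the other-relevant pattern completely regardless of conflict, so
#' the self pattern is always emitted first and the temporary neurons hold
#' the other pattern for the second output. No frontal gate is required.
#'
#' @param self_pattern,other_pattern Same-length numeric patterns.
#' @param circuit An [inhibition_circuit()].
#' @return A gating outcome as in [gate_other_first()].
#' @export
gate_self_first <- function(self_pattern, other_pattern, circuit) {
  if (length(self_pattern) != length(other_pattern)) {
    stop("self and other patterns must have the same channel count",
         call. = FALSE)
  }
  suppressed <- pmax(other_pattern - circuit$big_current, 0)
  list(
    first = list(pattern = self_pattern, source = "IPL", valid = TRUE),
    second = list(pattern = other_pattern, source = "pSTS", valid = TRUE),
    suppressed_other = suppressed,
    inr_fired = FALSE, ifg_activated = FALSE,
    latency_ms = circuit$tpj_self_ms)
}

#' Gate the belief export for an about-other question
#'
#' When the stored beliefs differ and the frontal connection to the self
#' store is mature, the self belief is inhibited and the other-attributed
#' belief exported (with added latency). When the connection is immature,
#' both candidate responses stay active and the outcome resolves toward the
#' self belief. Identical beliefs export directly with no frontal
#' involvement.
#'
#' @param store A [belief_store()].
#' @param circuit An [inhibition_circuit()].
#' @return A list with `belief`, `ambiguous`, `inr_fired`, `ifg_activated`
#'   and `latency_ms`.
#' @export
gate_belief <- function(store, circuit) {
  if (is.null(store$dmpfc) && is.null(store$vmpfc)) {
    return(list(belief = "no-belief", ambiguous = FALSE, inr_fired = FALSE,
                ifg_activated = FALSE, latency_ms = 0))
  }
  if (is.null(store$dmpfc)) {
    return(list(belief = "no-belief", ambiguous = FALSE, inr_fired = FALSE,
                ifg_activated = FALSE, latency_ms = 0))
  }
  if (identical(store$dmpfc, store$vmpfc) || is.null(store$vmpfc)) {
    return(list(belief = store$dmpfc, ambiguous = FALSE, inr_fired = FALSE,
                ifg_activated = FALSE,
                latency_ms = circuit$mpfc_export_ms))
  }
  if (circuit$ifg_vmpfc == 1) {
    list(belief = store$dmpfc, ambiguous = FALSE, inr_fired = TRUE,
         ifg_activated = TRUE,
         latency_ms = circuit$mpfc_export_ms + circuit$ifg_belief_ms +
           circuit$conflict_settle_ms)
  } else {
    chosen <- if (circuit$ambiguity == "self") {
      store$vmpfc
    } else {
      if (runif(1) < circuit$self_bias) store$vmpfc else store$dmpfc
    }
    list(belief = chosen, ambiguous = TRUE, inr_fired = TRUE,
         ifg_activated = FALSE,
         latency_ms = circuit$mpfc_export_ms + circuit$conflict_settle_ms)
  }
}
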