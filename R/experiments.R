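belief_stream <- function(agent, percepts, perspective) {
  # run perspective gating, perception and belief updating over a stream
  circuit <- agent$circuit
  zeta <- agent$config$zeta
  gates <- lapply(percepts, function(p) {
    s <- encode_sts(p$self)$currents
    o <- encode_sts(p$other)$currents
    if (perspective == "other") {
      gate_other_first(s, o, circuit)
    } else {
      gate_self_first(s, o, circuit)
    }
  })
  conflict <- any(vapply(gates, `[[`, logical(1), "inr_fired"))
  ifg <- any(vapply(gates, `[[`, logical(1), "ifg_activated"))
  wm_pc <- working_memory(zeta, agent$precuneus$n_in)
  wm_acc <- working_memory(zeta, 2)
  outcomes <- character(length(gates))
  beliefs <- character(length(gates))
  pc_ms <- acc_ms <- rep(NA_real_, length(gates))
  for (k in seq_along(gates)) {
    res <- precuneus_infer(gates[[k]]$first$pattern, wm_pc, agent$precuneus)
    wm_pc <- res$wm
    outcomes[k] <- res$outcome
    pc_ms[k] <- res$decision_ms
    bel <- acc_infer(res$outcome, wm_acc, agent$acc)
    wm_acc <- bel$wm
    beliefs[k] <- bel$belief
    acc_ms[k] <- bel$decision_ms
  }
  tpj_ms <- if (perspective == "other") {
    circuit$tpj_other_ms +
      if (conflict && circuit$ifg_tpj == 1) circuit$ifg_perspective_ms else 0
  } else {
    circuit$tpj_self_ms
  }
  list(outcomes = outcomes, beliefs = beliefs,
       final_belief = beliefs[length(beliefs)],
       conflict = conflict, ifg_activated = ifg, tpj_ms = tpj_ms,
       tpj_base_ms = if (perspective == "other") circuit$tpj_other_ms
                     else circuit$tpj_self_ms,
       precuneus_ms = pc_ms, acc_ms = acc_ms)
}

trace_rows <- function(question, condition, stages) {
  onset <- 0
  rows <- lapply(seq_along(stages), function(i) {
    dur <- stages[[i]]$dur
    r <- data.frame(question = question, condition = condition,
                    region = stages[[i]]$region, role = stages[[i]]$role,
                    onset = onset, offset = onset + dur,
                    duration = dur, stringsAsFactors = FALSE)
    onset <<- onset + dur
    r
  })
  do.call(rbind, rows)
}

#' Run a test scenario on a trained agent
#'
#' Streams the scenario events through perception encoding and perspective
#' routing, runs visual-access and belief reasoning along the
#' reasoning-about-other and reasoning-about-self pathways, applies the
#' belief-selection gate for each question, and compares the pointing
#' gestures to the scenario's ground truth. An activation trace records the
#' serial region onsets/offsets per question, with the frontal-gate
#' insertions where the gate engaged.
#'
#' @param agent A [train_agent()] result.
#' @param scenario A [gen_test_scenario()] object.
#' @return An object of class `task_result`: `answers`, `gestures`, `pass`,
#'   `trace` (a data frame), `details` (per-frame perception outcomes and
#'   beliefs per perspective, gate states).
#' @export
run_test <- function(agent, scenario) {
  stopifnot(inherits(agent, "tom_agent"), inherits(scenario, "test_scenario"))
  validate_scenario(scenario)
  percepts <- scenario_percepts(scenario)

  # perspective routing (conservation checked by construction)
  store <- perspective_store()
  for (p in percepts) {
    store <- tpj_route(encode_sts(p$self), store)
    store <- tpj_route(encode_sts(p$other), store)
  }

  other <- belief_stream(agent, percepts, "other")
  self <- belief_stream(agent, percepts, "self")

  beliefs <- belief_store()
  beliefs <- store_belief(beliefs, self$final_belief, "self", "IPL")
  beliefs <- store_belief(beliefs, other$final_belief, "other", "pSTS")

  sel_other <- mpfc_select(beliefs, "about-other", agent$circuit)
  sel_self <- mpfc_select(beliefs, "about-self", agent$circuit)
  answers <- c(`about-other` = sel_other$belief,
               `about-self` = sel_self$belief)
  gestures <- list(`about-other` = motor_respond(sel_other$belief,
                                                 "other-belief"),
                   `about-self` = motor_respond(sel_self$belief,
                                                "self-belief"))
  gt <- scenario$ground_truth
  pass <- identical(gestures$`about-other`$gesture,
                    paste0("point-", gt$other)) &&
    identical(gestures$`about-self`$gesture, paste0("point-", gt$self))

  incongruent <- !identical(gt$other, gt$self)
  cond <- function(side) {
    paste0(side, "-", if (incongruent) "incongruent" else "congruent")
  }
  cfg <- agent$config
  circ <- agent$circuit
  mean_ms <- function(x, default) {
    x <- x[!is.na(x)]
    if (length(x)) mean(x) else default
  }
  stage_list <- function(stream, sel, question) {
    st <- list(
      list(region = "STS", role = "encoding", dur = cfg$sts_ms),
      list(region = "TPJ", role = "routing", dur = stream$tpj_base_ms))
    if (stream$ifg_activated) {
      st <- c(st, list(list(region = "IFG", role = "perspective-inhibition",
                            dur = circ$ifg_perspective_ms)))
    }
    st <- c(st, list(
      list(region = "Precuneus/PCC", role = "visual-access",
           dur = mean_ms(stream$precuneus_ms, cfg$window)),
      list(region = "ACC", role = "belief", dur = mean_ms(stream$acc_ms,
                                                          cfg$window)),
      list(region = "mPFC", role = "belief-export",
           dur = circ$mpfc_export_ms)))
    extra <- sel$latency_ms - circ$mpfc_export_ms
    if (!is.null(sel$gating) && isTRUE(sel$gating$ifg_activated)) {
      st <- c(st, list(list(region = "IFG", role = "belief-inhibition",
                            dur = extra)))
    } else if (extra > 0) {
      st <- c(st, list(list(region = "mPFC", role = "conflict-settle",
                            dur = extra)))
    }
    c(st, list(
      list(region = "IFG", role = "goal-encoding", dur = cfg$ifg_goal_ms),
      list(region = "vPMC/M1", role = "motor", dur = cfg$vpmc_ms)))
  }
  trace <- rbind(
    trace_rows("about-other", cond("other"),
               stage_list(other, sel_other, "about-other")),
    trace_rows("about-self", cond("self"),
               stage_list(self, sel_self, "about-self")))

  structure(list(answers = answers, gestures = gestures, pass = pass,
                 trace = trace, scenario_kind = scenario$kind,
                 details = list(other = other, self = self,
                                beliefs = beliefs,
                                sel_other = sel_other, sel_self = sel_self)),
            class = "task_result")
}

#' @export
print.task_result <- function(x, ...) {
  cat(sprintf("<task_result %s  other: %s  self: %s  %s>\n",
              x$scenario_kind, x$answers[["about-other"]],
              x$answers[["about-self"]],
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Summarise reasoning latencies from an activation trace
#'
#' Computes per-condition totals and per-region durations from a trace.
#' The headline `reasoning_ms` covers the perspective gate, the frontal
#' inhibition insertions and the belief export (TPJ + inhibitory IFG +
#' mPFC) — the stages whose durations differ between conditions; the common
#' encoding, perception, belief-update, goal-encoding and motor stages are
#' reported per region but excluded from the comparison totals since they
#' are near-identical across tasks.
#'
#' @param trace A trace data frame from [run_test()] (possibly several
#'   row-bound together).
#' @param regions Regions included in the reasoning total.
#' @return A list with `by_condition` (condition, reasoning_ms, total_ms)
#'   and `by_region` (condition, region, role, duration) data frames.
#' @export
measure_timing <- function(trace,
                           regions = c("TPJ", "IFG", "mPFC")) {
  need <- c("condition", "region", "role", "duration")
  if (!is.data.frame(trace) || !all(need %in% names(trace))) {
    stop("malformed activation trace", call. = FALSE)
  }
  if (any(!is.finite(trace$duration)) || any(trace$duration < 0)) {
    stop("malformed activation trace: bad durations", call. = FALSE)
  }
  keep <- trace$region %in% regions & trace$role != "goal-encoding"
  agg <- stats::aggregate(duration ~ condition, data = trace[keep, ],
                          FUN = sum)
  names(agg)[2] <- "reasoning_ms"
  tot <- stats::aggregate(duration ~ condition, data = trace, FUN = sum)
  names(tot)[2] <- "total_ms"
  by_cond <- merge(agg, tot, by = "condition")
  by_region <- stats::aggregate(duration ~ condition + region + role,
                                data = trace, FUN = sum)
  list(by_condition = by_cond, by_region = by_region)
}

protocol_runs <- function(protocol) {
  # the agents to train and the scenarios each must face
  switch(protocol,
         blindfold = list(
           list(group = "opaque", kinds = "blindfold-opaque"),
           list(group = "transparent", kinds = "blindfold-transparent")),
         turn = list(list(group = "turn", kinds = c("turn-false",
                                                    "turn-true"))),
         stop("unknown protocol: ", protocol, call. = FALSE))
}

#' Repeat a full train-and-test protocol
#'
#' Retrains and retests `n` times; repetition `k` derives its seed from the
#' master seed so the runs differ in training randomness. The blindfold
#' protocol trains an opaque-group and a transparent-group agent per
#' repetition and tests each on its scenario; the turn protocol trains one
#' agent and tests it on the false- and true-belief turn scenarios. A
#' repetition passes when every question of every scenario is answered
#' correctly. Convergence failures are counted separately from task
#' failures.
#'
#' @param config A [tom_config()] (its `group` is overridden per run).
#' @param n Number of repetitions.
#' @param protocol `"blindfold"` or `"turn"`.
#' @param reuse_agent Reuse one trained agent across repetitions instead of
#'   retraining (the weaker protocol variant).
#' @return An object of class `tom_repeat`: `pass_count`, `n`,
#'   `convergence_failures`, `runs` (per-repetition data frame), `timing`
#'   (per-repetition condition latencies) and `timing_summary` (mean and sd
#'   per region and condition).
#' @export
repeat_experiment <- function(config = tom_config(), n = 20,
                              protocol = c("blindfold", "turn"),
                              reuse_agent = FALSE) {
  protocol <- match.arg(protocol)
  stopifnot(n >= 1)
  plan <- protocol_runs(protocol)
  runs <- list()
  timing <- list()
  cached <- NULL
  for (k in seq_len(n)) {
    rep_seed <- derive_seed(config$seed, 10000 + k)
    pass <- TRUE
    conv <- TRUE
    for (s in plan) {
      cfg <- config
      cfg$group <- s$group
      cfg$seed <- if (reuse_agent) derive_seed(config$seed, 10001) else
        rep_seed
      key <- paste(s$group, cfg$seed)
      agent <- if (reuse_agent && !is.null(cached[[key]])) {
        cached[[key]]
      } else {
        a <- train_agent(cfg)
        if (reuse_agent) cached[[key]] <- a
        a
      }
      conv <- conv && agent_converged(agent)
      for (kind in s$kinds) {
        res <- run_test(agent, gen_test_scenario(kind))
        pass <- pass && res$pass
        tm <- measure_timing(res$trace)$by_condition
        tm$rep <- k
        tm$kind <- kind
        timing[[length(timing) + 1L]] <- tm
        reg <- measure_timing(res$trace)$by_region
        reg$rep <- k
        reg$kind <- kind
        attr(timing[[length(timing)]], "by_region") <- reg
      }
    }
    runs[[k]] <- data.frame(rep = k, seed = rep_seed, pass = pass && conv,
                            task_pass = pass, converged = conv)
  }
  runs <- do.call(rbind, runs)
  timing_df <- do.call(rbind, timing)
  regions_df <- do.call(rbind, lapply(timing, attr, "by_region"))
  summ <- stats::aggregate(duration ~ condition + region + role,
                           data = regions_df,
                           FUN = function(x) c(mean = mean(x), sd = sd(x)))
  structure(list(protocol = protocol, n = n,
                 pass_count = sum(runs$pass),
                 convergence_failures = sum(!runs$converged),
                 runs = runs, timing = timing_df,
                 timing_by_region = regions_df, timing_summary = summ),
            class = "tom_repeat")
}

#' @export
print.tom_repeat <- function(x, ...) {
  cat(sprintf("<tom_repeat %s  passed %d/%d (convergence failures: %d)>\n",
              x$protocol, x$pass_count, x$n, x$convergence_failures))
  invisible(x)
}

#' Maturation sweep over hidden-layer size and frontal-gate flags
#'
#' Retrains an opaque-group agent for every cell of the grid and runs the
#' opaque-blindfold false-belief scenario. Reducing the perception network's
#' hidden layer models an immature region (less calculation capability);
#' zeroing a gate flag models an immature frontal connection. Each cell
#' records whether training itself succeeded (self visual-access learning),
#' whether the other agent's visual access was inferred correctly, the two
#' answers, and the failure mode.
#'
#' @param config A [tom_config()]; `group` is forced to `"opaque"`.
#' @param hidden_sizes Perception hidden-layer sizes to test.
#' @param flag_grid Data frame with columns `ifg_tpj`, `ifg_vmpfc`; defaults
#'   to all four combinations.
#' @return A data frame with one row per (hidden size, flag pair) cell:
#'   `hidden`, `ifg_tpj`, `ifg_vmpfc`, `self_learning_ok` (full
#'   training-set mastery), `training_accuracy`, `blindfold_accuracy`
#'   (accuracy on the blindfold scenes alone — what "learning the
#'   blindfold's visual access" requires), `other_access_ok`,
#'   `answer_other`, `answer_self`, `self_correct`, `pass`, `mode`
#'   (`"pass"`, `"wrong-other-visual-access"`, `"ambiguous-self-favored"`
#'   or `"wrong-other-belief"`).
#' @export
maturation_sweep <- function(config = tom_config(), hidden_sizes = 3,
                             flag_grid = NULL) {
  if (is.null(flag_grid)) {
    flag_grid <- expand.grid(ifg_tpj = c(0, 1), ifg_vmpfc = c(0, 1))
  }
  scenario <- gen_test_scenario("blindfold-opaque")
  gt <- scenario$ground_truth
  rows <- list()
  for (h in hidden_sizes) {
    for (i in seq_len(nrow(flag_grid))) {
      cfg <- config
      cfg$group <- "opaque"
      cfg$hidden_precuneus <- h
      cfg$ifg_tpj <- flag_grid$ifg_tpj[i]
      cfg$ifg_vmpfc <- flag_grid$ifg_vmpfc[i]
      agent <- train_agent(cfg)
      res <- run_test(agent, scenario)
      # the actor cannot see the move: every frame with the blindfold worn
      # must be inferred "unseen" from the other perspective
      worn <- vapply(scenario$frames,
                     function(f) identical(f$blindfold$worn_by, "other"),
                     logical(1))
      other_ok <- all(res$details$other$outcomes[worn] == "unseen")
      # how much of the visual-access experience the perception network
      # mastered, overall and on the blindfold scenes specifically
      va <- gen_visual_access_trials(cfg$group, cfg$n_visual_access,
                                     seed = derive_seed(cfg$seed, 1),
                                     include_desk = cfg$include_desk)
      s <- precuneus_samples(va, cfg$zeta)
      act <- vpsnn_batch_activity(agent$precuneus, s)
      correct <- vapply(seq_along(s), function(k) {
        identical(decode_output(act[k, ], agent$precuneus$labels),
                  agent$precuneus$labels[s[[k]]$target])
      }, logical(1))
      scene_of <- rep(vapply(va, `[[`, "", "scene"), each = 2)
      blindfold_acc <- mean(correct[scene_of == "blindfold"])
      self_ok <- identical(res$answers[["about-self"]],
                           gt$self)
      mode <- if (res$pass) {
        "pass"
      } else if (!other_ok) {
        "wrong-other-visual-access"
      } else if (isTRUE(res$details$sel_other$gating$ambiguous)) {
        "ambiguous-self-favored"
      } else {
        "wrong-other-belief"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        hidden = h, ifg_tpj = flag_grid$ifg_tpj[i],
        ifg_vmpfc = flag_grid$ifg_vmpfc[i],
        self_learning_ok = agent_converged(agent),
        training_accuracy = agent$precuneus$fit_accuracy,
        blindfold_accuracy = blindfold_acc,
        other_access_ok = other_ok,
        answer_other = res$answers[["about-other"]],
        answer_self = res$answers[["about-self"]],
        self_correct = self_ok, pass = res$pass, mode = mode,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
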