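test_that("training order is enforced: perception before belief", {
  expect_error(train_agent(tom_config(), order = c("acc", "precuneus")),
               "protocol violation")
})

test_that("agents are reproducible from config and seed alone", {
  a1 <- cached_agent("opaque", 1)
  a2 <- train_agent(tom_config(group = "opaque", seed = 1))
  expect_identical(a1$precuneus$w1, a2$precuneus$w1)
  expect_identical(a1$precuneus$w2, a2$precuneus$w2)
  expect_identical(a1$acc$w1, a2$acc$w1)
  expect_identical(a1$acc$w2, a2$acc$w2)
})

test_that("both networks converge under the default configuration", {
  ag <- cached_agent("opaque", 1)
  expect_true(ag$precuneus$converged)
  expect_true(ag$acc$converged)
  expect_true(agent_converged(ag))
  expect_equal(ag$precuneus$fit_accuracy, 1)
})

test_that("the trained behaviour table of the three query scenes holds", {
  # the three visual-access situations: blindfold interposed, robot turned,
  # object moved — inferred per group from its own experience
  labels <- c("left", "right", "unseen")
  frames <- function(f2) {
    list(scene_event("self", "ball", "left",
                     boxes = list(yellow = list(location = "left"),
                                  green = list(location = "right"))), f2)
  }
  probe <- function(ag, f2) {
    wm <- working_memory(ag$config$zeta, 24)
    fr <- frames(f2)
    for (f in fr) {
      r <- precuneus_infer(encode_sts(f)$currents, wm, ag$precuneus)
      wm <- r$wm
    }
    r$outcome
  }
  scen <- list(yellow = list(location = "left"),
               green = list(location = "right"))
  worn_opaque <- scene_event("self", NA, "absent", boxes = scen,
                             blindfold = list(present = TRUE, worn = TRUE))
  worn_transparent <- scene_event("self", "ball", "left", boxes = scen,
                                  blindfold = list(present = TRUE,
                                                   worn = TRUE))
  turned <- scene_event("self", NA, "absent", boxes = scen, turn = "turned")
  moved <- scene_event("self", "ball", "right", boxes = scen)
  opaque <- cached_agent("opaque", 1)
  transparent <- cached_agent("transparent", 1)
  # the opaque blindfold blocks sight; the trick blindfold does not
  expect_identical(probe(opaque, worn_opaque), "unseen")
  expect_identical(probe(transparent, worn_transparent), "left")
  # turning away blocks sight for both groups
  expect_identical(probe(opaque, turned), "unseen")
  # a moved object is perceived at its new side
  expect_identical(probe(opaque, moved), "right")
  expect_identical(probe(transparent, moved), "right")
})

test_that("working memory off makes perception depend on the current frame only", {
  ag <- cached_agent("opaque", 1)
  ev_a <- scene_event("self", "ball", "left")
  ev_b <- scene_event("self", "duck", "right")
  ev_probe <- scene_event("self", "cup", "right")
  outcome_after <- function(history) {
    wm <- working_memory(0, 24)
    for (ev in history) {
      r <- precuneus_infer(encode_sts(ev)$currents, wm, ag$precuneus)
      wm <- r$wm
    }
    precuneus_infer(encode_sts(ev_probe)$currents, wm, ag$precuneus)$outcome
  }
  expect_identical(outcome_after(list(ev_a, ev_b)),
                   outcome_after(list(ev_b, ev_a)))
  expect_identical(outcome_after(list(ev_a)), outcome_after(list(ev_b)))
})

test_that("belief updating follows perception and persists through occlusion", {
  ag <- cached_agent("opaque", 1)
  wm <- working_memory(ag$config$zeta, 2)
  seq_out <- c("left", "unseen", "unseen")
  beliefs <- character(0)
  for (o in seq_out) {
    r <- acc_infer(o, wm, ag$acc)
    wm <- r$wm
    beliefs <- c(beliefs, r$belief)
  }
  # hand-simulated truth table: visible fixes the belief, unseen keeps it
  expect_identical(beliefs, c("left", "left", "left"))
  r <- acc_infer("right", wm, ag$acc)
  expect_identical(r$belief, "right")
})

test_that("the full false-belief run produces the expected answers and trace", {
  ag <- cached_agent("opaque", 1)
  res <- run_test(ag, gen_test_scenario("blindfold-opaque"))
  expect_true(res$pass)
  expect_identical(res$gestures$`about-other`$gesture, "point-left")
  expect_identical(res$gestures$`about-self`$gesture, "point-right")
  # regions activate serially along the pathway
  tr <- res$trace
  for (q in unique(tr$question)) {
    seg <- tr[tr$question == q, ]
    expect_true(all(diff(seg$onset) >= 0))
    expect_equal(seg$onset[-1], seg$offset[-nrow(seg)])
  }
  # the frontal gate engaged for both inhibitions in the false-belief case
  expect_true(any(tr$role == "perspective-inhibition"))
  expect_true(any(tr$role == "belief-inhibition"))
})

test_that("a true-belief turn scenario never engages the perspective gate", {
  ag <- cached_agent("turn", 1)
  res <- run_test(ag, gen_test_scenario("turn-true"))
  expect_true(res$pass)
  expect_false(res$details$other$ifg_activated)
  expect_false(any(res$trace$role == "perspective-inhibition"))
})

test_that("timing summaries reject malformed traces", {
  expect_error(measure_timing(data.frame(x = 1)), "malformed")
  bad <- data.frame(condition = "a", region = "TPJ", role = "routing",
                    onset = 0, offset = 1, duration = -1)
  expect_error(measure_timing(bad), "malformed")
})

test_that("reasoning latencies order as the four belief conditions demand", {
  ag_o <- cached_agent("opaque", 1)
  ag_t <- cached_agent("transparent", 1)
  ag_u <- cached_agent("turn", 1)
  t_of <- function(res) {
    m <- measure_timing(res$trace)$by_condition
    setNames(m$reasoning_ms, m$condition)
  }
  fb <- t_of(run_test(ag_o, gen_test_scenario("blindfold-opaque")))
  tb <- t_of(run_test(ag_t, gen_test_scenario("blindfold-transparent")))
  tf <- t_of(run_test(ag_u, gen_test_scenario("turn-false")))
  tt <- t_of(run_test(ag_u, gen_test_scenario("turn-true")))
  # within the blindfold protocol
  expect_lt(tb[["self-congruent"]], fb[["self-incongruent"]])
  expect_lt(fb[["self-incongruent"]], tb[["other-congruent"]])
  expect_lt(tb[["other-congruent"]], fb[["other-incongruent"]])
  # false-belief reasoning takes longer than true-belief reasoning
  expect_lt(tb[["other-congruent"]], fb[["other-incongruent"]])
  expect_lt(tt[["other-congruent"]], tf[["other-incongruent"]])
  # the turn-around true-belief case skips the perspective gate entirely
  expect_lt(tt[["other-congruent"]], tb[["other-congruent"]])
  # self-belief timing is similar across conditions (< 10% relative)
  expect_lt(abs(fb[["self-incongruent"]] - tb[["self-congruent"]]) /
              tb[["self-congruent"]], 0.1)
})
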