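circ <- inhibition_circuit(n_channels = 4)

test_that("conflict detection: identical patterns silence the result neurons", {
  a <- c(1, 0, 1, 0)
  cd <- conflict_detect(a, a, circ)
  expect_false(cd$inr_fired)
  expect_equal(cd$residual, rep(0, 4))
  # conflicting patterns fire
  cd2 <- conflict_detect(c(1, 0, 1, 0), c(0, 1, 1, 0), circ)
  expect_true(cd2$inr_fired)
  expect_equal(cd2$residual, c(1, 0, 0, 0))
  # nothing to inhibit: all-zero self stays silent
  expect_false(conflict_detect(rep(0, 4), c(1, 1, 0, 1), circ)$inr_fired)
  expect_error(conflict_detect(c(1, 0), c(1, 0, 0), circ), "channel count")
})

test_that("other-first gating with a mature gate emits other then self", {
  s <- c(1, 0, 1, 0)
  o <- c(0, 1, 1, 0)
  g <- gate_other_first(s, o, circ)
  expect_true(g$inr_fired)
  expect_true(g$ifg_activated)
  expect_equal(g$first$pattern, o)
  expect_identical(g$first$source, "pSTS")
  expect_true(g$first$valid)
  expect_equal(g$second$pattern, s)
  expect_gt(g$latency_ms, circ$tpj_other_ms)
})

test_that("other-first gating with an immature gate corrupts the first output", {
  s <- c(1, 0, 1, 0)
  o <- c(0, 1, 1, 0)
  ci <- inhibition_circuit(n_channels = 4, ifg_tpj = 0)
  g <- gate_other_first(s, o, ci)
  expect_true(g$inr_fired)
  expect_false(g$ifg_activated)
  expect_false(g$first$valid)
  # the superposition equals neither stored pattern
  expect_false(identical(g$first$pattern, s))
  expect_false(identical(g$first$pattern, o))
  expect_equal(g$second$pattern, s)
  expect_equal(g$latency_ms, ci$tpj_other_ms)
})

test_that("no conflict means no frontal engagement and no added latency", {
  a <- c(1, 0, 1, 0)
  g <- gate_other_first(a, a, circ)
  expect_false(g$ifg_activated)
  expect_equal(g$latency_ms, circ$tpj_other_ms)
})

test_that("self-first gating always suppresses the other pattern", {
  set.seed(41)
  for (i in 1:50) {
    s <- sample(0:1, 4, replace = TRUE)
    o <- sample(0:1, 4, replace = TRUE) * 1.5  # max stimulus current
    g <- gate_self_first(s, o, circ)
    expect_equal(g$first$pattern, s)
    expect_equal(g$suppressed_other, rep(0, 4))
    expect_false(g$ifg_activated)
  }
  # suppression margin: big current is 10x the maximum stimulus current
  expect_gte(circ$big_current, 10 * 1)
})

test_that("belief gating follows the maturation truth table", {
  mk <- function(vm, dm) {
    b <- belief_store()
    b <- store_belief(b, vm, "self", "IPL")
    store_belief(b, dm, "other", "pSTS")
  }
  mature <- inhibition_circuit(ifg_vmpfc = 1)
  immature <- inhibition_circuit(ifg_vmpfc = 0)
  # conflicting beliefs, mature gate: other-attributed belief exported
  g <- gate_belief(mk("right", "left"), mature)
  expect_identical(g$belief, "left")
  expect_true(g$ifg_activated)
  # conflicting beliefs, immature gate: ambiguous, resolved toward self
  g2 <- gate_belief(mk("right", "left"), immature)
  expect_identical(g2$belief, "right")
  expect_true(g2$ambiguous)
  expect_false(g2$ifg_activated)
  # identical beliefs: straight export, result neurons silent
  g3 <- gate_belief(mk("right", "right"), mature)
  expect_identical(g3$belief, "right")
  expect_false(g3$inr_fired)
  expect_false(g3$ifg_activated)
  # empty stores
  expect_identical(gate_belief(belief_store(), mature)$belief, "no-belief")
})

test_that("frontal engagement adds strictly positive latency", {
  mk <- function(vm, dm) {
    b <- belief_store()
    b <- store_belief(b, vm, "self", "IPL")
    store_belief(b, dm, "other", "pSTS")
  }
  with_ifg <- gate_belief(mk("right", "left"), circ)
  without <- gate_belief(mk("right", "right"), circ)
  expect_gt(with_ifg$latency_ms, without$latency_ms)
  s <- c(1, 0, 1, 0)
  o <- c(0, 1, 1, 0)
  expect_gt(gate_other_first(s, o, circ)$latency_ms,
            gate_other_first(o, o, circ)$latency_ms)
})

test_that("question-dependent belief selection inhibits the right store", {
  b <- belief_store()
  b <- store_belief(b, "right", "self", "IPL")
  b <- store_belief(b, "left", "other", "pSTS")
  expect_identical(mpfc_select(b, "about-other", circ)$belief, "left")
  expect_identical(mpfc_select(b, "about-self", circ)$belief, "right")
  # self path never needs the frontal gate, whatever the maturation
  ci <- inhibition_circuit(ifg_tpj = 0, ifg_vmpfc = 0)
  expect_identical(mpfc_select(b, "about-self", ci)$belief, "right")
})

test_that("pointing gestures follow the selected belief", {
  expect_identical(motor_respond("left")$gesture, "point-left")
  expect_identical(motor_respond("right")$gesture, "point-right")
  expect_identical(motor_respond("no-belief")$gesture, "none")
})
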