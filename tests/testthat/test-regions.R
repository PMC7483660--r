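test_that("percept encoding round-trips over the finite event space", {
  reg <- object_registry()
  objects <- c(list(list(id = NA, loc = "absent")),
               unlist(lapply(reg[c(1, 5, 12)], function(o) {
                 list(list(id = o, loc = "left"), list(id = o, loc = "right"))
               }), recursive = FALSE))
  box_states <- list(list(), list(yellow = list(location = "left",
                                                occupied = TRUE)),
                     list(green = list(location = "right", occupied = TRUE)),
                     list(yellow = list(location = "right", occupied = TRUE),
                          green = list(location = "left", occupied = TRUE)))
  blindfolds <- list(list(present = FALSE, worn = FALSE),
                     list(present = TRUE, worn = FALSE),
                     list(present = TRUE, worn = TRUE))
  for (agent in c("self", "other")) {
    for (ob in objects) {
      for (bx in box_states) {
        for (bf in blindfolds) {
          for (tn in c("facing", "turned")) {
            ev <- scene_event(agent, ob$id, ob$loc, boxes = bx,
                              blindfold = bf, turn = tn)
            enc <- encode_sts(ev)
            expect_true(all(enc$currents %in% c(0, 1)))
            # exactly one neuron active in each paired state code
            expect_equal(enc$currents[["bf_worn"]] +
                           enc$currents[["bf_not_worn"]], 1)
            expect_equal(enc$currents[["bf_present"]] +
                           enc$currents[["bf_absent"]], 1)
            expect_equal(enc$currents[["turn_facing"]] +
                           enc$currents[["turn_turned"]], 1)
            dec <- decode_percept(enc)
            expect_identical(dec$agent_id, ev$agent_id)
            expect_identical(dec$object_location, ev$object_location)
            if (ev$object_location != "absent") {
              expect_identical(dec$object_id, ev$object_id)
            }
            expect_identical(dec$blindfold, ev$blindfold)
            expect_identical(dec$turn, ev$turn)
            expect_identical(sort(names(dec$boxes)), sort(names(bx)))
          }
        }
      }
    }
  }
})

test_that("encoding rejects unknown objects and impossible blindfold states", {
  expect_error(scene_event("self", "unicorn", "left"), "unknown object")
  expect_error(scene_event("self", NA, "absent",
                           blindfold = list(present = FALSE, worn = TRUE)),
               "cannot be worn")
})

test_that("perspective routing conserves and separates percepts", {
  set.seed(51)
  store <- perspective_store()
  n_self <- 0
  for (i in 1:30) {
    agent <- sample(c("self", "other"), 1)
    if (agent == "self") n_self <- n_self + 1
    ev <- scene_event(agent, "ball", sample(c("left", "right"), 1))
    store <- tpj_route(encode_sts(ev), store)
  }
  expect_equal(length(store$ipl), n_self)
  expect_equal(length(store$ipl) + length(store$psts), 30)
  # stored patterns are identity-stripped 24-channel stimuli
  expect_equal(length(store$ipl[[1]]), length(percept_channels()))
  bad <- encode_sts(scene_event("self", "ball", "left"))
  bad$id <- c(self = 1, other = 1)
  expect_error(tpj_route(bad, perspective_store()), "ambiguous identity")
})

test_that("working memory decays geometrically and can be disabled", {
  wm <- working_memory(0.5, 3)
  expect_true(wm$empty)
  expect_equal(wm$value, c(0, 0, 0))
  expect_error(working_memory(1.2, 3))
})

test_that("belief updating requires a trained network and handles no-belief", {
  net <- vpsnn_network(3, 3, 2, labels = c("left", "right"))
  wm <- working_memory(0.5, 2)
  expect_error(acc_infer("left", wm, net), "not been trained")
  net$trained <- TRUE
  net$converged <- TRUE
  # first frame unseen with empty memory cannot yield a belief
  r <- acc_infer("unseen", wm, net)
  expect_identical(r$belief, "no-belief")
})

test_that("untrained perception networks are rejected", {
  net <- vpsnn_network(24, 3, 3, labels = c("left", "right", "unseen"))
  wm <- working_memory(0.5, 24)
  expect_error(precuneus_infer(rep(0, 24), wm, net), "not been trained")
  net$trained <- TRUE
  expect_error(precuneus_infer(rep(0, 10), wm, net), "dimension")
})
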