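test_that("visual-access trials have two frames and group-true teachers", {
  for (grp in c("opaque", "transparent", "turn")) {
    trials <- gen_visual_access_trials(grp, n = 60, seed = 2)
    expect_length(trials, 60)
    for (tr in trials) {
      expect_length(tr$frames, 2)
      expect_length(tr$targets, 2)
      expect_true(all(tr$targets %in% c("left", "right", "unseen")))
      if (tr$scene == "blindfold") {
        expect_true(grp != "turn")
        expect_true(tr$frames[[2]]$blindfold$worn)
        if (grp == "opaque") {
          # the opaque blindfold blocks the first-person view
          expect_identical(tr$frames[[2]]$object_location, "absent")
          expect_identical(tr$targets[2], "unseen")
        } else {
          # the trick blindfold leaves the object visible
          expect_identical(tr$frames[[2]]$object_location, tr$targets[2])
        }
      }
      if (tr$scene == "turn") {
        expect_identical(tr$frames[[2]]$turn, "turned")
        expect_identical(tr$targets[2], "unseen")
      }
      if (tr$scene == "moved") {
        expect_false(identical(tr$frames[[2]]$object_location,
                               tr$frames[[1]]$object_location))
        expect_identical(tr$targets[2], tr$frames[[2]]$object_location)
      }
    }
    # the turn regime never contains a blindfold
    if (grp == "turn") {
      expect_false(any(vapply(trials, function(tr) {
        tr$frames[[2]]$blindfold$present
      }, logical(1))))
    }
  }
})

test_that("trial generation is byte-identical under a fixed seed", {
  a <- gen_visual_access_trials("opaque", 40, seed = 9)
  b <- gen_visual_access_trials("opaque", 40, seed = 9)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  expect_false(identical(a, gen_visual_access_trials("opaque", 40, seed = 10)))
  o1 <- gen_object_permanence_trials(20, seed = 3)
  o2 <- gen_object_permanence_trials(20, seed = 3)
  expect_identical(serialize(o1, NULL), serialize(o2, NULL))
})

test_that("object-permanence trials hide, then reveal or move the object", {
  trials <- gen_object_permanence_trials(25, seed = 4)
  expect_length(trials, 25)
  for (tr in trials) {
    expect_length(tr$frames, 3)
    side <- tr$frames[[1]]$object_location
    expect_true(side %in% c("left", "right"))
    # hidden frame: object absent, one box occupied at the same side
    expect_identical(tr$frames[[2]]$object_location, "absent")
    occ <- tr$frames[[2]]$boxes
    expect_length(occ, 1)
    expect_identical(occ[[1]]$location, side)
    end_side <- tr$frames[[3]]$object_location
    if (tr$scene == "hide-reveal") {
      expect_identical(end_side, side)
    } else {
      expect_identical(end_side, setdiff(c("left", "right"), side))
    }
    # the teacher always follows the true location
    expect_identical(unname(tr$targets), c(side, side, end_side))
  }
  # both experiences occur
  expect_setequal(unique(vapply(trials, `[[`, "", "scene")),
                  c("hide-reveal", "hide-move"))
})

test_that("generated trials stay within the encodable event space", {
  trials <- c(gen_visual_access_trials("opaque", 30, seed = 5),
              gen_object_permanence_trials(10, seed = 5))
  for (tr in trials) {
    for (f in tr$frames) {
      dec <- decode_percept(encode_sts(f))
      expect_identical(dec$object_location, f$object_location)
      expect_identical(dec$turn, f$turn)
      expect_identical(dec$blindfold, f$blindfold)
    }
  }
})

test_that("the opaque and transparent test streams are frame-identical", {
  a <- gen_test_scenario("blindfold-opaque")
  b <- gen_test_scenario("blindfold-transparent")
  expect_identical(a$frames, b$frames)
  # only the expected answers differ
  expect_identical(a$ground_truth$self, b$ground_truth$self)
  expect_false(identical(a$ground_truth$other, b$ground_truth$other))
})

test_that("test scenarios carry the protocol ground truths", {
  expect_identical(gen_test_scenario("blindfold-opaque")$ground_truth,
                   list(other = "left", self = "right"))
  expect_identical(gen_test_scenario("blindfold-transparent")$ground_truth,
                   list(other = "right", self = "right"))
  expect_identical(gen_test_scenario("turn-false")$ground_truth,
                   list(other = "left", self = "right"))
  expect_identical(gen_test_scenario("turn-true")$ground_truth,
                   list(other = "right", self = "right"))
  expect_identical(
    gen_test_scenario("blindfold-control-position")$ground_truth,
    list(other = "right", self = "right"))
  # the control blindfold is never worn
  ctl <- gen_test_scenario("blindfold-control-position")
  expect_false(any(vapply(ctl$frames, function(f) {
    !identical(f$blindfold$worn_by, "none")
  }, logical(1))))
})

test_that("percept derivation attributes states to the right perspective", {
  sc <- gen_test_scenario("blindfold-opaque")
  pp <- scenario_percepts(sc)
  # frame 3: actor blindfolded, participant not; object visible right
  expect_false(pp[[3]]$self$blindfold$worn)
  expect_true(pp[[3]]$self$blindfold$present)
  expect_true(pp[[3]]$other$blindfold$worn)
  expect_identical(pp[[3]]$self$object_location, "right")
  expect_identical(pp[[3]]$other$object_location, "right")
  tn <- scenario_percepts(gen_test_scenario("turn-false"))
  expect_identical(tn[[3]]$other$turn, "turned")
  expect_identical(tn[[3]]$self$turn, "facing")
})

test_that("scenarios validate and round-trip through JSON", {
  for (kind in c("blindfold-opaque", "turn-true",
                 "blindfold-control-position")) {
    sc <- gen_test_scenario(kind)
    expect_true(validate_scenario(sc))
    path <- tempfile(fileext = ".json")
    write_scenario(sc, path)
    back <- read_scenario(path)
    expect_identical(back$kind, sc$kind)
    expect_identical(back$ground_truth, sc$ground_truth)
    expect_equal(length(back$frames), length(sc$frames))
    # derived percepts agree frame by frame
    p1 <- scenario_percepts(sc)
    p2 <- scenario_percepts(back)
    for (k in seq_along(p1)) {
      expect_equal(encode_sts(p1[[k]]$other)$currents,
                   encode_sts(p2[[k]]$other)$currents)
    }
    unlink(path)
  }
  bad <- gen_test_scenario("blindfold-opaque")
  bad$schema_version <- "0.0"
  expect_error(validate_scenario(bad), "schema version")
})
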