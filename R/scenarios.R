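scenario_schema_version <- "1.0"

va_scene_types <- function(group) {
  switch(group,
         opaque = c("blindfold", "turn", "moved", "occluded", "revealed"),
         transparent = c("blindfold", "turn", "moved", "occluded",
                         "revealed"),
         turn = c("turn", "moved", "occluded", "revealed"),
         stop("unknown training group: ", group, call. = FALSE))
}

#' Generate visual-access training trials
#'
#' First-person training regime for the perception network. Each trial has
#' two frames: an object is placed at a random side, then one of the query
#' scenes follows — the blindfold is put on, the robot turns around, the
#' object is moved to the other side, the object is hidden in a box, or a
#' hidden object is revealed. The teacher target is the true visibility
#' outcome for the group: a worn opaque blindfold or a turned head or an
#' occluding box means `"unseen"`, a worn transparent blindfold leaves the
#' object visible, and a moved object is perceived at its new side.
#'
#' Scene types, sides and box identities are sampled in balanced
#' (stratified) proportions so that no rare combination is left untrained.
#' In the blindfold groups the blindfold additionally lies visibly on the
#' desk in half of the frames it is not worn in, so its mere presence in
#' the scene carries no information about visual access — the experience
#' the blindfold-position control probes at test time.
#'
#' The two blindfold groups experience identical scene structure; only
#' whether the worn blindfold blocks the first-person view differs, which is
#' exactly the self-experience difference the protocol manipulates.
#'
#' @param group `"opaque"`, `"transparent"` or `"turn"` (no blindfold in the
#'   turn regime).
#' @param n Number of trials.
#' @param seed Random seed.
#' @param include_desk Sample the blindfold-on-desk experience into non-worn
#'   frames (blindfold groups only).
#' @param holdout_test_object Exclude `"ladybird"` from training objects.
#' @return A list of trials, each `list(frames, targets, group, scene)` with
#'   `targets` the per-frame teacher labels.
#' @export
gen_visual_access_trials <- function(group = "opaque", n = 160, seed = 1L,
                                     include_desk = TRUE,
                                     holdout_test_object = FALSE) {
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  types <- va_scene_types(group)
  objects <- object_registry()
  if (holdout_test_object) objects <- setdiff(objects, "ladybird")
  # balanced strata: scene types first, then within each scene type the
  # joint (side x box identity x occlusion onset x start state) cells, so
  # that e.g. a fast blindfold onset over a right-side object is guaranteed
  # to be experienced, not left to a run of coin flips
  scenes <- sample(rep(types, length.out = n))
  sides <- character(n)
  boxes <- character(n)
  fast <- logical(n)
  boxed <- logical(n)
  objs <- character(n)
  for (ty in types) {
    idx <- which(scenes == ty)
    cells <- expand.grid(side = c("left", "right"),
                         box = c("yellow", "green"),
                         fast = c(TRUE, FALSE),
                         boxed = c(TRUE, FALSE))
    pick <- cells[sample(rep(seq_len(nrow(cells)),
                             length.out = length(idx))), ]
    sides[idx] <- as.character(pick$side)
    boxes[idx] <- as.character(pick$box)
    fast[idx] <- pick$fast
    boxed[idx] <- pick$boxed
    # objects cycle within each scene type so no identity channel becomes
    # correlated with a particular visibility outcome
    objs[idx] <- sample(rep(objects, length.out = length(idx)))
  }
  desk_ok <- include_desk && group != "turn"
  desk_bf <- function() {
    # blindfold visible on the desk, not worn, in half the eligible frames
    list(present = desk_ok && runif(1) < 0.5, worn = FALSE)
  }
  trials <- vector("list", n)
  for (i in seq_len(n)) {
    obj <- objs[i]
    side <- sides[i]
    scene <- scenes[i]
    other_side <- setdiff(c("left", "right"), side)
    # blindfold and turn queries also happen while the object sits in a box
    # (hidden before the query), so every occlusion cue is experienced on
    # top of remembered box scenery too
    boxed_start <- scene == "revealed" ||
      (scene %in% c("blindfold", "turn") && boxed[i])
    # box scenery persists across the trial's frames (boxes stay on the
    # desk whether or not anything is inside); occlusion scenes need a box
    # at the object's side, other layouts vary freely
    scenery <- list()
    needs_box <- boxed_start || scene == "occluded"
    if (needs_box) {
      scenery[[boxes[i]]] <- list(location = side,
                                  occupied = boxed_start ||
                                    scene == "occluded")
      if (runif(1) < 0.5) {
        scenery[[setdiff(c("yellow", "green"), boxes[i])]] <-
          list(location = other_side, occupied = FALSE)
      }
    } else {
      k <- sample(0:2, 1)
      if (k >= 1) {
        scenery[[boxes[i]]] <- list(location = sample(c(side, other_side), 1),
                                    occupied = FALSE)
      }
      if (k == 2) {
        first_loc <- scenery[[boxes[i]]]$location
        scenery[[setdiff(c("yellow", "green"), boxes[i])]] <-
          list(location = setdiff(c("left", "right"), first_loc),
               occupied = FALSE)
      }
    }
    f1 <- if (boxed_start) {
      scene_event("self", NA, "absent", boxes = scenery,
                  blindfold = desk_bf(), timestamp = 1L)
    } else {
      scene_event("self", obj, side, boxes = scenery,
                  blindfold = desk_bf(), timestamp = 1L)
    }
    # a reappearing object is always perceived at the other side (as in the
    # unexpected-transfer streams); a same-side reveal is indistinguishable
    # from a continuing occlusion and is not part of any evaluated stream
    side2 <- other_side
    f2 <- switch(scene,
      # an opaque blindfold covers most of the visual field: the (small)
      # object disappears from the percept while the large box scenery is
      # still caught peripherally
      blindfold = scene_event(
        "self",
        object_id = if (group == "transparent") obj else NA,
        object_location = if (group == "transparent") {
          if (boxed_start) side2 else side
        } else "absent",
        boxes = scenery,
        blindfold = list(present = TRUE, worn = TRUE), timestamp = 2L),
      # a twisted head, like a worn blindfold, loses the small frontal
      # object while the large box scenery is still caught peripherally
      turn = scene_event("self", NA, "absent", boxes = scenery,
                         turn = "turned", blindfold = desk_bf(),
                         timestamp = 2L),
      moved = scene_event("self", obj, other_side, boxes = scenery,
                          blindfold = desk_bf(), timestamp = 2L),
      occluded = scene_event("self", NA, "absent", boxes = scenery,
                             blindfold = desk_bf(), timestamp = 2L),
      revealed = scene_event("self", obj, side2, boxes = scenery,
                             blindfold = desk_bf(), timestamp = 2L))
    target2 <- switch(scene,
                      blindfold = if (group == "transparent")
                                    f2$object_location else "unseen",
                      turn = "unseen",
                      moved = other_side,
                      occluded = "unseen",
                      revealed = f2$object_location)
    target1 <- if (boxed_start) "unseen" else side
    # occlusion onset speed: a blindfold can land (or the head turn) while
    # the first frame's percept is still at full strength (delay 0 windows)
    # or after a full window's decay (delay 1); other transitions always
    # take a full window
    delay2 <- if (scene %in% c("blindfold", "turn") && fast[i]) 0L else 1L
    trials[[i]] <- list(frames = list(f1, f2),
                        targets = c(target1, target2),
                        delays = c(NA_integer_, delay2),
                        group = group, scene = scene)
  }
  trials
}

#' Generate object-permanence training trials
#'
#' Three frames per trial: the object is placed at a random side, hidden in
#' a box at that side, then perceived again — either revealed in place when
#' the box is removed (`"hide-reveal"`) or watched being moved to the other
#' side (`"hide-move"`, the repeated-hiding experience of the later
#' object-permanence stages). The teacher target is the object's true
#' location per frame — the robot always perceives the location at the end
#' of a trial, so it learns both that objects stay where last located while
#' out of view and that a currently visible object overrides the remembered
#' location.
#'
#' @param n Number of trials.
#' @param seed Random seed.
#' @return A list of trials as in [gen_visual_access_trials()].
#' @export
gen_object_permanence_trials <- function(n = 50, seed = 1L) {
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  objects <- object_registry()
  trials <- vector("list", n)
  for (i in seq_len(n)) {
    obj <- sample(objects, 1)
    side <- sample(c("left", "right"), 1)
    other_side <- setdiff(c("left", "right"), side)
    box <- sample(c("yellow", "green"), 1)
    scene <- sample(c("hide-reveal", "hide-move"), 1)
    end_side <- if (scene == "hide-move") other_side else side
    f1 <- scene_event("self", obj, side, timestamp = 1L)
    f2 <- scene_event("self", NA, "absent",
                      boxes = setNames(list(list(location = side,
                                                 occupied = TRUE)), box),
                      timestamp = 2L)
    f3 <- scene_event("self", obj, end_side, timestamp = 3L)
    trials[[i]] <- list(frames = list(f1, f2, f3),
                        targets = c(side, side, end_side),
                        group = "permanence", scene = scene)
  }
  trials
}

test_scenario_kinds <- function() {
  c("blindfold-opaque", "blindfold-transparent", "turn-false", "turn-true",
    "blindfold-control-position")
}

#' Generate a test scenario
#'
#' Builds the unexpected-transfer event stream for the five test kinds. In
#' the blindfold kinds the object is placed on the left, hidden in the
#' yellow box, then moved to the right and hidden in the green box while the
#' actor wears the blindfold, which is finally removed; the opaque and
#' transparent streams are frame-by-frame identical — only the agents'
#' training histories differ. In the turn kinds the move happens while the
#' actor is turned around (false belief) or watching (true belief). The
#' control kind leaves the blindfold on the desk so the actor's view is
#' never blocked.
#'
#' Ground truth: false-belief kinds expect the other-attributed answer at
#' the original location (left, yellow box) and the self answer at the final
#' location (right, green box); true-belief kinds and the control expect
#' both at the final location.
#'
#' @param kind One of `"blindfold-opaque"`, `"blindfold-transparent"`,
#'   `"turn-false"`, `"turn-true"`, `"blindfold-control-position"`.
#' @param seed Random seed (the streams are deterministic; kept for
#'   interface uniformity).
#' @return An object of class `test_scenario` with `frames` (scene-level
#'   descriptions), `questions`, `ground_truth` and the scripted actor goal.
#' @export
gen_test_scenario <- function(kind = "blindfold-opaque", seed = 1L) {
  kind <- match.arg(kind, test_scenario_kinds())
  boxes0 <- list(yellow = list(location = "left"),
                 green = list(location = "right"))
  frame <- function(t, loc, hidden_in = NA, bf_present = FALSE,
                    bf_worn_by = "none", actor_turn = "facing") {
    list(timestamp = t, object_id = "ladybird", object_location = loc,
         hidden_in = hidden_in, boxes = boxes0,
         blindfold = list(present = bf_present, worn_by = bf_worn_by),
         actor_turn = actor_turn)
  }
  frames <- if (kind %in% c("blindfold-opaque", "blindfold-transparent",
                            "blindfold-control-position")) {
    worn_by <- if (kind == "blindfold-control-position") "none" else "other"
    list(
      frame(1L, "left"),
      frame(2L, "hidden", hidden_in = "yellow"),
      frame(3L, "right", bf_present = TRUE, bf_worn_by = worn_by),
      frame(4L, "hidden", hidden_in = "green", bf_present = TRUE,
            bf_worn_by = worn_by),
      frame(5L, "hidden", hidden_in = "green"))
  } else {
    turned <- if (kind == "turn-false") "turned" else "facing"
    list(
      frame(1L, "left"),
      frame(2L, "hidden", hidden_in = "yellow"),
      frame(3L, "right", actor_turn = turned),
      frame(4L, "hidden", hidden_in = "green", actor_turn = turned),
      frame(5L, "hidden", hidden_in = "green"))
  }
  false_belief <- kind %in% c("blindfold-opaque", "turn-false")
  gt <- list(other = if (false_belief) "left" else "right", self = "right")
  structure(list(kind = kind, schema_version = scenario_schema_version,
                 frames = frames,
                 questions = c("about-other", "about-self"),
                 ground_truth = gt, actor_goal = "find-object",
                 seed = as.integer(seed)),
            class = "test_scenario")
}

#' Derive the self- and other-relevant percepts of a scenario
#'
#' The participant observes every frame; its self-relevant percept carries
#' its own (unobstructed) state, while the other-relevant percept carries
#' the actor's blindfold and turn state attributed to the same scene
#' content. An object hidden in a box is absent from both percepts. The
#' blindfold's optical kind is never encoded — the two blindfolds look
#' identical.
#'
#' @param scenario A [gen_test_scenario()] object.
#' @return A list per frame with `self` and `other` [scene_event()]s.
#' @export
scenario_percepts <- function(scenario) {
  stopifnot(inherits(scenario, "test_scenario"))
  lapply(scenario$frames, function(f) {
    visible <- !identical(f$object_location, "hidden")
    loc <- if (visible) f$object_location else "absent"
    oid <- if (visible) f$object_id else NA
    # both boxes stand on the desk in every frame; whether one holds the
    # object is not part of the percept
    boxes <- lapply(f$boxes, function(b) list(location = b$location))
    bf_present <- isTRUE(f$blindfold$present)
    list(
      self = scene_event("self", oid, loc, boxes = boxes,
                         blindfold = list(present = bf_present,
                                          worn = FALSE),
                         turn = "facing", timestamp = f$timestamp),
      other = scene_event("other", oid, loc, boxes = boxes,
                          blindfold = list(
                            present = bf_present,
                            worn = identical(f$blindfold$worn_by, "other")),
                          turn = f$actor_turn, timestamp = f$timestamp))
  })
}

#' Validate a scenario object against the schema
#'
#' @param scenario A [gen_test_scenario()] object (or one read back from
#'   JSON).
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_scenario <- function(scenario) {
  if (!identical(scenario$schema_version, scenario_schema_version)) {
    stop("unsupported scenario schema version", call. = FALSE)
  }
  stopifnot(scenario$kind %in% test_scenario_kinds(),
            length(scenario$frames) >= 1,
            all(scenario$questions %in% c("about-other", "about-self")),
            scenario$ground_truth$other %in% c("left", "right"),
            scenario$ground_truth$self %in% c("left", "right"))
  for (f in scenario$frames) {
    stopifnot(f$object_location %in% c("left", "right", "hidden"),
              f$blindfold$worn_by %in% c("none", "self", "other"),
              f$actor_turn %in% c("facing", "turned"))
    if (identical(f$object_location, "hidden")) {
      stopifnot(f$hidden_in %in% names(f$boxes))
    }
  }
  # percepts must round-trip through the binary encoding
  for (p in scenario_percepts(scenario)) {
    for (ev in p) {
      dec <- decode_percept(encode_sts(ev))
      stopifnot(identical(dec$object_location, ev$object_location),
                identical(dec$turn, ev$turn))
    }
  }
  invisible(TRUE)
}

#' Write a scenario to a JSON file
#'
#' @param scenario A [gen_test_scenario()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "test_scenario"))
  jsonlite::write_json(unclass(scenario), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read a scenario from a JSON file
#'
#' @param path File written by [write_scenario()].
#' @return A validated `test_scenario` object.
#' @export
read_scenario <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  obj$frames <- lapply(obj$frames, function(f) {
    f$hidden_in <- if (is.null(f$hidden_in)) NA else f$hidden_in
    f$object_id <- if (is.null(f$object_id)) NA else f$object_id
    f
  })
  obj$questions <- unlist(obj$questions)
  obj$seed <- as.integer(obj$seed)
  sc <- structure(obj, class = "test_scenario")
  validate_scenario(sc)
  sc
}
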