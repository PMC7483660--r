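#' Toy-object template registry
#'
#' The twelve object templates the symbolic perception layer can identify;
#' one-hot encoded in the percept. `"ladybird"` is the object used in the
#' test scenarios and is included in training by default.
#'
#' @return Character vector of object identifiers.
#' @export
object_registry <- function() {
  c("ladybird", "beetle", "duck", "car", "ball", "cup",
    "bear", "frog", "train", "plane", "drum", "doll")
}

#' Names of the 24 percept channels
#'
#' Layout of the identity-stripped stimulus encoding: object-id one-hot (12),
#' object location (left/right), box presence per (box, location) cell (4),
#' blindfold state (worn / not worn, present / absent) and turn state
#' (facing / turned). A box's contents are not observable from outside, so
#' the percept carries where each box stands, never whether it is full;
#' whether the object is hidden shows up only as the absence of the object
#' channels. The 2-neuron self/other identity tag travels alongside, not
#' inside, these channels, because it is stripped before perspective
#' storage.
#'
#' @return Character vector of length 24.
#' @export
percept_channels <- function() {
  c(paste0("obj_", object_registry()),
    "loc_left", "loc_right",
    "box_yellow_left", "box_yellow_right",
    "box_green_left", "box_green_right",
    "bf_worn", "bf_not_worn", "bf_present", "bf_absent",
    "turn_facing", "turn_turned")
}

#' Build a symbolic scene event
#'
#' A first-person snapshot of the scene as perceived by the owner of the
#' percept stream: the visible object (if any), occupied boxes, the
#' blindfold state attributed to the percept owner, and the owner's turn
#' state. Opaque-blindfold and turn-around occlusion is expressed by the
#' generator as `object_location = "absent"`.
#'
#' @param agent_id `"self"` or `"other"`: whose perspective the event is
#'   relevant to.
#' @param object_id Template label from [object_registry()], or `NA` when no
#'   object is visible.
#' @param object_location `"left"`, `"right"` or `"absent"`.
#' @param boxes Named list mapping box id (`"yellow"`, `"green"`) to
#'   `list(location = , occupied = )`; every listed box is visible in the
#'   scene (the occupancy flag is scene ground truth, not perceivable).
#' @param blindfold `list(present = , worn = )` for the percept owner.
#' @param turn `"facing"` or `"turned"`.
#' @param timestamp Frame index.
#' @return An object of class `scene_event`.
#' @export
scene_event <- function(agent_id = "self", object_id = NA,
                        object_location = "absent", boxes = list(),
                        blindfold = list(present = FALSE, worn = FALSE),
                        turn = "facing", timestamp = 0L) {
  stopifnot(agent_id %in% c("self", "other"),
            object_location %in% c("left", "right", "absent"),
            turn %in% c("facing", "turned"))
  if (object_location != "absent" &&
      !(object_id %in% object_registry())) {
    stop("unknown object template: ", object_id, call. = FALSE)
  }
  if (isTRUE(blindfold$worn) && !isTRUE(blindfold$present)) {
    stop("a blindfold cannot be worn if none is present", call. = FALSE)
  }
  for (b in names(boxes)) {
    stopifnot(b %in% c("yellow", "green"),
              boxes[[b]]$location %in% c("left", "right"))
  }
  structure(list(agent_id = agent_id, object_id = object_id,
                 object_location = object_location, boxes = boxes,
                 blindfold = list(present = isTRUE(blindfold$present),
                                  worn = isTRUE(blindfold$worn)),
                 turn = turn, timestamp = as.integer(timestamp)),
            class = "scene_event")
}

#' Encode a scene event into a percept vector
#'
#' Deterministic binary encoding of a [scene_event()] onto the 24 stimulus
#' channels of [percept_channels()], plus the separate 2-neuron identity tag
#' used only for perspective routing. Currents are 0.0 or 1.0; exactly one of
#' worn / not-worn, present / absent and facing / turned is active.
#'
#' @param event A [scene_event()].
#' @return A list with `currents` (named numeric, length 24) and `id`
#'   (named numeric, length 2: self / other tag).
#' @export
encode_sts <- function(event) {
  stopifnot(inherits(event, "scene_event"))
  ch <- percept_channels()
  x <- setNames(numeric(length(ch)), ch)
  if (event$object_location != "absent") {
    x[paste0("obj_", event$object_id)] <- 1
    x[paste0("loc_", event$object_location)] <- 1
  }
  for (b in names(event$boxes)) {
    x[paste0("box_", b, "_", event$boxes[[b]]$location)] <- 1
  }
  x["bf_worn"] <- as.numeric(event$blindfold$worn)
  x["bf_not_worn"] <- as.numeric(!event$blindfold$worn)
  x["bf_present"] <- as.numeric(event$blindfold$present)
  x["bf_absent"] <- as.numeric(!event$blindfold$present)
  x["turn_facing"] <- as.numeric(event$turn == "facing")
  x["turn_turned"] <- as.numeric(event$turn == "turned")
  id <- c(self = as.numeric(event$agent_id == "self"),
          other = as.numeric(event$agent_id == "other"))
  list(currents = x, id = id)
}

#' Decode a percept vector back into a scene event
#'
#' Inverse of [encode_sts()] on valid percepts; used to verify that the
#' encoding is lossless over the finite event space.
#'
#' @param percept A list as returned by [encode_sts()].
#' @return A [scene_event()].
#' @export
decode_percept <- function(percept) {
  x <- percept$currents
  reg <- object_registry()
  obj_bits <- x[paste0("obj_", reg)]
  loc <- if (x["loc_left"] == 1) "left" else
    if (x["loc_right"] == 1) "right" else "absent"
  oid <- if (loc == "absent") NA_character_ else reg[which(obj_bits == 1)]
  boxes <- list()
  for (b in c("yellow", "green")) {
    for (side in c("left", "right")) {
      if (x[paste0("box_", b, "_", side)] == 1) {
        boxes[[b]] <- list(location = side)
      }
    }
  }
  scene_event(
    agent_id = if (percept$id[["self"]] == 1) "self" else "other",
    object_id = oid, object_location = loc, boxes = boxes,
    blindfold = list(present = x[["bf_present"]] == 1,
                     worn = x[["bf_worn"]] == 1),
    turn = if (x[["turn_facing"]] == 1) "facing" else "turned")
}

#' Create an empty perspective store
#'
#' Two time-ordered buffers: IPL for self-relevant percepts, pSTS for
#' other-relevant percepts. Buffers are cleared per trial by default since
#' each test is a fresh episode.
#'
#' @return An object of class `perspective_store`.
#' @export
perspective_store <- function() {
  structure(list(ipl = list(), psts = list()), class = "perspective_store")
}

#' Route a percept into the perspective store
#'
#' Appends the percept to the IPL buffer if the identity tag marks it
#' self-relevant, to the pSTS buffer if other-relevant. The stored pattern is
#' the identity-stripped 24-channel stimulus (the routing output format).
#'
#' @param percept A list as returned by [encode_sts()].
#' @param store A [perspective_store()].
#' @return The updated store.
#' @export
tpj_route <- function(percept, store) {
  stopifnot(inherits(store, "perspective_store"))
  id <- percept$id
  if (sum(id) != 1) {
    stop("ambiguous identity tag: exactly one of self/other must be active",
         call. = FALSE)
  }
  if (id[["self"]] == 1) {
    store$ipl[[length(store$ipl) + 1L]] <- percept$currents
  } else {
    store$psts[[length(store$psts) + 1L]] <- percept$currents
  }
  store
}

#' Working-memory container with forgetting
#'
#' Holds the previous frame's trace, re-injected into the next frame's
#' input scaled by the forgetting factor `zeta`. With `zeta = 0` inference
#' depends only on the current frame.
#'
#' @param zeta Forgetting factor in `[0, 1]`.
#' @param n Vector length.
#' @return An object of class `working_memory`.
#' @export
working_memory <- function(zeta = 0.5, n) {
  stopifnot(zeta >= 0, zeta <= 1)
  structure(list(zeta = zeta, value = numeric(n), empty = TRUE),
            class = "working_memory")
}

#' Infer visual access for one frame
#'
#' The perception network receives the current stimulus superposed with the
#' decayed previous stimulus (`input_t = stimulus_t + zeta * stimulus_{t-1}`),
#' decodes the perceived object location over (left, right, unseen), and
#' updates the working memory to the current stimulus. The memory holds a
#' single-lag trace: on the two-frame training trials this coincides with
#' re-injecting the previous network input, and on longer test streams it
#' keeps every frame's input within the trained input distribution.
#'
#' @param stimulus 24-channel stimulus currents (identity-stripped).
#' @param wm A [working_memory()] holding the previous input.
#' @param net The trained perception network (labels left/right/unseen).
#' @return A list with `outcome` (`"left"`, `"right"`, `"unseen"` or
#'   `"no-decision"`), `decision_ms`, `activity` and the updated `wm`.
#' @export
precuneus_infer <- function(stimulus, wm, net) {
  stopifnot(inherits(net, "vpsnn"), inherits(wm, "working_memory"))
  if (!isTRUE(net$trained)) {
    stop("perception network has not been trained", call. = FALSE)
  }
  if (length(stimulus) != net$n_in) {
    stop("stimulus dimension does not match the network input layer",
         call. = FALSE)
  }
  input <- as.numeric(stimulus) + wm$zeta * wm$value
  res <- vpsnn_infer(net, input)
  wm$value <- as.numeric(stimulus)
  wm$empty <- FALSE
  list(outcome = res$label, decision_ms = res$decision_ms,
       activity = res$activity, wm = wm)
}

#' Update the believed object location for one frame
#'
#' The belief network receives the visual-access outcome one-hot over
#' (left, right, unseen) with the decayed previous belief superposed on the
#' two belief-location input neurons, and decodes the believed location.
#' When the object is visible the belief follows perception; when unseen the
#' decayed previous belief carries the location forward (object permanence).
#'
#' @param visual_outcome `"left"`, `"right"` or `"unseen"`.
#' @param wm A [working_memory()] holding the previous belief one-hot
#'   (length 2).
#' @param net The trained belief network (labels left/right).
#' @return A list with `belief` (`"left"`, `"right"` or `"no-belief"`),
#'   `decision_ms`, `activity` and the updated `wm`.
#' @export
acc_infer <- function(visual_outcome, wm, net) {
  stopifnot(inherits(net, "vpsnn"), inherits(wm, "working_memory"))
  if (!isTRUE(net$trained)) {
    stop("belief network has not been trained", call. = FALSE)
  }
  stopifnot(visual_outcome %in% c("left", "right", "unseen", "no-decision"))
  if (visual_outcome %in% c("unseen", "no-decision") && wm$empty) {
    return(list(belief = "no-belief", decision_ms = NA_real_,
                activity = rep(NA_real_, net$n_out), wm = wm))
  }
  input <- c(as.numeric(visual_outcome == "left"),
             as.numeric(visual_outcome == "right"),
             as.numeric(visual_outcome %in% c("unseen", "no-decision")))
  input[1:2] <- input[1:2] + wm$zeta * wm$value
  res <- vpsnn_infer(net, input)
  belief <- res$label
  if (belief == "no-decision") belief <- "no-belief"
  if (belief %in% c("left", "right")) {
    wm$value <- c(as.numeric(belief == "left"),
                  as.numeric(belief == "right"))
    wm$empty <- FALSE
  }
  list(belief = belief, decision_ms = res$decision_ms,
       activity = res$activity, wm = wm)
}

#' Create an empty belief store
#'
#' Ventral store for the self-attributed belief, dorsal store for the belief
#' attributed to the other agent; populated from belief-network outputs, with
#' the perspective source recorded.
#'
#' @return An object of class `belief_store`.
#' @export
belief_store <- function() {
  structure(list(vmpfc = NULL, dmpfc = NULL,
                 provenance = list(vmpfc = NA, dmpfc = NA)),
            class = "belief_store")
}

#' Store a reasoned belief
#'
#' @param store A [belief_store()].
#' @param belief `"left"`, `"right"` or `"no-belief"`.
#' @param perspective `"self"` (ventral store) or `"other"` (dorsal store).
#' @param source Which perspective buffer the reasoning consumed
#'   (`"IPL"` or `"pSTS"`).
#' @return The updated store.
#' @export
store_belief <- function(store, belief, perspective, source) {
  stopifnot(inherits(store, "belief_store"),
            perspective %in% c("self", "other"))
  if (perspective == "self") {
    store$vmpfc <- belief
    store$provenance$vmpfc <- source
  } else {
    store$dmpfc <- belief
    store$provenance$dmpfc <- source
  }
  store
}

#' Select the belief to export for a question
#'
#' For a question about the other agent, a conflict between the self and
#' other beliefs engages the frontal self-belief inhibition gate (see
#' [gate_belief()]); the dorsal (other) belief is exported when the gate is
#' mature, and the ambiguity resolves toward the self belief when it is not.
#' For a question about the self, the other belief is fully suppressed and
#' the ventral store is exported without frontal involvement.
#'
#' @param store A [belief_store()].
#' @param question `"about-other"` or `"about-self"`.
#' @param circuit An [inhibition_circuit()].
#' @return A list with `belief`, `gating` (a gating outcome for the
#'   about-other path, `NULL` otherwise) and `latency_ms`.
#' @export
mpfc_select <- function(store, question, circuit) {
  stopifnot(question %in% c("about-other", "about-self"))
  if (question == "about-self") {
    if (is.null(store$vmpfc)) {
      return(list(belief = "no-belief", gating = NULL, latency_ms = 0))
    }
    settle <- !is.null(store$dmpfc) && !identical(store$dmpfc, store$vmpfc)
    return(list(belief = store$vmpfc, gating = NULL,
                latency_ms = circuit$mpfc_export_ms +
                  if (settle) circuit$conflict_settle_ms else 0))
  }
  g <- gate_belief(store, circuit)
  list(belief = g$belief, gating = g, latency_ms = g$latency_ms)
}

#' Turn a selected belief into a pointing gesture
#'
#' @param belief `"left"`, `"right"` or `"no-belief"`.
#' @param driven_by Which belief store drove the response.
#' @return A list with `gesture` (`"point-left"`, `"point-right"` or
#'   `"none"`) and `driven_by`.
#' @export
motor_respond <- function(belief, driven_by = "other-belief") {
  gesture <- switch(belief,
                    left = "point-left",
                    right = "point-right",
                    "none")
  list(gesture = gesture, driven_by = driven_by)
}
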