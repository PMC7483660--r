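---
title: "A spiking-network model of false-belief reasoning from self-experience"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spiking-network model of false-belief reasoning from self-experience}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Non-verbal unexpected-transfer tasks probe whether an observer attributes a
*false belief* to another agent: an object is hidden, then moved while the
other agent cannot see, and the observer is asked where the object is
"according to" the other agent and according to itself. Passing requires
(i) *object permanence* — a belief about an object's location that persists
while the object is out of view, (ii) *visual access* inference — deciding
from observable cues (a worn blindfold, a turned-away head) whether an agent
could see an event, and (iii) *perspective selection* — reporting the other
agent's belief rather than one's own when the two diverge.

`spiketom` implements a brain-region-structured account of these abilities:
every component is either learned from first-person experience by a small
spiking network or realised as an explicit inhibitory gating circuit. Two
training groups differ only in their blindfold experience — one wore an
opaque blindfold, the other a trick blindfold that looks identical but can
be seen through — and that difference alone flips the attributed belief in
the test, while the test stimuli themselves are identical for both groups.

## Architecture

Symbolic scene events stand in for robot vision. Each event is encoded onto
24 binary stimulus channels (object identity one-hot, object side, box
presence per box and side, blindfold worn/not-worn and present/absent, and
facing/turned), plus a two-neuron self/other identity tag used only for
routing. Percepts are routed by the identity tag into a self-relevant
buffer and an other-relevant buffer (the perspective store). Two shallow
spiking networks do the learned work:

* a **perception network** (24 input, 3 hidden, 3 output neurons) maps a
  stimulus, superposed with a working-memory trace of the previous
  stimulus, to the perceived object location — left, right, or an explicit
  *unseen* signal when no object is detected;
* a **belief network** (3 input, 3 hidden, 2 output neurons) maps the
  perception outcome, superposed with the decayed previous belief, to the
  believed location; because its training always ends with the object's
  true location revealed, it learns that objects stay where last located
  when the outcome is "unseen".

An inhibitory control circuit selects whose information flows where: in
perspective gating, inhibitory neurons carry the other-relevant pattern
against the self-relevant one; identical patterns cancel, a conflict fires
the inhibit-result neurons, and — if the frontal connection has matured —
the frontal gate suppresses the self pattern so the other-relevant stimuli
are processed first. The same machinery gates which stored belief is
exported for a question; for self-directed questions a large inhibitory
current suppresses the other-relevant information with no frontal
involvement. The two frontal connections carry binary maturation flags
whose four combinations are the developmental ablation grid.

## Neuron model and learning rule

Neurons are conductance-based leaky integrate-and-fire units:
\(\tau_m \dot V = -(V - V_L) - (g_E/g_L)(V - V_E)\), with the excitatory
conductance decaying with \(\tau_E\) and driven by presynaptic activity.
Defaults are standard cortical values (\(V_L = -70\), \(V_{th} = -54\),
\(V_E = 0\) mV, \(\tau_m = 20\), \(\tau_E = 5\) ms, 2 ms refractory period,
0.1 ms step, 100 ms presentation window); none of the behavioural claims
depends on the absolute millisecond values and all are configurable. Hidden
neurons spike and reset; output neurons integrate without reset, so the
decision variable is the time-averaged normalised potential and the
decision time is the first threshold crossing. Propagated activity is a
rate–potential code: the normalised potential (rectified at rest) plus
10 ms of threshold-level activity per spike — a plain sawtooth average is
insensitive to firing rate, which we verified empirically.

Training follows a four-step voltage-driven scheme per sample:

1. a free feed-forward presentation, whose potential updates blend a
   homeostatic correction toward input–output balance at weight
   \(1 - t/T\) (training starts homeostatically dominated and ends purely
   feed-forward);
2. a teaching signal on the output layer — implemented as a second
   presentation with the output potentials clamped to the teacher state;
   the clamp's influence reaches the hidden layer through the reciprocal
   hidden–output synapses (feedback scale 0.3);
3. consolidation of the teaching-induced potential *changes* into the
   weights: readout synapses integrate presynaptic activity times the
   teacher displacement of the outputs (a delta rule), hidden synapses
   integrate the input currents times the clamped-minus-free displacement
   of the hidden potentials (a contrastive, GeneRec-style update);
4. slow multiplicative decay (3×10⁻⁴ per sample) of the input synapses,
   pruning channels the task never recruits.

We chose the contrastive reading of the consolidation rule deliberately:
with only three hidden neurons, purely unsupervised homeostatic weight
shaping cannot make the hidden code task-aligned (a linear readout of the
resulting hidden activities stalls near 64% on the visual-access task), so
the teaching signal must shape the hidden features, and reciprocal
connectivity is the biologically standard route for it. The synaptic decay
matters because twelve of the 24 channels carry object identity, which is
irrelevant to every training target; without decay those synapses retain
initialisation noise and occasionally support degenerate fits.

Training runs 60 epochs of the blend ramp and then, if needed, continues in
feed-forward mode up to 200 epochs. Convergence means every training sample
is classified correctly; we additionally keep a smoothed (late-epoch
averaged) copy of the weights and retain the best-fitting state seen at any
checkpoint, because continued training past convergence slowly erodes the
fit (the decay keeps acting once the error pressure vanishes). A run that
never fits the training set restarts from a fresh initialisation — the
local two-phase rule settles in a poor optimum (typically a left/right
confusion) for a minority of draws — stepping through a deterministic
ladder of decay values; up to eight attempts are made and a failure after
all of them is reported, never masked.

## The synthetic scenario generator

The generator emulates the training and test regimes as symbolic event
streams. Visual-access training comprises 160 two-frame trials: an object
appears at one side, then one of five query scenes follows — the blindfold
is put on, the head turns away, the object moves to the other side, a box
occludes it, or a hidden object is revealed. The teacher is the true
visibility outcome for the group (opaque worn, turned, or boxed ⇒ unseen;
trick blindfold ⇒ still visible; moved or revealed ⇒ the new side).
Object-permanence training comprises 50 three-frame trials (place, hide in
a box, then reveal in place or watch it move), with the object's true
location as the target throughout.

Several generator properties matter and are worth stating explicitly,
together with why we chose them:

* **Percepts carry only observable quantities.** Box channels encode where
  each box stands, never whether it is full — a closed box looks the same
  either way — and boxes persist as scenery across frames, as they do on
  the test desk. "Unseen" therefore rests on the absence of the object
  channels, which is also how the training target is defined.
* **Occlusion cues spare large scenery.** A worn (opaque) blindfold covers
  most of the visual field and a twisted head loses the frontal view: in
  both cases the small attended object disappears from the percept while
  the large box scenery is still caught peripherally. Without this, the
  test frames — observed third-person with boxes in full view — would sit
  outside the first-person training distribution.
* **Occlusion onset speed varies.** In half of the blindfold/turn trials
  the occlusion lands fast: the attended object's channels persist at full
  trace strength while background channels decay by ζ. The critical test
  frame (occluder present *and* full-strength object evidence, which must
  still be judged "unseen" by the opaque group) is thereby a literal
  training constraint rather than an extrapolation; this single property
  was the dominant driver of test reliability.
* **The blindfold lies around.** In the blindfold groups the (unworn)
  blindfold is visible in half of all non-worn frames, so its mere
  presence in a scene carries no visual-access information — precisely
  what the blindfold-position control experiment probes.
* **Balanced strata.** Scene types, sides, box identities, onset speeds,
  start states and object identities are sampled in balanced, shuffled
  proportions rather than i.i.d.; with 160 trials, unbalanced draws
  otherwise leave whole cue combinations (for example a fast blindfold
  onset over a right-side object) untrained, and identity channels become
  spuriously correlated with visibility outcomes.

The working memory holds a single-lag trace:
\(input_t = stimulus_t + \zeta\,stimulus_{t-1}\). On the two-frame training
trials this is indistinguishable from re-injecting the previous network
input, but on the five-frame test streams the recursive variant compounds
geometrically (\(\zeta^2, \zeta^3, \dots\)) and places every later frame
outside the trained input distribution; we verified that this breaks the
perception outcomes downstream and therefore adopted the single-lag trace.
The forgetting factor defaults to ζ = 0.75: the network learns to cancel
remembered location evidence only at the strength it sees during training,
so the trace must be strong enough that the learned cancellation covers the
full-strength evidence present at test. The belief network's memory (the
decayed previous decoded belief) is depth-one by construction.

The belief network's training inputs are teacher-forced on both components
(true visibility outcome, true previous location). The perception network
still misreads an occasional object-permanence frame, and feeding its raw
decodings would make the belief training set internally inconsistent — the
same input pattern with two different targets — rendering the convergence
criterion unsatisfiable. At test time the belief network consumes the
perception network's actual decoded outcomes.

## Test protocols and timing

The five test scenarios follow the unexpected-transfer structure: object
left → hidden in the yellow (left) box → moved right while the actor wears
the blindfold / faces away (false belief) or watches (true belief) → hidden
in the green (right) box → occluder removed. The opaque and transparent
streams are frame-by-frame identical; only the agents' training histories
differ. The control scenario leaves the blindfold on the desk.

A repetition of a protocol retrains every network from a
repetition-specific seed and passes only if both questions are answered
correctly; the stronger retrain-per-repetition reading was chosen (a
reuse switch exists). Activation traces record serial region onsets and
offsets; "time consumption" is simulated time from a stage's input onset to
its output decision. The perception/belief decision times come from the
first output threshold crossing; the gating stages have configurable
durations (perspective gate 5–6 ms, frontal perspective inhibition
53.8 ms, belief export 10 ms, frontal belief inhibition 17.5 ms, conflict
settling 0.4 ms; encoding and motor stages 448 and 500 ms). The defaults
place each stage in the tens-of-milliseconds range typical of cortical
processing; only the *orderings* among conditions carry scientific content
— false-belief reasoning exceeds true-belief reasoning because the belief
gate engages, other-directed reasoning exceeds self-directed reasoning
because the perspective gate engages, the turn-around true-belief case is
fastest because identical perspectives skip the gate entirely, and
self-directed timing is nearly condition-independent. The headline
comparisons sum the perspective gate, frontal inhibition insertions and
belief export (the stages that differ between conditions) and exclude the
common encoding, perception, belief-update, goal-encoding and motor stages.

## Ablations

Maturation of the two frontal connections is modelled as binary weights.
The four combinations reproduce the canonical table on the opaque
false-belief scenario: both immature → the failed self-perspective
inhibition corrupts the first perspective output (the predominant
self-relevant activity with a 0.1-weight residue of the other pattern) and
the other's visual access is inferred wrongly; only the belief gate mature
→ same perception failure; only the perspective gate mature → the
attribution is correct but both candidate responses stay active and the
self-directed action wins (a deterministic self-belief preference, with a
stochastic-bias switch); both mature → pass. The self-directed question is
unaffected in every cell.

Reducing the perception network's hidden layer models an immature region.
In this implementation one hidden unit cannot learn the visual-access
discrimination at all (≈50% ceiling), two units learn most of it —
including the blindfold scenes essentially perfectly — but plateau around
92% overall and fail the false-belief attribution, and three units master
the training set and pass. The capability threshold thus appears one step
earlier in learning than sometimes described (as a training ceiling rather
than a pure attribution failure); with two units the blindfold's own
visual-access meaning is still acquired while the task is failed, which is
the behavioural signature that matters.

## Problem sizes and what the tests show

The shipped experiments use the protocol sizes throughout: 160
visual-access trials, 50 object-permanence trials, 20 repetitions per
protocol. The experiment configuration integrates 50 ms presentation
windows at a 0.2 ms step — the attained potentials and decisions are
indistinguishable from finer settings for these stimuli, and a full
train-and-test repetition then takes a few seconds on one CPU core; the
neuron-level default step stays at 0.1 ms and both are configurable. A
full twenty-repetition protocol runs in two to three minutes.

The generator emulates the *structure* of the robot experiments — symbolic,
noise-free percepts with ground-truth identity tags — not camera vision:
there is no sensor noise, no identification error, and self/other
recognition is taken as given. Passing these tests therefore shows that the
learning scheme, memory structure and gating circuit jointly produce the
belief-attribution behaviour under the stated experience; it does not show
robustness to perceptual noise or real-world timing.

## Known limitations

* Reliability is an engineered property: training restarts, balanced
  strata, the fast-onset trials and the synaptic decay were all required to
  make 20/20 repetitions typical; with three hidden units the margin on
  the critical frames is structurally small, and rare seeds may still fail
  a repetition.
* Maturation is binary and not itself learned; graded maturation and
  learning of the frontal connections are out of scope.
* The absolute stage latencies are calibrated constants, not emergent
  quantities; only their orderings are claims.
* A same-side reveal (object reappearing where it was hidden) is excluded
  from perception training — it is indistinguishable from a continuing
  occlusion at trace strength ζ within this architecture — and no
  evaluated stream contains one; the belief network covers that case
  through its teacher-forced object-permanence training.
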