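---
title: "Training DNA profile HMMs with Conditional Baum-Welch and Dynamic Model Surgery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training DNA profile HMMs with Conditional Baum-Welch and Dynamic Model Surgery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plan7)
```

## The model

A profile HMM represents a sequence family as a chain of ancestral
positions.  Each position $p$ of a Plan 7 model carries three states: a
Match state $M_p$ with a position-specific multinomial emission
distribution over A, C, G, T; an Insertion state $I_p$ emitting from a
single shared (background-like) distribution; and a silent Deletion state
$D_p$.  Seven transitions leave each position triple --
$M{\to}M, M{\to}I, M{\to}D, I{\to}M, I{\to}I, D{\to}M, D{\to}D$ -- and
Insertion$\leftrightarrow$Deletion transitions do not exist.  A model with
$n$ positions has $3n + 4$ states, counting Begin, End and the two
flanking bookkeeping states.  In *local* mode the flanking states act as
DeletionIn/DeletionOut: a hit may enter the model at any position (Begin
$\to$ DeletionIn, continue probability .9999 per skipped position, exit
.0001) and leave early through DeletionOut, while flanking insertions are
disallowed.  `buildPlan7()` constructs either topology;
`canonicalOrdering()` and `transitionTable()` expose the state graph.

Under the canonical ordering (Begin, DeletionIn, then $M_p, I_p, D_p$ per
position, then DeletionOut, End) every strictly advancing transition moves
at most $k = 5$ index steps forward, the longest hop being $M_p \to
D_{p+1}$.  This band is what allows the forward and backward dynamic
programming recursions to proceed state-by-state (row-wise) instead of
time-by-time, which in turn makes the conditional updates below no more
expensive than ordinary Baum-Welch.

## Estimation

**Baum-Welch** iterates a full expectation step (scaled forward-backward
over all sequences, accumulating the expected number of uses of every
emission and transition; `expectedCounts()`) and a maximization step
(counts plus Dirichlet pseudocounts, normalized per multinomial group;
`maximizeStep()`).  We use add-one (Laplace) pseudocounts by default; the
transposon regime scales the transition pseudocounts by the initial model
length to reflect their repeated use.  A floor of $10^{-5}$ is enforced on
every trained parameter so the algorithms cannot get trapped at
zero-valued parameters.  With pseudocounts $a$ the update
$(\text{counts} + a)/\Sigma$ monotonically increases the penalized
objective $\log L + \sum a \log \theta$; the trace reports both this
objective and the raw log-likelihood, and the monotonicity contracts are
stated on the former.

**Conditional Baum-Welch** (an expectation *conditional* maximization
scheme) updates the parameter group of one position at a time -- its match
emission row and its seven transitions -- using the current values of all
other parameters, sweeping positions in ascending order and then updating
the state-independent group (insertion emissions, Begin, DeletionIn/Out).
The sweep reuses dynamic programming work: forward columns before the
active position already reflect the updated parameters, backward columns
after it are still valid because their parameters have not changed, and
the likelihood needed for normalizing the expected counts is computed
from a transition cut between the two regions.  One sweep costs the same
order as one Baum-Welch iteration; each conditional update is provably
monotone in the penalized objective (`cbwSweepTracked()` verifies this).

Convergence is declared when the average Euclidean distance over
parameter groups (one norm per multinomial, then the arithmetic mean --
a unit that stays comparable when the model length changes) falls below
the tolerance: $10^{-5}$ in the simulation regime, $10^{-7}$ in the
transposon regime.

## Dynamic Model Surgery

EM on four-letter alphabets is notorious for local optima in which model
positions are misaligned against the family: a position that the family
does not use attracts deletions, and a region where the model is too
short forces insertions.  Surgery monitors, for every position $j$, the
fraction of sequences whose expected insertion (deletion) usage at $j$
exceeds a threshold $\xi$; when that fraction reaches $\nu_\text{ins}$
($\nu_\text{del}$), a position is added after $j$ (removed).  Simulation
defaults: $\xi_0 = .01$, both fractions .5, and $\xi$ escalates by
$\epsilon = .005$ whenever the structure cycles.  Transposon defaults:
$\xi_0 = .1$, insertion fraction .1, deletion fraction .9, and adaptive
escalation to the midpoint of the two smallest usage values above the
current $\xi$ (the smallest move that changes an exceedance fraction).
The deletion-usage statistic counts ordinary Deletion-state occupancy;
local-mode DeletionIn/Out skipping is the entry/exit mechanism of a hit,
not evidence that a position is unused, and is deliberately not counted.

Two stabilizing choices, made where the method's description is silent,
matter in practice and were selected after observing the failure modes of
the alternatives (each alternative was implemented first):

* **Bounded appetite.**  At a freshly initialized (near-uniform) model
  the expected counts are diffuse and *every* position looks deletable:
  applying all triggered actions in one sweep deletes essentially the
  whole model.  The trainer therefore corrects only the
  strongest-margin trigger per iteration
  (`dms$maxActionsPerIteration`, default 1), so each correction changes
  the usage counts the next decision sees, and lets surgery engage only
  after a two-iteration warm-up (`dms$delay`), by which point the counts
  reflect the data rather than the starting point.
* **Cycle signature.**  A cycle is declared when an iteration that took
  actions lands on a model length already seen since the last
  escalation; a strictly growing or shrinking history never escalates.
  Signatures based on exact action sites almost never repeat, so under
  them escalation would never fire and the threshold would stay pinned
  at $\xi_0$ amid perpetual churn.  With the length signature, a run
  whose structure oscillates steadily raises $\xi$ until the
  oscillating triggers fall silent, after which the parameters converge
  normally; runs whose structure is simply right converge quickly with
  $\xi$ barely moved.  Structural search of this kind takes more
  iterations than plain EM, so surgery runs are given a higher
  iteration budget (800 in the packaged studies, versus the ~70 sweeps
  a plain run needs).

Inserted positions copy the source position's transition group and start
with a neutral uniform emission.  (Duplicating the source emissions was
also tried; under the bounded-appetite cadence two identical positions
share usage and keep re-triggering insertion, inflating the model.)

## The simulation harness

`sampleTrueProfile(L, c)` draws a random consensus of length $L$ and
builds a "true" profile whose match emission puts probability $c$ (the
conservation level) on the consensus residue and $(1-c)/3$ on each other
residue.  Truth transitions are high-fidelity -- $M{\to}M$ .97, branches
.015 each, gap extension .3 -- so sampled sequences stay near the
consensus length; these values are the package's choice, made once,
since only the emission construction is prescribed.  By design, sequences
sampled at conservation $c$ agree with the consensus at a fraction $c$ of
their match-state emissions, which `matchIdentity()` measures using the
simulation-time alignments.  Starting profiles
(`randomStartProfile()`) draw match emissions from the flat Dirichlet --
the uniform distribution on the simplex -- so that different seeds give
genuinely different starts, with neutral global-mode transitions
(simulation regime) or the local-mode table (transposon regime: Match
enters DeletionOut with .9, continues with .095; gaps extend/end with .5
each; Begin enters DeletionIn with .9).

What the simulator does *not* emulate: residue composition bias,
transition/transversion-biased substitution, and realistic indel length
distributions.  Passing tests on simulated families therefore demonstrate
correct and effective estimation under the model's own assumptions, not
performance on real genomic sequence.

The packaged study sizes are scaled to run comfortably inside a test
suite: truth length 50 with 50 training sequences and 8 paired starts for
the algorithm comparison, and 12 runs for the length-recovery check.

## Hit search and calibration

`scanProfile()` finds hits with a local Viterbi pass (log-odds scored
against the profile's insertion distribution as the background), greedily
taking the best hit, masking its span and repeating; the reverse strand
is scanned on the reverse complement with coordinates mapped back.  The
score threshold comes from scanning a shuffled copy of the target
(`shuffleSequence()`, composition-preserving) and choosing the smallest
score with at most 5% of null hits strictly above it
(`empiricalThreshold()`).  Ties in the Viterbi traceback prefer Match
over Deletion over Insertion, then the lower position index, so results
are deterministic.

## Transitive alignments

To evaluate hits on two genomes against each other without a curated
truth set, two hits are projected through a genome-genome fragment
alignment (`buildPileup()`): element rows carry their genomic residues at
covered columns, and columns where the *other* genome's row is gapped are
marked unalignable (lowercase).  Dropping the genome rows yields the
implied element-element alignment (`transitiveAlign()`); columns at which
the genome-genome alignment itself is gapped become dot-gap columns,
rendered "." and excluded from all statistics.  Remaining columns are
matches, transitions (substitutions within \{A,G\} or \{C,T\}),
transversions, or gaps, and the comparison score is matches plus
transitions.  Ambiguous residues (N) fall in the transversion class and
are counted separately as a diagnostic.  A hit pair aligning through
several fragments contributes one alignment per fragment; duplicate
(hitA, hitB, fragment) triples are deduplicated by coordinates.

## Numerical choices and edge cases

* Forward/backward values are kept in linear space with per-time scale
  factors rather than log space, so the row-wise restart can reuse
  columns cheaply; time 0 holds the pre-emission silent states.  During a
  conditional sweep the scale factors are frozen at their sweep-start
  values -- they only need to prevent under/overflow, not renormalize.
* The DeletionIn/Out chains are folded into effective entry/exit
  probabilities (entry at $M_p$ costs $.9 \times .9999^{p-2} \times
  .0001$), so the engine never materializes per-position flanking states.
* The ambiguity code N emits with probability one from every emitting
  state, removing it from likelihood discrimination.
* An empty sequence is a legal Viterbi input (empty hit, score
  $-\infty$), but training requires nonempty sequences.
* Degenerate maximization (all-zero counts with all-zero pseudocounts)
  raises an error rather than renormalizing garbage.

## A worked example

```{r example, eval = FALSE}
truth <- sampleTrueProfile(50, conservation = .7, seed = 1)
train <- sampleSequences(truth$model, 50, seed = 2)
start <- randomStartProfile(50, "simulation", seed = 3)

plain <- cbwTrain(start, train, maxIterations = 500)
surg  <- trainProfile(start, train,
                      trainingConfig("CBW", useDMS = TRUE,
                                     maxIterations = 500))
c(plain = tail(plain$trace$loglik, 1),
  surgery = tail(surg$trace$loglik, 1),
  length = modelLength(surg$model))
```

## Known limitations

* The transposon-regime defaults are implemented and unit-tested, but the
  package's studies are simulation-scale; genome-scale search behaviour
  (very long targets, repeat-dense backgrounds) is untested territory.
* Surgery inherits EM's dependence on the starting point: with
  pathological starts it can converge to a structurally wrong but locally
  optimal model; the trial-and-revert rule bounds the damage but cannot
  guarantee the global optimum.
* The HMMer-2-style export targets semantic fidelity (probabilities
  recoverable from the printed scores), not byte compatibility with any
  historical tool output.
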