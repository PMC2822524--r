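# plan7

Profile hidden Markov models for DNA repeat families, with training
algorithms built to escape the local optima that plague EM on four-letter
alphabets.

Profile HMMs are the standard probabilistic model of a sequence family:
a chain of ancestral positions, each with a Match state (position-specific
emission distribution over A, C, G, T), an Insertion state (shared
background-like emissions) and a silent Deletion state, in the "Plan 7"
topology that forbids direct Insertion–Deletion transitions.  They are
ubiquitous for proteins but rarely used for DNA, largely because
Baum-Welch (EM) converges prematurely on small alphabets — a serious
obstacle for modeling poorly conserved families such as ancient
transposable elements.  This package implements, besides classic
Baum-Welch:

* **Conditional Baum-Welch (CBW)** — an expectation conditional
  maximization scheme that updates one model position's parameter group
  at a time, conditional on all the others.  Because the canonical state
  ordering of a Plan 7 model is banded (no transition advances more than
  k = 5 states), the forward/backward recursions can run state-by-state
  and a full sweep costs the same order as one Baum-Welch iteration.
* **Dynamic Model Surgery (DMS)** — on-line structural correction during
  training: positions whose expected deletion usage exceeds a threshold
  ξ in enough sequences are removed, positions attracting insertions gain
  a neutral neighbour, and ξ escalates whenever the structural history
  cycles, so the search silences itself once the data stop supporting
  changes.

Around the trainers the package provides the full working environment:
a simulation harness (truth profiles at a stated conservation level,
sequence sampling with true alignments, random starting profiles,
composition-preserving shuffles), local-mode Viterbi hit search with
shuffle-calibrated score thresholds, a transitive-alignment metric that
scores hits found on two genomes against each other through a
genome–genome fragment map, and readers/writers for FASTA, a profile
serialization format, hit tables, fragment maps and an HMMer-2-style
export.

## A worked example

```r
library(plan7)

truth <- sampleTrueProfile(50, conservation = .7, seed = 1)
train <- sampleSequences(truth$model, 50, seed = 2)
start <- randomStartProfile(50, "simulation", seed = 3)

plain <- cbwTrain(start, train, maxIterations = 500)
surg  <- trainProfile(start, train,
                      trainingConfig("CBW", useDMS = TRUE,
                                     maxIterations = 500))

tail(plain$trace$loglik, 1)   # -2696.36  (plain CBW, stuck slightly shifted)
tail(surg$trace$loglik, 1)    # -2675.57  (CBW+DMS, higher optimum)
modelLength(surg$model)       # 50        (truth length kept)
```

The traces hold one row per iteration (log-likelihood, penalized
log-posterior, parameter distance, model length, surgery actions, current
ξ), so the structural search is fully inspectable; `writeTrace()` /
`readTrace()` round-trip them through disk.

A thin command-line front end over the same functions lives at
`inst/cli/plan7.R` (subcommands `simulate`, `train`, `scan`,
`transitive`, `report`).

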