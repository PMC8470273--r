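---
title: "Models and methods for karyotype evolution in Helicoidea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for karyotype evolution in Helicoidea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyevol)
```

## The scientific problem

Helicoid land snails show striking karyotype diversity — diploid numbers
from 2n = 40 to 2n = 62 and complements ranging from all-metacentric to
largely telocentric — yet the published chromosome data are scattered
across decades of literature with heterogeneous conventions. This package
formalises the comparative analysis of such data: it measures and
classifies chromosomes, counts the minimal rearrangement events separating
two karyotypes, and reconstructs ancestral diploid numbers on a phylogeny.

The three event types modelled are the ones that dominate chromosome
evolution in this group:

* a **translocation** (tandem or Robertsonian fusion) merges two
  chromosomes: 2n decreases by 2;
* a **fission** splits one chromosome: 2n increases by 2 and, in the
  Robertsonian expectation, a biarmed pair yields two telocentric pairs;
* a **pericentric inversion** moves the centromere: 2n is unchanged and
  exactly one pair changes morphology class.

Reciprocal translocations that conserve 2n are deliberately *not*
modelled: every chromosome-number comparison in the underlying data is a
multiple of two chromosomes, so the |Δ2n| / 2 calculus is the natural
currency, and a 2n-conserving exchange is invisible to it.

## Measurement and classification

`compute_measurements()` implements the two standard per-pair statistics.
With short and long arm lengths $s_i \le l_i$:

$$\mathrm{RL}_i = 100\,\frac{s_i + l_i}{\sum_j (s_j + l_j)}, \qquad
  \mathrm{CI}_i = 100\,\frac{s_i}{s_i + l_i}.$$

RL sums to 100 over the haploid complement (an invariant the tests check
to $10^{-9}$); CI lies in $[0, 50]$ because arms are ordered. Both are
stored at full precision and rounded to one decimal only for display,
matching how cytogenetics tables are usually printed.

Classification follows the Levan convention as a step function on CI with
boundaries at 37.5, 25 and 12.5 (m, sm, st, t from metacentric down). The
literature this data model mirrors cites the convention without printing
thresholds, so the boundary policy had to be fixed here: a pair exactly on
37.5 is called metacentric, and each lower boundary belongs to its own
interval (25 → sm, 12.5 → st). Monotonicity — a higher CI is never
assigned a less metacentric class — is a tested property.

Measurement tables in the wild list arms in either order, so inputs with
`short > long` are swapped with a warning rather than rejected; a negative
length or an empty table is an error. Haploid complements (karyotype
formulae are per-pair counts) normalise directly; a diploid chromosome
list must contain an even count per class or is rejected.

## The event calculus

`count_translocations_fissions(a, b)` returns |2n_a − 2n_b| / 2 events in
the direction a → b: all translocations when the number falls, all
fissions when it rises, never both. It is additive along monotone chains
of diploid numbers and is a lower bound on the true number of
number-changing events along any evolutionary path — both tested
properties, the latter against simulated histories.

`inversion_distance(a, b)` applies to formulae with equal pair number.
Because one inversion re-classifies exactly one pair (a pericentric
inversion can traverse class boundaries in one step), the minimal count is
the number of pairs that must change class:

$$d_I(a, b) = \tfrac12 \sum_{c \in \{m, sm, st, t\}} |a_c - b_c|.$$

This is a metric for each fixed pair number; the test suite verifies
identity, symmetry and the triangle inequality exhaustively for all
formulae with up to six pairs (84 formulae at n = 6, every waypoint
checked).

One published comparison is knowingly not reproduced: the three-inversion
claim for *Trochoidea pyramidata* (20m+4sm) → *T. trochoides*
(16m+7sm+1t). Half-L1 gives 4 (four pairs change class), and no
one-pair-per-event sequence can do it in three. The value is carried in
the fixture's notes; the implementation does not special-case it.

`combined_event_path()` makes comparisons across different pair numbers
explicit: first the |Δ2n| / 2 merges (each consuming two pairs and
producing one pair of a configurable class, default metacentric) or
fissions (one biarmed pair → two telocentric pairs, also configurable),
then the inversions needed to finish. Each merge greedily picks the pair
of classes whose removal keeps the intermediate closest (L1) to the
target, preferring telocentrics on ties — the classical Robertsonian
picture. The returned path always replays exactly onto the target (a
tested invariant over hundreds of random pairs); it is a concrete
certificate, not a claimed global minimum. A fission path from a
complement with too few biarmed pairs is reported as an error naming the
blocking classes, because fissions only create telocentrics.

## Ancestral reconstruction

`sankoff_reconstruct()` is a standard Sankoff dynamic program over a
finite state grid, chosen here as the even diploid numbers 40–64: every
reported helicoid state falls inside, and the grid is configurable
(`cost_model(state_range = ...)`). The cost of a branch from parent state
$a$ to child state $b$ is $w_T (a-b)/2$ for a drop and $w_F (b-a)/2$ for a
rise, with $w_T = w_F = 1$ by default — one event per step of two
chromosomes, which is exactly the currency of the printed event counts.
Asymmetric weights let users penalise fissions (rarer in this group) more
heavily.

Implementation notes:

* Polytomies are first-class: the upward pass sums child contributions,
  however many there are, and results are invariant to child order (tested).
* A downward pass computes, for every node and state, the cost of the rest
  of the tree, so the reported per-node sets contain exactly the states
  attainable in *some* globally optimal labeling. Ties are reported as
  sets; nothing is broken silently.
* `annotate_branch_events()` extracts one optimal labeling for display:
  `prefer-ancestral-max` (default) resolves every tie toward the higher
  diploid number, `prefer-ancestral-min` toward the lower, and
  `all-optimal` blanks any branch whose count is not pinned down
  (conservatively: any upstream tie marks the branch `NA`). Under either
  concrete policy the branch counts sum exactly to the total cost.
* Tips without data are pruned with a warning; a tip state off the grid is
  an error; a tie at the root is reported, never resolved by fiat.
* `brute_force_reconstruct()` enumerates all internal labelings (refusing
  more than 8 internal nodes) and is the independent oracle: the suite
  compares total costs and per-node sets on 200 random instances with up
  to 5 tips, under symmetric and asymmetric weights.

On the curated tree the root set is uniquely {60}, the branch into the
Hygromiidae + Geomitridae ancestor carries 4 translocations, and the
single fission (Camaenidae ancestor 58 → *Cathaica fasciola* 60) appears
under the tie policy that biases ancestors low. The total cost (44 events)
is lower than a tally of the narrative lineage-by-lineage counts would
suggest, because the optimiser may place some ancestors differently than a
hand reconstruction — e.g. it prefers lifting the Polygyridae ancestor
toward the three 2n = 62 genera once each is represented by a single
lineage. The root inference is insensitive to this (and to collapsing the
uncertainty-flagged branches into polytomies, a tested sensitivity).

## The curated dataset

`paper_fixtures()` returns two layers of records plus the tree:

* the sixteen newly karyotyped records (fifteen species; *Theba pisana*
  from two localities) with diploid numbers, formulae where a formula was
  printed, and NOR-pair annotations (one pair in *Cernuella virgata* —
  the ancestral condition in mollusks — three in *Otala lactea*, four in
  *Cornu apertus*);
* literature and clade-level records (tribe or subfamily rows such as
  Hygromiini 2n = 42) that the family-level tree maps onto.

Conflicts are stored, not resolved: *Cochlicella acuta* is 2n = 52 here
against 2n = 46 in earlier literature (a candidate cryptic-lineage split,
flagged in `notes`); the two *Monacha* counts (44 in the summary table,
46 in the karyotype description) are both carried and the species is kept
out of the tree rather than guessing. Where a species' prose description
and its printed comparative formula disagree on class counts (all three
*Trochoidea*), the printed formula is used for distance computations and
the description-derived alternative is noted.

The tree transcribes only clades named in the comparative analysis;
unresolved structure is left as polytomies, and two tentatively placed
deep branches carry `[&uncertain]` flags that `collapse_uncertain()` can
dissolve for sensitivity analysis. NOR and heterochromatin observations
are annotations only — no computation consumes them, mirroring their
descriptive role.

## The simulator and what passing tests show

`evolve_karyotypes()` draws, per branch, independent Poisson numbers of
translocations, fissions and inversions (rate × branch length each) and
applies them in random order; a translocation merges two uniformly chosen
pairs into a metacentric, a fission splits a uniformly chosen biarmed pair
into two telocentrics, an inversion moves a uniformly chosen pair to a
uniformly chosen different class. Events that would cross the diploid
bounds (default 40–64) or need an unavailable class are dropped and
counted; the event log replays bit-exactly from the seed. Discrete
per-branch Poisson counts — rather than a continuous-time chain — are the
minimal stochastic model matching how the comparative argument itself
reasons, in whole events per lineage.

Default rates are 0.25 translocations, 0.05 fissions and 0.15 inversions
per unit branch length: translocations dominant, fissions rare, inversions
in between, mirroring the inferred relative frequencies. Random trees are
pure-birth (Yule) with edge lengths rescaled to unit mean, so a rate is
also the expected event count on an average branch.

`recovery_experiment()` quantifies when parsimony can be trusted: the
fraction of replicates whose true root state lies in the inferred root
set, the error of the inferred event total against the true count of
number-changing events, and the tie frequency. Two calibration facts,
measured once with seed 2021 and 200 replicates on 8-tip trees and then
frozen:

* at ~0.3 expected events per branch, recovery is ≈ 0.85 (and ≈ 0.7 if
  the 0.3 is all translocations and fissions) — loss-dominated histories
  drag the parsimony root below the truth;
* at the package's headline low-rate setting (0.10 / 0.02 / 0.06 per unit
  branch, ≈ 0.18 events per branch) recovery is 0.95, and the acceptance
  suite asserts ≥ 0.9 there.

Parsimony's total cost is a lower bound on the true simulated event count
in 100% of replicates at every setting tried — inversions are invisible to
the diploid-number character, and parsimony never overcounts the visible
ones.

What the simulator does *not* emulate: chromosome-level identity (it
tracks class counts, not gene content or synteny), rate variation across
lineages, any dependence of rates on the current karyotype, and
measurement noise in RL/CI. Passing recovery tests therefore show that the
inference machinery is correct and well-behaved under the stated model —
not that real helicoid karyotype evolution satisfies that model.

## Numerical and interface choices

* All event counts are exact integer arithmetic; the only tolerances in
  the package are $10^{-9}$ slack when collecting minimal-cost states
  (guarding floating-point summation of costs) and the RL-sum check.
* Problem sizes in the test suite are chosen to keep the full run around
  half a minute: oracle equivalence at ≤ 5 tips × 200 instances,
  exhaustive metric checks at n ≤ 6, recovery at 200 replicates × 8 tips,
  Poisson calibration at 500 replicates × 4 tips.
* The formula grammar accepts `+`, comma or whitespace separators and
  optional space before the class symbol, because the printed sources mix
  `1st` and `1 t` styles; the canonical output form is
  `<k>m+<k>sm+<k>st+<k>t` with zero classes omitted.
* The CLI returns 0 on success, 2 on validation failure and 3 on I/O
  failure, writes machine-readable JSON beside every human-readable
  report, and refuses to overwrite outputs without `--force`.

## Known limitations

* The rearrangement calculus operates on morphology-class multisets; it
  cannot see gene-order rearrangements, reciprocal translocations, or
  heterochromatin changes, and its counts are lower bounds by design.
* Sankoff parsimony needs a finite state grid and has no notion of branch
  lengths or rates; for rate estimation or probabilistic ancestral states
  a likelihood model of chromosome-number evolution would be the next
  step, out of scope here.
* The curated tree is a family-level transcription with polytomies; it is
  suitable for the superfamily-level question it was built for, not for
  fine within-genus inference.
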