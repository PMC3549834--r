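---
title: "Determining disulfide bond topology by evidence fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining disulfide bond topology by evidence fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsfusion)
```

## The problem

A protein with $n$ cysteines can form disulfide (S-S) cross-links between
pairs of them; the set of bonds is a matching on the cysteines (no residue
participates twice). Several families of methods estimate this topology —
tandem mass spectrometry of proteolytic digests, supervised sequence
classifiers, nearest-neighbour transfer from annotated homologues — and on
real proteins they routinely disagree: each reports a set of candidate
bonds $(C_i, C_j)$ with a confidence $\sigma_k(i,j) \in [0,1]$, and the
sets may be consonant, partially overlapping, or entirely disjoint.

`dsfusion` treats this as an evidence-combination problem in the
Dempster–Shafer sense. It does not need the sources' error distributions,
it quantifies how much they conflict, it is symmetric in the order the
sources arrive, and external knowledge about a source's reliability enters
through an explicit discounting step.

## Frames, mass functions, belief and plausibility

The *frame of discernment* $\theta$ is the set of primitive hypotheses —
candidate bonds. Two modes are supported: the default **union** frame
(all bonds reported by at least one method; this is what the worked case
studies use) and an **all-pairs** frame of every $n(n-1)/2$ cysteine pair,
capped in practice by the subset-cardinality limit below.

A *basic belief assignment* (mass function) $m$ distributes unit belief
over subsets of $\theta$ plus the *environment* $\Theta$ (the universal
set, holding unassigned belief, i.e. ignorance):
$m(\emptyset) = 0$, $m(A) \ge 0$, and $\sum_A m(A) = 1$ with the
environment included in the sum. From $m$, two evidential functions are
derived for a decision set $A$: the belief
$\beta(A) = \sum_{B \subseteq A} m(B)$ and the plausibility
$P(A) = \sum_{B \cap A \ne \emptyset} m(B)$ (the environment intersects
every non-empty $A$). The interval $[\beta(A), P(A)]$ brackets the
support for $A$; `belief_of()` and `plausibility_of()` compute both, and a
property test confirms $\beta \le P$ universally.

Subsets whose bonds share a cysteine are chemically impossible, so they
are *inconsistent* and carry mass zero by construction;
`enumerate_consistent_subsets()` materializes only the consistent ones,
verified against a brute-force power-set filter in the tests.

## From per-bond scores to a mass function

Each method reports per-bond scores, not subset masses. The assignment
function implemented in `assign_masses()` scores a consistent subset $j$
with member scores $\sigma_1 \dots \sigma_k$ as

$$m(j) = \max\!\Big(\tfrac{1}{k}\sum_{i=1}^{k}(2\sigma_i + \gamma - 1),\; 0\Big),
\qquad
\gamma = \begin{cases}
-\sum_i \sigma_i / 2k & \text{if any } \sigma_i = 0\\
\phantom{-}\sum_i \sigma_i / 4k & \text{otherwise,}
\end{cases}$$

where a bond of the frame that the method did not report enters with
$\sigma = 0$. The design intent: extreme scores (zero, or near one) move
the subset mass strongly, middling scores barely at all. Three
consequences worth knowing:

* a singleton with $\sigma > 0.5$ has raw mass $2.25\sigma - 1$,
  strictly increasing in $\sigma$;
* a subset containing any unreported bond is penalized through the
  negative branch of $\gamma$ and almost always clamps to zero;
* sources whose scores are all middling (for instance a profile-transfer
  method reporting $\sigma \approx 0.2$ for every bond) produce a
  *vacuous* mass function — all mass on the environment. This is
  deliberate: such a source contributes ignorance, not support, and the
  discounting step (below) is the mechanism that would rehabilitate it.

The raw subset scores are then normalized. The function above is not a
probability assignment, so two cases arise: if the raw scores total more
than one they are scaled to sum to one (environment mass zero); if they
total less, the deficit is assigned to the environment. This
reconstructs the published worked example exactly (MS scores 0.80/0.81
give normalized masses 0.33/0.34 for the singletons and 0.33 for the
two-bond subset).

When the branch condition of $\gamma$ is mixed (some members zero, some
positive), the negative branch is used: the presence of any unreported
bond is treated as the dominant signal.

## Combination rules

All four rules consume one mass function per source and are computed in
their simultaneous n-ary form — products of one focal element per source
accruing to the intersection of the tuple — rather than by pairwise
iteration. For the Dempster and Campos rules the two forms agree
(associativity, covered by a test); the Yager rule is *not* associative,
and only its n-ary form reproduces the intended behaviour of sending all
pairwise-conflicting product mass to the environment in one step.

* **Dempster** (`combine_dempster()`): discard conflicting product mass
  $k$ and renormalize by $1-k$. The *weight of conflict* is
  $\log(1/(1-k))$ (natural log; the magnitudes involved are $O(1)$ and
  no base is dictated by convention). Total conflict ($k = 1$) raises an
  explicit error — no silent fallback. The rule's well-known pathology
  is preserved and tested: two sources confident in disjoint bonds but
  sharing one low-confidence bond fuse to certainty in that shared bond.
* **Yager** (`combine_yager()`): identical products, no renormalization;
  conflict mass joins the environment as ignorance. Total conflict is
  representable (environment mass one, no bond supported).
* **Campos** (`combine_campos()`): the Dempster result de-rated by
  $1 + \log(1/(1-k))$, with the deficit assigned to the environment —
  conflict reduces commitment rather than being renormalized away.
* **Shafer** (`combine_shafer()`): each source is first discounted by a
  reliability $\alpha_i \in [0,1]$ (focal masses scaled by $\alpha_i$,
  the complement moved to the environment), then sources are averaged
  focal set by focal set. The plain arithmetic mean is used for any
  number of sources; a weighted mean would double-count reliability,
  which is already expressed through $\alpha$.

Discounting applies *only* inside the Shafer rule; Dempster, Yager and
Campos consume undiscounted masses. Per-bond results are read out with
`bond_scores()` as the containment sum — total fused mass of focal sets
containing the bond — with singleton belief available separately via
`belief_of()`.

Intersection of focal sets is plain set intersection on bonds. Two
different bonds sharing a cysteine intersect to the empty set, i.e. they
conflict, which is the combination-level counterpart of the
inconsistency rule above.

## Source reliability (discounting)

Reliability weights $\alpha$ are computed per source:

* **MS** (`discount_ms()`): start at 1; subtract `alpha_mass` = 0.1 if
  the precursor ion mass exceeds `T_mass` = 4000 Da (large ions fragment
  poorly), subtract `alpha_pp` = 0.2 if the abundance-significance score
  pp2 falls below `T_pp` = 50 (the confirmed matches could be
  low-abundance noise). Decrements are subtractive, floored at zero.
* **SVM** (`discount_svm()`): the weight starts at the belief itself;
  mid-range beliefs (0.5, 0.9) are divided by 1.5, beliefs at or below
  0.5 by 3. Boundary conventions (unstated in the source material and
  fixed here): belief exactly 0.9 keeps its full value, exactly 0.5
  falls in the lowest band. No further renormalization is applied after
  the division.
* **CSP** (`discount_csp()`): start at 1; a profile divergence $D > 10$
  costs $D/100$; fewer than two reference entries tied at the minimal
  divergence costs another 0.1 (a unique nearest neighbour lacks
  corroboration). $D$ exactly 10 incurs no penalty.

## The constituent predictors

**Cysteine separation profiles** (`compute_profile()`,
`predict_topology()`). The profile of a protein is the vector of gaps
between consecutive cysteine positions; similar bonding patterns imply
similar folds and hence similar profiles. A query is compared by L1
divergence $D$ against every reference entry with the same profile
length (unequal lengths are incomparable rather than padded — the
distance is undefined otherwise); the nearest entry's topology is
transferred by cysteine ordinal, each bond carrying belief
$(1 + \log_{10}(1 + D/10))^{-2}$. Ties at minimal $D$ resolve to the
first entry in database order, with the tie count surfaced to
`discount_csp()`. The query profile uses *all* cysteines, since
oxidation state is unknown before prediction. The package ships a small
synthetic reference database as a stand-in for a curated collection of
annotated topologies.

**Sequence classification** (`encode_pair()`, `predict_pairs()`). Each
cysteine pair is encoded as 521 features: two 13-residue windows
centered on the cysteines (6 either side — the window includes the
central residue, a convention fixed here), one-hot over the 20 standard
amino acids with out-of-sequence and non-standard positions as zero
blocks, plus the raw residue separation. The classifier is a pluggable
margin function (positive margin = bonded, a sign convention fixed
here); `train_reference_classifier()` provides an RBF-kernel SVM
reference implementation. Margins become beliefs through the sigmoid
$1/(1 + e^{Af+B})$ with $A < 0$; `fit_platt()` estimates $A, B$ by
regularized maximum likelihood (softened targets, Newton iterations,
tolerance $10^{-6}$, at most 100 iterations), and a test confirms
parameter recovery from $10^4$ synthetic margins.

**MS/MS scoring** (`ms_score_spectra()` and parts). Candidate
disulfide-bonded peptide pairs are enumerated from a tryptic or
chymotryptic digest (intra-peptide bonds included; linked mass = peptide
masses minus two hydrogens). The candidate mass list is trimmed
subset-sum style: a greedy scan keeps a mass only if it exceeds
$(1+\varepsilon)$ times the last kept one, guaranteeing every removed
mass a kept representative within relative $\varepsilon$ (default
$10^{-4}$, configurable — small enough to prune only duplicates at
typical mass spacings). Spectra select candidates within the precursor
tolerance (default 1.0 Da). Theoretical fragments cover twelve ion types
(a, b, y with water/ammonia losses, c, x, z), singly charged and
monoisotopic; fragments retaining a bonded cysteine carry the intact
partner peptide, and intra-peptide candidates omit fragments that would
sever the ring. Matching uses a 0.5 Da tolerance and ignores peaks below
10% of the maximum intensity (both configurable). Three scores result:
the intensity-weighted matched fraction VS on a 0–100 scale; the
binomial-tail significance pp of the match count, with per-fragment
random-match probability $p_2 = 2m \cdot \mathrm{VM_{TH}} / r$ read with
$m$ = the number of theoretical fragments (the only reading under which
$p_2$ is a probability); and the Gaussian-tail significance pp2 of the
matched abundance, with the peak-intensity mean and s.d. estimated from
the spectrum itself. Both tail scores use $-\log_{10}$, consistent with
threshold magnitudes like $T_{pp} = 50$.

The per-bond belief exported for fusion is $\min(pp/100, 1)$ — a
reporting convention, exposed as `pp_max`, not a derived quantity. The
globally consistent topology is the maximum-weight matching over the
*raw* pp scores (`global_topology()`, exact branch-and-bound,
lexicographic tie-break): using the capped belief would erase the margin
between a true bond and a decoy built from the same peptide pair.

## The synthetic-evidence generator

`generate()` draws proteins with an even number of cysteines (4–10),
plants a random perfect matching as the true topology, and simulates
three methods: planted bonds are reported with beliefs
$\mathcal{N}(0.85, 0.05)$ (clamped to $[0.01, 0.99]$) unless dropped out
(probability 0.1 per method), and conflicting decoys sharing a cysteine
with a true bond are added at rate 0.1 with beliefs
$\mathcal{N}(0.2, 0.05)$. These defaults mirror the spread between
confident true bonds and weak false positives seen in the fused-belief
tables of real studies. Sequences place a tryptic site after every
cysteine so each falls in its own peptide — inter-peptide linked pairs
are the regime MS/MS can actually localize; a bond between two cysteines
of the *same* peptide with no distinguishing fragments is physically
ambiguous, and the generator does not manufacture such undecidable
cases. `synth_spectra()` emits spectra whose peaks are the planted
pairs' theoretical fragments plus optional uniform noise peaks.

What the generator does *not* emulate: isotope envelopes, multiple
charge states, instrument-specific noise and intensity distributions,
homology structure between proteins, and correlated errors between
methods. Passing the planted-recovery tests therefore demonstrates that
the fusion and scoring machinery is correct under its stated model, not
that the method attains any particular accuracy on real spectra.

All generation is a pure function of (configuration, seed); the tests
assert byte-identical output across repeated runs.

## Numerical and design notes

* Residue numbering is 1-based everywhere; bonds are canonical
  `"a-b"` keys with $a < b$.
* Beliefs are carried at full precision; rounding to two decimals
  happens only at report time.
* Masses are monoisotopic; fragment masses use standard residue masses
  and the proton/water/CO/NH$_3$ constants.
* Unit-sum checks on mass functions use a $10^{-9}$ tolerance.
* The consistent-subset enumeration is capped at cardinality 4 by
  default (the most simultaneous bonds the worked analyses consider);
  the cap bounds the $2^{|\theta|}$ growth of the all-pairs frame.
* Equal-weight matchings resolve to the lexicographically first bond
  set; zero-score bonds never enter a matching.
* In one published worked example the printed per-subset values for a
  middling-belief source (scores around 0.21) are small positive
  numbers, whereas the assignment function as defined yields zero and a
  vacuous source; this package follows the function. Likewise the
  printed singleton masses there are swapped relative to the
  monotonicity of the assignment function (0.34 against the higher
  input score, 0.33 against the lower); the implementation keeps the
  monotonic assignment, which leaves the two-bond subset value
  unchanged. Finally, the per-bond values printed for the
  Dempster/Campos/Shafer rules after combining all three sources in
  that example depend on an aggregation not fully determined by the
  printed intermediates (under the stated pipeline the three sources
  are near-totally conflicting); the package reports the
  containment-sum beliefs its own pipeline computes.

## Problem sizes used in the test suite

The property tests run on deliberately small instances where exhaustive
oracles are feasible: combination rules are checked against full tuple
enumeration on up to 3 sources with up to 4 focal sets each; subset
enumeration against the full power set for frames of up to 6 bonds;
matchings against brute force for up to 8 cysteines; fusion-based
planted recovery on 50–100 proteins; spectral recovery on a handful of
proteins with 4–6 cysteines. These sizes exercise every code path while
keeping the whole suite under a minute.

## Limitations

* Fragment generation covers singly charged ions only; internal ions,
  higher charge states and isotope envelopes are out of scope.
* The shipped CSP database is a synthetic fixture; real use requires a
  curated reference collection.
* The SVM module ships an encoder, calibrator and reference trainer,
  not a trained production model.
* Specificity-family metrics need the full cysteine list to define the
  negative pair universe; from bond lists alone only sensitivity-family
  counts are available (`detection_counts()`).
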