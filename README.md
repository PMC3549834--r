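# dsfusion

Determination of protein disulfide (S-S) bond topology by fusing
bond-level evidence from heterogeneous predictors under an extended
Dempster-Shafer framework.

## The problem

A protein's disulfide bonds form a matching on its cysteines. The methods
used to find them — tandem-MS fragment matching, SVM sequence
classification, cysteine-separation-profile (CSP) transfer from annotated
homologues — each report candidate bonds (C_i, C_j) with confidences
σ_k(i, j) ∈ [0, 1], and on real proteins they concur in parts and
conflict in others. `dsfusion` combines them without assuming anything
about their error distributions.

The machinery, in Dempster-Shafer terms:

* a **frame of discernment** θ of candidate bonds (union of reported
  bonds, or all n(n−1)/2 pairs);
* a **mass function** m over consistent subsets of θ (bond sets sharing a
  cysteine are impossible and get zero mass) plus the environment Θ
  (ignorance), built from per-bond scores by
  `m(j) = max(mean_i(2σ_i + γ − 1), 0)` with γ = −Σσ/2k if any member is
  unreported, +Σσ/4k otherwise, then sum-normalized;
* **belief** ß(A) = Σ_{B⊆A} m(B) and **plausibility**
  Ƥ(A) = Σ_{B∩A≠∅} m(B) bracketing the support for any decision;
* four **combination rules** — Dempster (renormalizes conflict away),
  Yager (conflict becomes ignorance), Campos (de-rates by the weight of
  conflict log(1/(1−k))), and Shafer (discount each source by a
  reliability α_i, then average);
* **discounting** of source reliability: data-driven for MS (precursor
  mass > 4000 Da and pp2 < 50 thresholds), empirical rules for SVM and
  CSP;
* a final **maximum-weight matching** turning per-bond beliefs into a
  globally consistent topology.

The constituent predictors are implemented too: CSP profile matching with
divergence-based beliefs `(1 + log10(1 + D/10))^-2`; a 521-feature
local-environment encoder with Platt-calibrated margins
`1/(1 + exp(A·f + B))`; and MS/MS scoring with a twelve-ion-type
fragment model, subset-sum search-space trimming, intensity-weighted
match scores, and binomial/Gaussian tail significances (pp, pp2).

## Worked example

The packaged case study is beta-1,4-galactosyltransferase (P08037), whose
true topology is {134-176, 247-266}. Three methods disagree: MS supports
the true bonds (0.80/0.81), CSP supports them weakly (0.21), and the SVM
confidently asserts an incompatible bond 134-247 (0.96).

```r
library(dsfusion)
cs <- load_case_study()
fused <- fuse_topology(cs, rule = "shafer")
round(fused$scores, 3)
#> 134-176 134-247 247-266
#>   0.221   0.333   0.224
fused$topology
#> <ss_topology> 134-176  247-266
```

The fused per-bond beliefs still rank the SVM's wrong bond highest in
isolation (0.333), but the maximum-weight matching prefers the two
compatible true bonds (total 0.445) — the fusion recovers the correct
topology with no prior knowledge of which method to trust. The Yager
rule on the same input pushes all conflicting mass into ignorance and
leaves every bond below 0.01:

```r
max(fuse_evidence(cs, rule = "yager")$scores)
#> [1] 0
```

Other entry points: `read_fasta()` / `read_evidence_table()` for I/O,
`predict_topology()` (CSP), `predict_pairs()` (SVM),
`ms_score_spectra()` (spectra → evidence), `generate()` /
`synth_spectra()` (seeded synthetic data), `confusion()` / `metrics()` /
`macro_metrics()` (evaluation), and the `exec/ssfuse` command-line
wrapper (`fuse`, `csp`, `eval`, `simulate` subcommands).

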