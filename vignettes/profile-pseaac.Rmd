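---
title: "Profile-based PseAAC for DNA-binding protein prediction: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile-based PseAAC: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(propseaac)
```

## The problem

DNA-binding proteins — transcription factors, polymerase subunits, repair
enzymes, histones — are central to gene regulation and genome maintenance,
and annotating a protein as DNA-binding from sequence alone is a
long-standing classification task. Structure-based predictors need solved
or modeled structures; sequence-based predictors must instead find a
representation of the amino-acid sequence that preserves both its
composition and some of its order and evolutionary context, in a
fixed-length vector a standard classifier can consume.

`propseaac` implements one such representation and the machinery around
it: a per-protein evolutionary profile is collapsed to a consensus
sequence, the consensus is converted to a pseudo amino acid composition
(PseAAC) vector, and an RBF-kernel support vector machine does the
classification. Leave-one-out evaluation, discriminant-weight analysis
and a negative-subset ensemble complete the toolkit.

## The model, step by step

### Frequency profiles and pseudo-counts

A frequency profile for a protein of length $L$ is an $L \times 20$
row-stochastic matrix: row $j$ is a probability distribution over the 20
standard amino acids at position $j$, estimated from the protein's
homologs. Two routes produce one:

* **Parsed**: PSI-BLAST's ASCII matrix output contains, per position, 20
  integer log-odds and 20 weighted observed percentages.
  `read_psiblast_pssm()` uses the percentage block — the closest printed
  analogue of per-position target frequencies — divides by 100 and
  renormalizes each row. Rows that are all zero (PSI-BLAST emits these
  where a position has no alignment evidence) become one-hot on the query
  residue, the natural no-information fallback. Whether the percentages
  should be renormalized at all is a judgment call (they usually sum to
  99–101 after rounding); we renormalize so every downstream invariant is
  exact.
* **Computed**: from a user-supplied multiple alignment,
  `observed_profile()` counts standard residues per column (gaps and
  ambiguity codes excluded), and `apply_pseudocounts()` blends the
  observed frequencies with substitution-implied expectations,
  $$g_{ij} = \sum_k \frac{f_{kj}}{p_k}\, q_{ik}, \qquad
    m_{ij} = \frac{\alpha_j f_{ij} + \beta g_{ij}}{\alpha_j + \beta},$$
  with $p$ the background frequencies, $q$ the joint pair frequencies,
  $\beta = 10$ (the PSI-BLAST convention), and $\alpha_j$ the number of
  *distinct* residues observed in column $j$ minus one — the
  independent-observations count, so a perfectly conserved column
  ($\alpha_j = 0$) is fully replaced by its pseudo-counts and sparse
  columns are strongly regularized, while deep diverse columns stay close
  to their observed frequencies. Because the row marginals of $q$ equal
  $p$, each pseudo-count column sums to one and row-stochasticity is
  preserved exactly.

**The substitution model.** $q$ must be a joint pair-frequency matrix,
not the integer log-odds score matrix — only the frequency reading makes
$g_{\cdot j}$ a probability vector. The packaged default is derived from
BLOSUM62: starting from $q^{(0)}_{ik} = p_i p_k 2^{s_{ik}/2}$ (inverting
the half-bit log-odds definition) we apply symmetric iterative
proportional fitting until the row marginals equal the background to
machine precision. This removes the distortion that integer rounding of
the scores introduced, and makes the row-stochasticity of pseudo-counted
profiles exact rather than approximate. Any other model can be supplied
through `substitution_model()`.

### The consensus sequence

`consensus_sequence()` takes each profile row's most frequent residue,
producing the consensus string $P'$ whose residues reflect evolutionary
preference rather than the observed sequence. Ties are broken toward the
earlier residue in the canonical ordering — the alphabetical single-letter
order `r paste(aa_alphabet(), collapse = " ")`, which is also the column
order of every matrix and feature vector in the package. Determinism here
matters more than the (arbitrary) choice itself: profiles built by
different routes must yield identical consensus strings.

Ambiguity codes (B, Z, X, U, O) and gaps are tolerated on input but never
enter the 20-dimensional arithmetic: they are excluded from column counts
and can never appear in $P'$.

### PseAAC featurization

Seven physicochemical property scales — hydrophobicity, hydrophilicity,
side-chain mass, pK1 (α-carboxyl), pK2 (α-amino), isoelectric point, and
mean accessible surface area — are standardized per property to mean 0
and **population** (divide-by-$n$) standard deviation 1 over the 20
residues; that is the convention of the PseAAC literature, and a test
pins it so switching to the sample convention is a one-line change.
Z-scoring makes every downstream feature invariant to affine rescaling of
any raw property row, so the scales' original units are irrelevant.

The packaged raw values are drawn from the standard compilations cited in
the source comments. They are deliberately easy to replace
(`read_property_table()` accepts a 7 × 21 TSV) because published variants
of these seven scales differ in minor ways; all structural properties of
the features (nonnegativity, normalization, symmetry of the pair
dissimilarity) hold for any non-constant table.

Residue-pair dissimilarity is
$\Theta(a, b) = \tfrac{1}{7}\sum_j (H_j(a) - H_j(b))^2$, and the
sequence-order correlation factors of $P'$ are
$$\theta_k = \frac{1}{L-k} \sum_{i=1}^{L-k} \Theta(P'_i,\, P'_{i+k}),
  \qquad k = 1, \dots, \lambda.$$
The feature vector appends the weighted factors to the consensus residue
frequencies $f_u$ and normalizes:
$$x_u = \frac{f_u}{\sum_v f_v + \omega \sum_k \theta_k} \;(u \le 20),
  \qquad
  x_{20+k} = \frac{\omega\, \theta_k}{\sum_v f_v + \omega \sum_k \theta_k}.$$
Every vector is nonnegative and sums to one; at the default
$\lambda = 3$ it has 23 entries.

$\lambda$ is applied strictly per sequence: a sequence with $L \le
\lambda$ has undefined $\theta_\lambda$ and is rejected (or dropped under
`permissive = TRUE`), never zero-padded. In practice this is no
constraint — benchmark datasets exclude fragments under 50 residues.

### Tunable parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| $\lambda$ | order-correlation depth (features $20+\lambda$) | 3 | jackknife optimum of the published parameter sweep; `run_paramscan()` reproduces the sweep |
| $\omega$ | weight of the order factors, $(0, 1]$ | 0.7 | same sweep |
| $\beta$ | pseudo-count weight | 10 | PSI-BLAST convention |
| $C$ | SVM soft-margin penalty | 8192 ($2^{13}$) | grid-search optimum; inside the default grid $2^{-5..15}$ |
| $\gamma$ | RBF width in $e^{-\gamma\|x-y\|^2}$ | 8.0 ($2^{3}$) | grid-search optimum; inside the default grid $2^{-15..3}$ |
| $k$ | ensemble subsets | 4 | matches a ~4:1 negative:positive pool |

### Classifier, calibration, evaluation

Training uses libsvm (via e1071) with the kernel form
$K(x, y) = e^{-\gamma\|x-y\|^2}$ matching the $\gamma$ convention above,
and no feature scaling (PseAAC vectors are already commensurate, summing
to 1). The fitted object stores the support vectors, the signed dual
coefficients oriented so that a positive decision value means
DNA-binding, and the full training matrix. Decision values are recomputed
directly from these stored quantities — verified against the libsvm
output at training time — which is what makes the JSON model archive
(`write_model()`) complete: a restored model predicts bit-identically.

Class probabilities use a Platt-style sigmoid $P(+1 \mid f) =
\mathrm{logistic}(a + b f)$ fitted by logistic regression on the
*training* decision values. Libsvm's built-in calibration runs an
internal cross-validation whose shuffling is not controlled by R's RNG;
fitting on training decision values keeps every prediction a
deterministic function of the inputs. The calibrator is isolated in one
field, so a different scheme is a drop-in replacement. On separable
training sets the sigmoid saturates and probabilities approach 0/1 —
acceptable for ranking and averaging, which is all the pipeline uses them
for.

The jackknife (`jackknife()`) is exact leave-one-out: $N$ rounds, each
training on $N-1$ samples, confusion counts accumulated over the held-out
predictions, with Sn, Sp, Acc, MCC from their closed forms (an MCC
denominator of zero is defined as 0 with a warning) and the ROC built by
threshold sweep over the held-out decision values. AUC is computed as the
Mann–Whitney statistic with ties counted one half, so constant scores
give exactly 0.5. `counts_from_rates()` inverts printed
sensitivity/specificity tables back to integer confusion counts, accepting
either rounding or truncation at two decimals, and requiring uniqueness —
this is how published summary rows are recomputed exactly.

### Discriminant weights

$W_j = \sum_i A_i M_{ij}$ projects the signed dual coefficients through
the training features. For a linear kernel this *is* the primal weight
vector (a test asserts it reproduces the decision values); for the RBF
kernel it is a first-order summary of which features push toward which
class, and its sign structure is the interpretable output: composition
features with positive weight mark residues over-represented in
DNA-binding proteins (arginine and lysine, in both real data and the
synthetic fixtures).

### The negative-subset ensemble

Real screening pools contain far more non-binders than binders. Rather
than training one classifier on an imbalanced set,
`partition_negatives()` splits the negative pool by a seeded uniform
shuffle and round-robin slicing into $k$ subsets (sizes differing by at
most one, deterministic per seed), one model is trained per subset paired
with the shared positive set, and `predict_ensemble()` averages the
members' calibrated probabilities. The decision threshold on the averaged
probability is 0.5 — the calibrated default — with exact ties labeled
positive; the tie direction is arbitrary but documented and tested.

## The synthetic generator: what it does and does not emulate

`synthetic_spec()` describes the study conditions every end-to-end check
runs under; the generators are pure functions of the spec (seed
included), so any result is reproducible from its manifest.

* **Composition signal.** Positives are drawn with selected residues'
  background frequencies multiplied by an enrichment factor (default
  `c(R = 2.5, K = 2.5)`, echoing the arginine/lysine excess of real
  DNA-binding regions); negatives follow the background. This is the
  planted signal the pipeline must recover.
* **Profile noise.** Real profiles come from alignments; the generator
  instead smears each position's one-hot row with Dirichlet noise at
  concentration `profile_noise` (default 50, giving consensus sequences
  that mostly but not always match the source). As the concentration
  grows the profile tends to one-hot and the consensus recovers the
  sequence exactly; at concentration 1 the consensus is visibly
  corrupted. One knob, row-stochastic by construction.
* **Order correlation.** With `order_effect > 0`, consecutive residues of
  positive-class sequences are drawn with probability reweighted by
  $e^{-\text{order\_effect}\cdot\Theta(\text{prev}, a)}$, inducing
  nearest-neighbor property autocorrelation that the $\theta_k$ features
  can detect. The default is 0: the baseline fixtures carry a purely
  compositional signal.
* **Sizes.** Defaults are 30 + 30 sequences of length 50–200 — small
  enough that a full jackknife runs in under a second, large enough that
  the planted signal dominates sampling noise. The ensemble checks use a
  24-positive / 96-negative pool split 4 ways with a separate 40-sample
  test set.

What the generator does **not** emulate: realistic evolutionary profiles
(columns are independent; there is no phylogeny, no substitution-process
sampling, no alignment depth structure), domain architecture, length–class
correlations, or database-dependent PSI-BLAST behavior. Consequently,
passing the synthetic recovery checks demonstrates that the pipeline's
plumbing and mathematics are correct — features faithful to their
equations, classifier able to exploit a known signal, ensemble averaging
behaving as specified — not that any particular accuracy will be attained
on real proteomes. Published-scale accuracy additionally depends on the
profile database and the exact property table, which are inputs here.

## Numerical choices and degenerate inputs

* Row-stochasticity is enforced at 1e-9 on construction and restored by
  explicit renormalization after pseudo-counting and PSSM parsing.
* Consensus ties break to the canonical ordering (first maximum).
* Generated PSSM files write percentages by largest-remainder rounding so
  each row sums to exactly 100, keeping the parser round-trip within the
  1% quantization bound.
* Sequences shorter than $\lambda + 1$ are rejected with an error that
  names the offending ids (droppable under `permissive`).
* Alignment columns with no standard residue, empty FASTA records, and
  non-numeric PSSM cells are hard errors naming the location.
* Single-class training sets and holdouts that would empty a class are
  errors; grid-search folds are stratified by class to avoid degenerate
  folds.
* MCC with a zero denominator is defined as 0, with a warning.
* All randomness (fold assignment, partitioning, generators) flows from
  caller-supplied seeds through `withr::with_seed()`; nothing depends on
  the ambient RNG state.

## Limitations

* The discriminant weight vector is a linear summary of a nonlinear
  model; for the RBF kernel its magnitudes are heuristic (its signs are
  the interpretable part).
* Platt calibration on training decision values is optimistic on
  separable sets; probabilities near 0/1 should be read as rankings, not
  frequencies.
* The packaged property table is a standard-compilation stand-in and
  intentionally overridable; results are insensitive to affine changes of
  any scale but not to substituting a genuinely different property.
* Only the classic seven-property, squared-difference PseAAC variant is
  implemented (no amphiphilic or general-correlation forms).
* Running PSI-BLAST, building benchmark datasets, and homology-culling
  are out of scope: profiles and alignments are inputs.
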