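---
title: "Methods: population structure and heterotic-group analysis of inbred SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population structure and heterotic-group analysis of inbred SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(popstructr)
```

This vignette is the package's own account of its models and the choices
behind them. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The data model

The observable is a lines × loci matrix of alternate-allele dosages
`{0, 1, 2, NA}` with an accompanying variant table (chromosome, 1-based
position, alleles) sorted by (chromosome, position). Panels of inbred
lines are dominated by dosages 0 and 2; heterozygous calls are residual
(a few percent) and missingness is routine in reduced-representation
genotyping. VCF 4.2 and TASSEL-style HapMap text are supported in both
directions; admixture Q/P matrices use the whitespace layout of the
standard admixture tools (one row per line in `.Q`, one row per locus in
`.P`).

## Quality control

Loci are retained when MAF ≥ 5%, missing rate ≤ 20% and heterozygote
fraction ≤ 5% — the customary GBS-panel cuts, exposed in
`qc_thresholds()`. The three criteria are evaluated independently on
the raw calls (a locus failing several is counted once per criterion,
removed once), which makes the filter idempotent and order-free. MAF is
computed on non-missing calls with heterozygotes contributing one copy
of each allele; the denominator convention is a declared choice, since
panels of this kind are usually described without stating it. There is
deliberately no per-line QC: the workflow filters loci only.

For subgroup-level analyses a stricter convention applies
(`subgroup_missing_mask()`): every heterozygous call is treated as
missing — in an inbred, a het call is as likely a sequencing/paralogy
artifact as a true heterozygote — and loci whose resulting missing rate
exceeds 10% are dropped.

## Diversity statistics

Per locus, with alternate-allele frequency p and q = 1 − p:
GD = 1 − (p² + q²) (gene diversity, at most 0.5 for biallelic loci) and
PIC = GD − 2p²q², with PIC ≤ GD as an algebraic identity that the test
suite sweeps across p. Moving-window GD uses 10 Mb windows advanced by
1 Mb; the window size is the conventional genome-scan choice, and the
step (not usually stated alongside it) defaults to a tenth of the
window. Adjacent-locus distances are computed within chromosomes only
and summarized in the customary distance bands (0–0.1 kb up to > 75 kb).

## Linkage disequilibrium

r² is the squared Pearson correlation of dosage vectors over
pairwise-complete lines — composite LD, which requires no phasing and
matches how panel studies compute it. D′ needs haplotype frequencies, so
it is estimated from the two-locus table: lines homozygous at one or
both loci contribute resolvable haplotypes, and double heterozygotes are
split between coupling and repulsion phases by EM. Pair enumeration is
capped at a 1 Mb physical window to bound the O(m²) pair count; the cap
is a computational device, not a biological claim.

The decay distance is defined operationally: pair r² values are pooled
into log-spaced distance bins, bin means are made monotone
non-increasing by an isotonic regression (raw binned means are noisy and
non-monotone, and a threshold-crossing rule needs a monotone curve), and
the decay distance is the midpoint of the first bin at or below the
threshold (default r² = 0.1). A threshold at or above the initial fitted
value yields distance 0; a curve that never reaches the threshold is
reported censored at the cap.

## Haplotype blocks and tagSNPs

Blocks follow the Gabriel confidence-interval recipe. For each pair
within a 500 kb span cap, 90% bounds on |D′| are read from the
normalized two-locus profile likelihood evaluated on a 101-point |D′|
grid with allele frequencies fixed at their estimates — the likelihood
counts resolvable haplotypes directly and keeps the coupling/repulsion
mixture term for double heterozygotes. Pairs with fewer than 10
pairwise-complete lines are uninformative. A pair is *strong LD* when
CI_low ≥ 0.70 and CI_high ≥ 0.98, *strong recombination* when
CI_high < 0.90 (Haploview's defaults; all exposed as arguments). A span
is a block when its outermost pair is strong and at least 95% of its
evidence-bearing pairs are strong; maximal non-overlapping spans are
kept longest-first with ties to the leftmost. Intermediate pairs
(neither strong nor recombination) carry no evidence either way — the
usual Gabriel denominator.

TagSNPs are a greedy set cover within each block: repeatedly pick the
locus tagging (r² ≥ 0.8) the most untagged members, ties to the lower
position. Every locus tags itself, so the cover always completes, and a
block can legitimately need several tags — which is why panel-wide tag
counts exceed block counts. A haplotype-frequency-based tagger was
considered and rejected: the greedy r² cover is deterministic, easy to
audit, and sufficient for marker-reduction purposes.

## Kinship

The centered genomic relationship K = ZZ′ / (2Σpⱼ(1 − pⱼ)) with Z the
column-centered dosage matrix, missing dosages mean-imputed, and
monomorphic loci excluded. For the "relative kinship" report, negative
off-diagonal entries are floored at zero — unrelated — matching the
non-negative scale on which such panels are usually summarized; the raw
matrix is kept alongside. Mean imputation biases relationships toward
zero, which is acceptable at the ≤ 20% missingness enforced upstream.

## The admixture model

For line i, locus j: g_ij ~ Binomial(2, π_ij), π_ij = Σₖ Q_ik P_kj,
missing calls skipped. `fit_admixture()` maximizes this by EM: each
observed allele is allocated to a source group proportionally to
Q_ik P_kj (alternate) or Q_ik (1 − P_kj) (reference), and expected
counts renormalize into Q and P. EM was chosen over quasi-Newton block
relaxation deliberately: same stationary points, a monotone
log-likelihood trace that the tests assert on every run, and a simple
contract. The kernel is compiled (Rcpp); allocations are computed so
that they sum *exactly* to the allele counts, which keeps Q rows on the
simplex by construction (an earlier formulation via 1 − π drifted off
the simplex and diverged — the invariant is load-bearing). P is clamped
to [1e-6, 1 − 1e-6].

Numerical contract: convergence at relative log-likelihood change
< 1e-6 (cap 2000 sweeps), 5 random restarts by default with the best
likelihood kept, deterministic given `seed`. K = 1 is solved in closed
form (Q ≡ 1, P = observed frequencies). Label switching is resolved by
ordering groups by total Q mass; biological names are attached
afterwards from indicator lines (`name_groups_by_indicators()`), each
fitted column taking the majority known identity of the indicator lines
whose largest Q falls in it.

**Choosing K.** `cv_error()` masks a fold of the observed entries,
refits, and scores held-out dosages against 2π̂ by mean squared error,
averaged over 5 folds. This squared-error deviance is not identical to
the deviance used by the standard admixture software, and no equivalence
is claimed for the error *values* — only for the argmin over K, which
the tests check on simulated panels. Per-fold refits use one restart
and a 200-sweep cap: K selection is robust to loose per-fold
convergence, and this keeps the K grid affordable.

## Fst and trees

Between-group differentiation is the Nei-style ratio of sums
Fst = Σⱼ(H_T,j − H_S,j) / Σⱼ H_T,j, with H_S the mean within-group gene
diversity and H_T the gene diversity of the pooled mean frequency —
the family used by admixture software when reporting divergence between
inferred groups, computable from either fitted P or observed subgroup
frequencies. Weir–Cockerham's estimator is available behind
`method = "wc"` (it needs per-group sample sizes and is labeled as
what it is, not as the default). Group trees are UPGMA on the Fst
matrix, deterministic with ties resolved by label order.

## Heterotic-group assignment

With A the group of the largest Q value and B the runner-up:

| condition | identity |
|---|---|
| Q_A > 0.5 and Q_A − Q_B > 0.1 | A |
| Q_A > 0.5 and Q_A − Q_B < 0.1 | A_Para |
| Q_A ≤ 0.5 and Q_A − Q_B ≥ 0.15 | A_Para |
| otherwise | Mixed |

Two genuinely open points were decided here. First, the margin exactly
equal to 0.1 at dominant Q_A is covered by neither strict inequality of
the rule as published; it resolves to the clear assignment A (favoring
the stronger claim makes the rule total) and is flagged `boundary`.
Second, the published worked examples are not all consistent with the
published rule: a row like (0.35, 0.26) — top value not dominant,
margin 0.09 < 0.15 — is Mixed under the rule as printed, although the
narrative around it reports a Para identity. The implementation follows
the printed rule; the acceptance test pins this behavior down rather
than guessing at unstated thresholds. Argmax ties in the default
identity take the first-listed group and are flagged.

## Group-specific loci

"Unique", "neutral" and "fixed" are qualitative terms in the source
literature; the numeric bands here are this package's declared
operationalization, all exposed in `locus_class_thresholds()`:
polymorphic means within-group MAF ≥ 0.05; neutral means frequency in
[0.30, 0.70]; fixed means frequency outside [0.10, 0.90] (either allele
near fixation); differential means |P_A − P_B| ≥ 0.50, a cut consistent
with the magnitude of the differences such studies tabulate. "Unique"
is read as *private polymorphism* (segregating in exactly one group)
rather than private allele. Classes are independent flags — a locus may
be both unique and differential — and the A/B classification mirrors
exactly under group swap.

## The synthetic-panel generator

`simulate_panel()` draws from the Balding–Nichols model: per locus an
ancestral frequency p ~ Uniform(0.05, 0.95) — kept off the boundaries so
that filter behavior is governed by drift, not by the base draw — and
per group k a drifted frequency Beta(p(1−F_k)/F_k, (1−p)(1−F_k)/F_k),
giving expected differentiation F_k. Admixture rows are Dirichlet, with
a configurable fraction of lines forced pure (one-hot). Inbreeding is
modeled directly: with probability 1 − `residual_het_rate` one allele is
drawn and doubled, else two independent alleles are drawn; missingness
is MCAR (no mechanism being stated for real panels, the neutral choice).
Map positions can be telomere-enriched: density t at the outer 10% of a
chromosome, 1 in the middle 10%, linear in between, so the outer/middle
density ratio is t by construction; t is a free parameter, not
calibrated to any particular genome. One user seed drives everything;
per-stage sub-seeds are derived as fixed offsets, so a fixed seed gives
byte-identical panels.

Defaults emulate a realistic structured breeding panel at desk scale:
490 lines, 5000 loci (the scale of a tagSNP set) on 10 chromosomes of
200 Mb, K = 10 groups at F = 0.25 (the magnitude of between-subgroup
Fst reported for structured maize germplasm), 2% residual
heterozygosity, 5% missingness, 80% pure lines.

`simulate_block_panel()` adds linkage by block copying: each block has a
small founder-haplotype pool and each fully homozygous line copies one
founder per block, independently across blocks — maximal LD within
blocks, background LD between. This is the truth standard for the
decay-distance and block-detection tests.

**What passing tests show, and what they do not.** The generator
reproduces the statistical skeleton the estimators assume — drifted
group frequencies, near-homozygosity, MCAR missingness, block-wise LD —
but not coalescent genealogies, linked selection, pedigree loops,
allele-frequency clines, or informative missingness. Recovery results
on these panels validate the estimators' correctness, not their
robustness to everything a real GBS panel can contain.

## Problem sizes and determinism

The test suite and acceptance script run their recovery studies at
200 lines × 2000 loci with K = 3 and F = 0.3 (three seeds for
Q-recovery, five for cross-validated K over K ∈ 1..6), block and decay
studies at 40–100 lines with 2–20 blocks, and the end-to-end pipeline at
100 lines × 300 loci — sizes chosen so the full suite completes in a few
minutes on one CPU while leaving the conclusions seed-stable. Every
stochastic routine takes an explicit seed and restores the caller's RNG
state; seeded reruns of the pipeline are byte-identical, which the tests
verify by checksum.

## Known limitations

- D′ confidence intervals treat a homozygous line's two identical
  haplotypes as two observations; for fully inbred panels this counts
  each line's haplotype twice, making the intervals somewhat optimistic
  relative to a haploid treatment. The Gabriel thresholds were tuned for
  exactly this diploid convention, so the block caller is internally
  consistent.
- Mean-imputed kinship and PCA shrink relationships for high-missingness
  lines toward the panel mean.
- The cross-validation deviance is squared-error, not binomial; its
  values are not comparable to other software's CV errors, only its
  argmin behavior is.
- UPGMA assumes rate-constancy on the Fst distance matrix; it is a
  display device, not a phylogeny.
- The pipeline's block stage is O(pairs within the span cap); panels
  with very dense maps need the cap (or per-chromosome subsetting) to
  stay affordable.
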