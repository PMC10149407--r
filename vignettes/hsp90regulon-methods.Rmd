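---
title: "Methods: detecting strain-specific Hsp90-dependent regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting strain-specific Hsp90-dependent regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, parameters and numerical choices
behind `hsp90regulon`, in the spirit of a statistical-methods appendix.
Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The design being analyzed

The pipeline targets a multi-strain chemical-genomics design: several
diverged yeast strains, each profiled by RNA-seq under an
Hsp90-inhibiting treatment (e.g. geldanamycin) and a vehicle control,
with biological replicates. The scientific object is the set of
transcription factors (TFs) whose regulons respond to chaperone
inhibition *differently across strains* — the molecular signature of
Hsp90-buffered or Hsp90-potentiated regulatory variation. A gene whose
between-strain expression gap widens under inhibition is called
*buffered* (the chaperone was hiding the difference); one whose gap
shrinks is *potentiated*.

## Differential expression

Counts are normalized with median-of-ratios size factors: for sample
$s$, $\hat{f}_s = \mathrm{median}_g\, c_{gs}/\tilde{c}_g$ over genes
expressed in every sample, $\tilde{c}_g$ the geometric mean. Genes whose
raw count is below 5 in *every* sample are removed first (the
alternative reading — drop genes with any sample below 5 — is available
as `filter_mode = "min"` but discards most of a typical matrix).

Per strain, with condition means $m^+, m^-$ of normalized counts and a
pseudocount of $\tfrac12$:

$$\log_2\mathrm{FC} = \log_2\frac{m^+ + 1/2}{m^- + 1/2},\qquad
\mathrm{Var}(\log_2(\hat m + \tfrac12)) \approx
\frac{\mu + \alpha\mu^2}{k\,\mu^2 \ln^2 2}$$

with $k$ replicates and NB dispersion $\alpha$
($\mathrm{Var} = \mu + \alpha\mu^2$). The Wald statistic
$z = \log_2\mathrm{FC}/\mathrm{se}$ is referred to the standard normal,
p-values are Benjamini–Hochberg adjusted across genes, and a gene is
differentially expressed when adj. $p < 0.05$ and FC $> 2$ or $< 1/2$
(cutoffs 1.5/2/2.5 exposed via `fc_cut`; DE sets are nested across
cutoffs by construction).

**Dispersion estimation is the one place where naive method-of-moments
fails.** At 3 replicates the per-gene MoM estimate
$(\hat v - \hat m)/\hat m^2$ has ~2 degrees of freedom; its sampling
distribution is strongly right-skewed, so both per-gene plug-in values
and their across-gene *median* sit far below the true dispersion and
make the Wald test anti-conservative (empirically a doubled type-I
rate). The default is therefore a *common* dispersion: the **mean** of
per-gene MoM values over well-measured genes (condition mean > 5),
floored at 0.01 — an (asymptotically) unbiased moment estimator that
pools information across genes, in the same spirit as the
common-dispersion estimators of mainstream count-model packages. With
it, the simulated null type-I rate sits at the nominal 0.05 (checked by
the test suite over 200 simulations). Per-gene estimates remain
available (`dispersion = "gene"`). This simplified test deliberately
omits shrinkage, independent filtering and outlier handling; numerical
agreement with full-featured NB packages is not promised.

Fold-change *ratios* between strains use the same pseudocounted linear
FC, so the pair-specific rule (ratio > 2 or < ½) matches the DE
fold-change scale exactly. By default only genes DE in at least one
strain of a pair are eligible (`require_de = TRUE`), since pair-specific
genes are conceptually a refinement of the DE set; the flag is exposed
because the definition is defensible either way. Buffered/potentiated
calls compare $|\Delta\log_2(m^+ + \tfrac12)|$ against
$|\Delta\log_2(m^- + \tfrac12)|$; exact equality is reported as `tie`
rather than forced into a class.

## Promoter scanning and motif conservation

Promoters are the 500 bp immediately 5′ of the translation start on the
coding strand (reverse-complemented for minus-strand genes; shorter
flanks are returned truncated and flagged). A PWM is a 4 × L matrix of
per-position log-likelihoods with a per-TF score cutoff; a window's
score is the plain sum of its bases' log-likelihoods, both strands are
scanned with single-base steps, and a hit requires score **strictly
greater** than the cutoff (ties excluded, following the usual "higher
than the cutoff" phrasing). Windows containing N are skipped — assigning
an arbitrary log-likelihood to an unknown base would be a silent prior.
Hit positions are reported as the 1-based distance from the translation
start to the hit base nearest it, the convention in which a site "273 bp
upstream" reads naturally. The bulk scanner concatenates promoters with
N spacers and scores each PWM once per strand through Biostrings'
C-level scorer; a property test pins its equality with the one-window
reference implementation.

Cross-strain conservation uses a center-star multiple alignment of each
gene's promoters: global Needleman–Wunsch (match +1, mismatch −1, linear
gap −2) against the strain minimizing the summed pairwise distance. The
scheme is deterministic, $O(k^2 L^2)$, and adequate for 500-bp
promoters; when the optimal pairwise score equals the gap-free score
$L - 2\cdot\mathrm{Hamming}$ the ungapped alignment is emitted directly
(an exact shortcut, since it attains the optimum — it covers nearly all
pairs in SNP-dominated data). Hits of one TF are grouped greedily by
ascending alignment column (ties to the higher score), with a 20-column
window measured in alignment columns — gaps counted, the only reading
consistent with grouping *within an alignment*. A group with a hit in
every strain and identical site sequence is `conserved`; with sequence
variation, `conserved_with_variation`; a missing strain makes it
`non_conserved`. Target sets for the TF cascade use conserved plus
variant classes by default (`include_variant = FALSE` restricts to
strict conservation); how overlapping same-TF hits should be
de-duplicated has no canonical answer, so each greedy group counts once.

## The TF-candidate cascade

For each TF with at least 3 targets in *every* strain (smaller regulons
are excluded): the per-strain lists of target log₂ fold changes enter a
Kruskal–Wallis test (mid-ranks, tie correction; all-tied data return
p = 1 rather than dividing by a zero correction factor). KW p-values are
Bonferroni-adjusted across tested TFs; candidates have adj. p < 0.05.
Log₂ fold change is used rather than linear FC because the rank tests
are invariant to monotone transforms within a group and the log scale
keeps the two directions symmetric.

Candidates' target fold changes are then compared between every strain
pair with two-sided Wilcoxon rank-sum tests — exact by enumeration for
combined n ≤ 12 without ties, otherwise the normal approximation with
tie and continuity corrections — and Bonferroni-adjusted over **all
(TF, pair) tests performed** (the most natural single family; a per-TF
family would be a configuration variant). Finally, for each pair, a
one-sided two-proportion z test (pooled proportions, continuity
correction on by default to mirror the common R default) asks whether
the pair's strain-pair-specific genes are over-represented among the
TF's targets relative to all analyzed genes; a TF enriched in at least
one pair is *high-confidence*. Labels per (TF, pair) — 0 (KW adj.
p ≥ 0.05), 1 (KW < 0.05, Wilcoxon ≥ 0.05), 2 (both < 0.05) — feed a
complete-linkage clustering on Euclidean row distances with
deterministic smallest-index tie-breaks.

Chaperone-client and GO-term enrichment use the upper-tail
hypergeometric probability computed in log space. One boundary
convention deserves a warning: `hypergeometric_ge(k, ...)` is the
*inclusive* tail $P(X \ge k)$ — the quantity a textbook enrichment test
reports — while upper-tail CDF calls in common statistical environments
return the *exclusive* tail $P(X > k)$ unless the observed count is
decremented first. At small counts the two differ several-fold (at the
classic 7-of-21-vs-23-of-187 overlap: 0.0063 inclusive vs 0.0011
exclusive), and published values often follow the exclusive convention.
`client_enrichment()` therefore reports both (`p_ge`, `p_gt`).

## Distance trees

Genetic distances use the Tamura–Nei (1993) closed form with pairwise
deletion of gaps/N and base frequencies averaged over the two sequences
at the retained sites (a whole-alignment frequency pool, as some
reference implementations use, changes distances only in the fourth
decimal on realistic data). Saturated pairs (non-positive logarithm
arguments) raise an error naming the pair instead of returning
infinity. Expression distances are Euclidean on replicate-mean TPM/1000
per condition; TPM is rate-normalized counts scaled to $10^6$ per
sample.

Trees are built with BIONJ: neighbor joining whose reduction step mixes
the two joined rows with the weight $\lambda$ minimizing the variance of
the reduced matrix (variances initialized to the distances and reduced
alongside). On additive matrices this recovers the generating topology
and branch lengths exactly (to $10^{-9}$ in the tests). Negative branch
lengths — possible on noisy matrices — are clamped to zero with the
deficit transferred to the sibling branch, keeping path lengths through
the join unchanged; BIONJ's description leaves this policy to
implementations, so it is stated here explicitly. Distance matrices are
compared by Spearman correlation over strictly-lower-triangle entries
paired by label.

## The synthetic-data generator

The generator emulates the study design rather than yeast biology in
full. Defaults: 5 strains, 2 conditions, 3 replicates, 2000 genes,
500-bp promoters, 20 TFs with 30-gene regulons, and 5 responsive
(TF, strain) pairs planted at log₂ effect 1.5 on treated means only.
Counts are NB with a shared dispersion α = 0.05 (variance μ + αμ²) —
gene-wise dispersions would be more realistic but make recovery tests
harder to interpret — log-normal baseline means (meanlog = log 200,
sdlog = 1) and log-normal library-size factors (sdlog = 0.1). The
background SNP rate is 0.005/bp per strain, the scale of divergence
among wild yeast isolates (tens of thousands of SNPs on a 12-Mb
genome).

Planted motifs are the PWM consensus; each PWM carries one degenerate
position whose alternative base costs only 0.2 score units, and the
cutoff sits 1.0 below the consensus score, so exactly one designed
substitution stays above cutoff while any other substitution falls
below. With probability 0.02 an instance receives that tolerated
substitution in one random strain (→ conserved with variation), and
with probability 0.02 it is scrambled below cutoff in one random strain
(→ non-conserved); background SNPs avoid planted footprints so these
two rates alone govern motif fate. The resulting ~96% conserved
fraction matches the scale reported for real cross-strain TFBS maps.
Motif length defaults to 12 bp so that chance consensus matches on
random background are rare enough not to blur ground-truth recovery
tests.

Randomness is split into two documented streams: promoter/genome draws
use `seed`, count draws `seed + 1` (and the GO map `seed + 2`), so the
genome layer can be held fixed while counts are redrawn. Because
responsiveness is planted on treated-condition *means* and never touches
promoter sequence, multi-seed simulations (planted-TF recovery over 20
seeds, family-wise error over 200 seeds, both in the acceptance checks)
legitimately condition on one promoter/motif realization and redraw
only the count layer — the quantity under study is the count-based
cascade, and this keeps the two simulations inside a few minutes on one
CPU. Those are also the problem sizes the acceptance script uses: one
2000-gene fixture, 20 planted-count simulations, 200 null simulations.

**What passing tests do and do not show.** The generator has no indels,
no gene-wise dispersion, no linkage between genetic distance and
baseline expression, no correlated regulons beyond random target
overlap, and planted effects act multiplicatively on treated means
only. Recovery and error-control results therefore validate the
pipeline's statistics and bookkeeping — not robustness to alignment
artifacts, dispersion misspecification, or confounded library
composition in real data. The Spearman correlation between genetic and
expression distances, in particular, is not meaningful under this
generator (baseline expression is independent of the SNP layer) and is
reported only as a descriptive statistic of each run.

## Known limitations

- The DE test is a deliberately simplified NB Wald test; it trades
  DESeq2's shrinkage machinery for transparency and testability.
- Shared targets of paralogous TFs are not de-duplicated: each TF is
  tested on its own regulon, so paralogs with overlapping regulons can
  both be flagged without the data distinguishing them.
- Center-star alignment is a 2-approximation to optimal multiple
  alignment; for promoters with complex indel structure a profile
  aligner would be preferable.
- Attribution of causal variants (TF itself vs upstream signaling) is
  outside the package's scope, as is direct-vs-indirect buffering.
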