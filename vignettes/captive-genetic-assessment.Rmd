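---
title: "Marker-based genetic assessment and studbook reconciliation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-based genetic assessment and studbook reconciliation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(captivekin)
```

## The problem

Captive breeding programs for endangered species are managed from a
*studbook*: a genealogical registry recording every individual's sire and
dam, under the convention that founders are unrelated and non-inbred.  Gene
diversity projections, mean-kinship breeding recommendations and inbreeding
estimates all flow from that registry — and are only as good as it is.
Recording errors (a dam confused with her full sister, a litter sired by the
resident male's brother), unknown parentage, and the founder assumption
itself can all distort the picture.

`captivekin` implements the molecular side of the audit.  Given three marker
classes routinely typed in managed canid populations — a maternally
inherited mitochondrial control-region fragment, the highly polymorphic
MHC class II locus DLA-DRB1 (whose sequence haplotypes behave as codominant
alleles of a single nuclear locus), and a panel of unlinked nuclear
microsatellites — it computes the standard diversity statistics, estimates
pairwise relatedness and parentage likelihoods, estimates contemporary
effective population size from linkage disequilibrium, and reconciles all of
it against the studbook.

## The models, stage by stage

### Sequence diversity and neutrality

For an aligned panel of haplotypes with per-individual assignments,
`diversity_stats()` reports segregating sites $S$, transitions and
transversions, the mean number of pairwise differences
$k = \binom{n}{2}^{-1} \sum_{i<j} d_{ij}$ over the $n$ gene copies,
nucleotide diversity $\pi = k/L$, its Jukes–Cantor-corrected version
(applied per pair, then averaged — at the divergences seen within a species
the difference from correcting the mean is negligible), and haplotype
diversity $H_d = \frac{n}{n-1}(1 - \sum p_i^2)$.

Alignment columns containing anything other than A/C/G/T in any sequence are
excluded everywhere (complete deletion).  This is a deliberate, documented
choice: it makes $S$, distances, and haplotype collapsing mutually
consistent, at the cost of discarding whole columns for a single ambiguous
base.

`neutrality_tests()` implements Tajima's $D$ (1989 constants) and Fu and
Li's $D^*$ (1993 variance constants).  Balancing selection at an immune
locus shows up as significantly *positive* values: too many
intermediate-frequency variants, too few singletons.  Because no worked
published example of $D^*$ could be reproduced offline, both statistics are
validated by simulation instead: under a neutral coalescent
(`sim_coalescent()`, $n = 20$, $\theta = 5$) their means are within $\pm0.1$
of zero and their standard deviations close to one — errors in the variance
constants would show up immediately in that spread.  Significance can be
assessed either by the conventional $|D| > 2$ flag or by an empirical
coalescent p-value (`n_sim > 0`).

### Haplotype phasing against a known panel

Diploid Sanger reads of the MHC locus give an unphased site-wise allele
multiset.  `phase_pairs()` resolves each individual to an unordered pair of
known panel haplotypes in three escalating steps: (i) homozygotes and
genotypes compatible with exactly one panel pair are resolved with
probability 1; (ii) pedigree transmission constraints zero out pairs a
genotyped parent could not have produced; (iii) remaining ambiguities go to
an EM estimate of panel haplotype frequencies, and the posterior of the best
pair is reported.  Pairs below a 0.9 posterior are flagged unresolved rather
than guessed — mirroring the ">90% probability" reporting convention of
Bayesian phasing tools.

### Minimum spanning network

`build_msn()` connects haplotypes by a minimum spanning tree under raw
pairwise nucleotide differences (integer "mutational steps"), using
Kruskal's algorithm with deterministic lexicographic tie-breaking, so the
same panel always yields the same network.  A Tamura–Nei (TN93) distance
matrix is attached for reference, since distance-model choice for network
construction is a genuinely open convention; the tree weight is tested
against exhaustive enumeration of all spanning trees for panels of up to
seven haplotypes.

### Microsatellite diversity

Per locus: observed heterozygosity, Nei's unbiased expected heterozygosity
$H_E = \frac{2n}{2n-1}(1-\sum p_i^2)$, the inbreeding index
$F_{IS} = 1 - H_O/H_E$ (the definition used in the captive-management
literature; Weir–Cockerham's estimator is deliberately *not* substituted),
rarefied allelic richness
$R_S(g) = \sum_i \left[1 - \binom{N-N_i}{g}/\binom{N}{g}\right]$
(default $g$ = twice the minimum number of typed individuals, the FSTAT
convention), and the probabilities of identity for unrelated pairs and for
full siblings.  Negative $F_{IS}$ — a heterozygote excess — is the expected
signature of a small, family-structured, recently bottlenecked population.

The Hardy–Weinberg test permutes alleles among individuals and compares the
observed heterozygote count with its permutation distribution.  The count is
discrete, and a plain tail probability is measurably conservative (type-I
rate ~0.02 at nominal 0.05 in our null calibration), so mid-p tail
probabilities are used; with them the empirical size is back at the nominal
level.  The linkage-disequilibrium test uses the sum of squared Burrows
composite disequilibria with genotype permutation; its statistic is
effectively continuous and needs no such adjustment.

### Maximum-likelihood relatedness

For a dyad, each co-typed locus contributes
$P(g_1,g_2\mid k) = k_0 P_0 + k_1 P_1 + k_2 P_2$, where $(k_0,k_1,k_2)$ are
the probabilities of sharing 0, 1 or 2 alleles identical by descent and the
$P_m$ condition on the shared alleles, drawing all non-IBD alleles from the
population frequencies.  The $P_1$ table is validated against an exact
generative enumeration to $10^{-12}$.  `estimate_r()` maximises the summed
log-likelihood on the $k$-simplex by a 0.01-step grid with Nelder–Mead
refinement; $\hat r = k_1/2 + k_2$.  `classify_relationship()` evaluates the
four fixed hypotheses U, HS, FS, PO and breaks ties toward the less-related
category, so relatedness claims are never inflated by ties.  Confidence sets
(`relationship_ci()`) use a parametric bootstrap: alternatives are rejected
when the observed log-likelihood difference exceeds the 95th percentile of
differences simulated under the alternative, preserving the observed
missingness pattern.

Two honesty notes.  Genotyping error is ignored in these likelihoods (it
enters only the parentage model), matching standard practice.  And because
$\hat r \ge 0$ by construction, the estimate for truly unrelated pairs is a
truncated-at-zero quantity whose mean is slightly positive — about
0.05–0.06 at 14 loci of the informativeness simulated here.  Calibration
simulations recover category means of roughly 0.054 / 0.28 / 0.50 / 0.52 for
U / HS / FS / PO; the unrelated category therefore sits just outside a
$\pm0.05$ band around zero, which is a property of every
simplex-constrained ML relatedness estimator, not a defect of the
implementation.

### Parentage likelihoods

For a candidate parent, each co-typed locus contributes
$L_1 = (1-\epsilon)T + \epsilon P_{HW}(g_o)$ against the same expression
with the candidate integrated out, where $T$ is the exact Mendelian
transition probability (a known other parent is conditioned on; an unknown
one integrated over the population under HWE) and $\epsilon$ is a simple
per-locus error mixture (default 0.01; the rate is configurable and always
reported, because field data rarely state it).  The LOD is the summed log
ratio; Delta is the gap between the top two candidates.  With $\epsilon = 0$
a single Mendelian exclusion drives the LOD to $-\infty$.

`mhc_trio_check()` adds the haplotype veto: a trio is possible only if the
two offspring haplotypes can be assigned one-per-parent consistently.
`resolve_parentage_case()` chains exclusion, LOD/Delta ranking and the MHC
veto into a single case report — the workflow that, on real captive data,
resolves most uncertain-sire cases between full brothers and leaves
genuinely uninformative cases flagged ambiguous.

### Effective population size from linkage disequilibrium

Among unlinked loci in a closed finite population, drift generates
transient associations: $E(r^2) \approx 1/(3N_e) + $ sampling noise.
`ne_point()` computes Burrows composite $r^2$ for every allele pair of
every locus pair (alleles below `p_crit` excluded; comparisons equally
weighted), subtracts the published sampling expectation
($1/S + 3.19/S^2$ for harmonic mean sample size $S \ge 30$;
$0.0018 + 0.907/S + 4.44/S^2$ below), and inverts the drift relation —
random mating $N_e = (1/3 + \sqrt{1/9 - 2.76 r^2{'}})/(2 r^2{'})$, with the
monogamous analogue $(2/3 + \sqrt{4/9 - 7.2 r^2{'}})/(2 r^2{'})$, which is
always the larger of the two on the same data.  Two numerical details are
deliberate: the $n/(n-1)$ factor on the Burrows estimator is retained
because the published sampling expectation was calibrated with it (null
simulations at $S=50$ reproduce $1/S + 3.19/S^2$ with the factor and fall
short without it), and $r^2$ is truncated at its theoretical bound of 1,
which the factor can marginally exceed on a perfectly associated pair.
Non-positive corrected $r^2{'}$ yields an infinite estimate — the data
carry no drift signal.

Confidence intervals are a delete-one-individual jackknife on $r^2{'}$,
mapped through the (monotone) inversion to the $N_e$ scale.  Calibration on
Wright–Fisher simulations (true $N_e = 50$, $S = 50$, 14 loci × 8 alleles,
20 generations, 100 replicates, `p_crit = 0.02`) gives a median estimate
within 10% of truth and ~95% CI coverage.  The calibration `p_crit` of 0.02
follows the standard advice to exclude alleles expected fewer than about
twice in the sample; analyses of a real ~100-individual dataset would
typically use a smaller threshold tied to their own missingness structure,
and `p_crit` is a first-class argument everywhere.

### Pedigree engine and reconciliation

`kinship()` implements the classical recursion with founders unrelated and
non-inbred — exactly the convention the audit is designed to interrogate.
`classify_dyad()` maps a pedigree to the categories PO, FS, HS, GP, AV, FC,
U by highest expected relatedness.  `consistency_report()` encodes the
mapping used when comparing marker-based categories with the registry:
marker data cannot separate grandparental, avuncular or first-cousin pairs
from half-sibs or unrelated pairs, so studbook GP/AV/FC is scored
consistent with genetic HS or U, while PO/FS/HS/U must match exactly; dyads
with $\hat r > 0.6$ are flagged as unexpectedly highly related.
`overlay_markers()` flags matrilineal mtDNA violations and MHC trio
failures directly on the pedigree.

## The synthetic-data generator

`sim_config()` defaults describe the population shape this pipeline is
aimed at: 28 founders, three descendant generations of monogamous pairs
(kinship-zero pairing unless inbreeding is explicitly enabled), litters
Poisson with mean 5, 14 unlinked microsatellite loci with 4–14 alleles and
Dirichlet(1) frequency priors (giving per-locus expected heterozygosity
near 0.75, matching captive canid panels), two mtDNA haplotypes, ten MHC
haplotypes.  `gene_drop()` transmits alleles Mendelianly, mtDNA
matrilineally and MHC biparentally, with no mutation (negligible over 3–4
generations).  Error injectors corrupt genotypes (frequency-weighted
mis-calls, missingness) and studbooks (dam replaced by a full sister, sire
by his brother), always emitting a truth ledger so tests assert against
recorded truth, never re-derived truth.

What the generator does *not* emulate: null alleles and allelic dropout
with locus-specific rates, population structure among founders, mutation,
overlapping generations, or non-random sampling of carcasses/packs.
Passing calibration on synthetic data therefore demonstrates correctness of
the estimators under their own assumptions, not robustness to every field
artefact.

## Problem sizes used in the shipped tests

The test suite calibrates each estimator at sizes chosen to make sampling
error small relative to the tolerance being asserted: 2000 coalescent
genealogies for the neutrality statistics, 200 null tables for test size,
250 dyads per relationship category for relatedness recovery, 100
Wright–Fisher replicates for $N_e$, 200 corrupted studbooks for error
detection, and 50,000 gene drops for the kinship cross-check.

## A worked example

```{r example}
cfg <- sim_config(seed = 7)
f <- sim_founders(cfg)
sp <- sim_pedigree(cfg, f)
truth <- gene_drop(sp$ped, f, seed = 7)
truth$gt

ld <- locus_diversity(truth$gt)
attr(ld, "summary")

fr <- allele_frequencies(truth$gt)
kid <- sp$sb$id[!is.na(sp$sb$sire_id)][1]
sire <- sp$sb$sire_id[sp$sb$id == kid]
parentage_lod(truth$gt, kid, sire,
              other = sp$sb$dam_id[sp$sb$id == kid],
              freqs = fr, epsilon = 0.01)$LOD
```

## Known limitations

* Relatedness likelihoods assume an outbred reference population; a
  triadic, inbreeding-aware estimator is out of scope.
* The LD-$N_e$ comparison weighting (equal weight per allele-pair
  comparison) is one of several published conventions; absolute agreement
  with other implementations on identical data is expected to be
  approximate.
* Null-allele inference is limited to the homozygote-excess tail of the
  HWE test; no dedicated null-allele algorithm is provided.
* The phasing EM assumes the panel of haplotypes is complete; a genotype
  incompatible with every panel pair is an error, not a discovery
  mechanism for new haplotypes.
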