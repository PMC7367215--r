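---
title: "Array-informed allele-frequency annotation and variant prioritization: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Array-informed allele-frequency annotation and variant prioritization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popafkit)
```

## The problem

Clinical interpretation of a newly sequenced genome leans heavily on
population allele frequencies: a variant that is common in the patient's own
population is unlikely to cause a rare severe disease, however striking it
looks against a global reference panel. For understudied, strongly admixed
populations the global panels (gnomAD-style) are a poor proxy, but a large
genotyping-array cohort from the same population — cheap "breadth" to the
sequencing's "depth" — can supply population-specific allele frequencies at
millions of the most variable loci. This package implements that synergy as a
reusable pipeline:

1. estimate per-locus allele frequencies from an array cohort
   (`build_panel()`),
2. annotate whole-genome variant calls with local and reference frequencies
   and rank them by a two-proportion Z statistic (`annotate_vcf()`,
   `summarize_priorities()`),
3. validate the calls by array concordance (`concordance()`) and standard QC
   ratios (`sample_qc()`, `share_partition()`),
4. place samples in their population context by PCA projection, supervised
   admixture, centrality-based representative selection and an
   identity-by-state neighbor-joining tree (`fit_pca()`,
   `supervised_admixture()`, `select_representatives()`, `ibs_distance()`,
   `neighbor_joining()`),
5. intersect structural-variant calls from two callers and classify their
   novelty (`intersect_callers()`, `classify_novelty()`).

The real cohorts this design mirrors are controlled-access, so the package
ships a synthetic-cohort generator with full ground truth; every downstream
stage is exercised against that truth.

## The rarity statistic

For a variant with local alt-allele frequency $p_1$ over $n_1$ called alleles
and reference frequency $p_2$ over $n_2$ alleles, the package computes the
pooled two-proportion statistic

$$\bar p = \frac{p_1 n_1 + p_2 n_2}{n_1 + n_2}, \qquad
Z = \frac{p_1 - p_2}{\sqrt{\bar p (1 - \bar p)\left(\tfrac{1}{n_1} + \tfrac{1}{n_2}\right)}}.$$

$n$ counts alleles, i.e. twice the called diploid samples. A strongly
negative $Z$ marks a variant rarer locally than in the reference — a
candidate for scrutiny under negative selection; a strongly positive $Z$
marks a locally common variant unlikely to be strongly deleterious. Tiers are
assigned at the conventional cutpoints: $|Z| \ge 1.96$ (nominal) and
$|Z| \ge 4$ (strong), inclusive at the boundary. No continuity correction is
applied: the cutpoints are used comparatively for ranking, not as calibrated
hypothesis tests, although the null calibration of the nominal tier is in
fact verified (the acceptance suite simulates $10^5$ null loci and checks the
two-sided $1.96$ tail rate against $5\% \pm 0.8$ points).

Two aggregation modes handle multiple reference populations. `global`
(default) pools the reference panels by allele counts into one combined
reference — appropriate when the question is "different from the world at
large". `strictest_vs_all` scores a variant only when every per-population
$Z$ shares one sign, and then reports the weakest of them — the literal
"different from *all* reference populations" reading. Both are exposed
because the choice is genuinely open; the default is the pooled panel since
it is well-defined for every variant.

The summary table uses the strong threshold for the all-scored row and the
nominal threshold for the annotation rows (ClinVar classes, SIFT/PolyPhen,
protein-altering): the annotation categories are orders of magnitude smaller,
so the nominal threshold is what keeps their tails populated. Both thresholds
are arguments of `summarize_priorities()`.

Missing reference allele numbers are replaced by a configurable
diploid-equivalent default (251,496 alleles, a gnomAD-scale cohort), since
array-style panels always carry AN but public reference exports sometimes do
not.

## The synthetic cohort

`simulate_cohort()` draws a stated world, not a tunable one. Its defaults are
fixed once and mirror the scale of the motivating design:

* ancestral allele frequencies uniform on $(0.05, 0.95)$ — array loci are
  ascertained to be polymorphic, so frequencies are bounded away from
  fixation;
* $K$ population frequency vectors from the Balding–Nichols model,
  $f_{km} \sim \mathrm{Beta}\!\left(p_m \tfrac{1-c}{c},\, (1-p_m)\tfrac{1-c}{c}\right)$,
  the standard F-model whose likelihood matches supervised admixture
  estimation; $c$ plays the role of Fst (default 0.1, continental-scale
  divergence);
* admixture rows $q_i \sim \mathrm{Dirichlet}(\alpha)$ with flat
  $\alpha = (1, \dots, 1)$ — a gradient continuum of admixture rather than
  discrete clusters;
* genotypes $g_{im} \sim \mathrm{Binomial}(2,\, q_i^\top f_{\cdot m})$, 2%
  independent missingness, and a known-sites mask covering 97% of loci
  (the dbSNP-scale known share);
* alleles drawn uniformly over ordered ACGT pairs, so palindromic (A/T, C/G)
  pairs occur at their natural 1/3 rate and the strand-confusion filter is
  genuinely exercised.

All draws derive from one global seed through named substreams
(`substream_seed()`), so adding an output never perturbs existing ones and
every artifact is byte-reproducible.

What the generator deliberately does **not** emulate: linkage disequilibrium
(loci are independent), sequencing error as a read-level process, sex
chromosomes, and a human site-frequency spectrum (frequencies are uniform,
not skewed toward rare). Consequently the generator's Ti/Tv is the uniform
0.5, not the genome-wide ~2 of real human call sets, and a green test
establishes correctness of the *computation*, not realism of the biology.
Per-sample WGS-only extra loci are always novel with respect to the
known-sites set, so the novel fraction of an emitted call set is the known
mask's complement diluted by the extras — higher than the ~3% of a real
genome against dbSNP.

`emit_sample_vcf()` carries two explicit error processes for the validation
stage: `discordance_rate` swaps het and hom-alt on emitted records (errors
stay comparable, so an injected rate of 0.005 is recovered as ~99.5%
concordance), and `strand_flip_rate` writes records on the complementary
strand without changing the genotype.

## Concordance and the filter cascade

Array and sequencing genotypes are compared only after the validation
cascade, applied in a fixed order so every array locus lands in exactly one
bin: missing array genotype → array indel → multiallelic (duplicated
position on either side, or an unsplit ALT) → palindromic pair → allele
reconciliation. "Strand confusion" is operationalized as the standard
array-merge practice: A/T and C/G pairs are removed outright (their strand is
undecidable from alleles), and remaining mismatching pairs are reconciled by
complementing and/or swapping ref/alt, with swaps recoding the dosage
$g \to 2 - g$; irreconcilable pairs are dropped and counted. Array loci with
no SNV call in the VCF are excluded (intersection semantics), not assumed
hom-ref — the sequencing file records variants, so absence is not evidence
of a reference genotype. Concordance is genotype-level by default;
`allele_level = TRUE` scores the two alleles separately (a het/hom mismatch
then costs half). With zero comparable loci the statistic is reported as
undefined, never as 0%.

## Supervised admixture

With the per-population frequency matrix $F$ fixed (computed from labeled
reference samples and clipped to $[10^{-6}, 1-10^{-6}]$ — unclipped vertices
break the updates), the admixture vector $q$ of a genotype vector $g$ is the
maximizer of the binomial likelihood
$g_m \sim \mathrm{Binomial}(2, \sum_k q_k f_{km})$. The EM update

$$q_k \leftarrow \frac{q_k}{2M'} \sum_m \left[ \frac{g_m f_{km}}{p_m} +
\frac{(2-g_m)(1-f_{km})}{1-p_m} \right], \qquad p_m = \sum_k q_k f_{km}$$

($M'$ = non-missing loci) preserves the simplex exactly and never decreases
the log-likelihood — a property the tests assert on every trace. The
likelihood is concave in $q$ for fixed $F$, so the uniform $1/K$ start
matters only for ties; convergence is declared when the gain drops below
$10^{-7}$ or after 2000 iterations.

## Representative selection, IBS and neighbor joining

Subpopulation representatives are chosen per group as the sample nearest
(Euclidean) to its group centroid in the retained principal-component plane
(default $D = 2$, the plane one plots). The centrality metric was an open
design point; distance-to-centroid is the simplest estimator of "typical for
the subpopulation" and is tie-broken by the higher dominant-ancestry
proportion, then lexicographic id, making selection deterministic.

PCA standardizes each locus by mean $2p$ and scale $\sqrt{2p(1-p)}$ and
mean-imputes missing genotypes (standardized zero), which keeps projection of
new samples linear and matches common array-PCA practice. Component signs are
fixed by making each column's largest-magnitude loading positive.

Identity-by-state distance is the fraction of allele mismatches over
mutually called loci, $d \in [0, 1]$. The neighbor-joining implementation is
the standard Saitou–Nei agglomeration with the Q-criterion; it recovers any
additive matrix exactly (verified against 50 random trees to $10^{-9}$ and
against the `ape` reference implementation on noisy matrices). Negative
limbs — possible on non-additive input — are clamped to zero with the
deficit moved to the sibling limb, a documented deviation from raw NJ chosen
because downstream consumers (newick, plotting) reject negative branch
lengths. No LD pruning is applied before IBS: simulated loci are independent
by construction.

## Structural variants

Two callers' call sets are intersected one-to-one: DEL/INV calls match when
they share chromosome and type with reciprocal overlap
$\min(\mathrm{ov}/|a|, \mathrm{ov}/|b|) \ge 0.5$ (the community default for
database comparison); insertions are point events, so they match by
breakpoint window (100 bp) and size ratio (min/max ≥ 0.5) instead. Matching
is greedy by best overlap with ties broken by smaller start — deterministic
and near-optimal at realistic call densities, and verified equal to
brute-force all-pairs matching on simulated sets. The consensus interval is
the union of the two supports. Novelty against a background database uses the
same equivalence rule; with the database covering 86.5% of true events the
merged set's novel fraction lands at the ~13.5% scale the design targets.

## Numerical choices and degenerate inputs

* Z with a degenerate pooled proportion ($\bar p \in \{0, 1\}$) is defined
  as 0: both cohorts fixed for the same allele carry no signal.
* Ties at exactly $|Z| = $ threshold fall in the tail (inclusive
  inequalities, as the summary headers print them).
* All-missing loci are excluded from panels with a logged count; a locus
  needs at least one called genotype to have a frequency.
* Panel joins are exact on (chrom, pos, ref, alt); indels are scored only on
  exact key match and inputs are assumed pre-normalized (no left-alignment
  is attempted).
* Genotype phase is ignored throughout; half calls count as missing.
* SV coordinates are 0-based half-open internally; the TSV reader accepts a
  1-based inclusive dialect flag.

## Limitations

The generator's independence assumptions (no LD, no site-frequency skew)
make absolute counts — shared-variant totals, novel percentages, Ti/Tv —
scale-true but not distribution-true for real genomes. The EM estimator
fixes $F$; joint estimation of $F$ and $Q$ (unsupervised admixture) is out
of scope, as are haplogroup assignment, imputation, VQSR-style filtering and
consequence prediction. The pipeline treats every VCF as single-sample,
biallelic, and pre-split; unsplit records are rejected with counted
warnings rather than silently mangled.
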