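---
title: "Models and methods behind pdachet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pdachet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdachet)
```

`pdachet` analyses multi-region tumour cohorts: several lesions per
patient, each with somatic mutation calls, allele-specific copy-number
segments, expression counts and methylation peak sets against a matched
normal. This vignette records the models the package implements, the
choices made where a convention was genuinely open, and what the synthetic
cohort generator does and does not emulate.

## Somatic variants and TMB

Variant records pass the somatic filter when sequencing depth is at least
20 in both tumour and normal, the normal carries at most 5 alternative
reads, the tumour at least 5, and the maximum population allele frequency
across ExAC/ESP6500/gnomAD is below 1%. Both depth thresholds are
inclusive; a missing population frequency is treated as 0, the usual
annotation convention for a variant absent from all three databases.
Tumour mutational burden divides the count of passed *nonsynonymous*
mutations (missense, nonsense, splice, frameshift, in-frame) by a 38 Mb
exome; synonymous records stay in the table but never count. A gene with
two or more passed nonsynonymous mutations in one lesion is flagged
multi-hit.

Candidate driver mutations require the gene to be in a driver catalog
(pan-cancer plus PDAC lists; `default_driver_catalog()` ships a compact
default, studies should supply their own) and either a truncating
consequence or a damaging missense call: FATHMM-MKL > 0.5, or at least two
of SIFT in [0, 0.05], PolyPhen2 possibly/probably damaging,
MutationAssessor medium/high, FATHMM-MKL > 0.5. Missing scores count as
non-damaging, so incomplete annotation can only lose candidates, never
invent them.

## Copy-number burden, wGII and arm events

All states are defined on the ploidy-normalised log2 ratio
$r = \log_2(\mathrm{CN_t}/\psi)$ with gain at $r \ge \log_2(2.5/2)$ and
loss at $r \le \log_2(1.5/2)$ — for a diploid sample exactly
$\mathrm{CN_t} \ge 2.5$ and $\le 1.5$. CNV burden is the percentage of
covered autosomal length in non-neutral segments; the same cutoffs define
it, which keeps one consistent state definition across the package. The
wGII averages, over autosomes, the fraction of chromosome length whose
*rounded* total copy number differs from the rounded sample ploidy;
rounding avoids floating-point equality and makes a cleanly doubled genome
score 0.

Arm events need more than 98% of the arm length in one state; segments
straddling the centromere are split at the boundary first. Arm boundaries
ship as data files (an hg19 cytoband-derived table and a three-chromosome
toy genome used in tests). Across a patient's regions an arm event is
clonal when the same state recurs in more than 75% of the *remaining*
regions; a single-region patient is clonal by convention (the rule is
vacuous) with a warning, and conflicting gain/loss calls yield subclonal
with a warning. Genome doubling is called when more than half of the
covered genome carries major allele copy number ≥ 2.

## Cancer cell fractions, timing, clone trees

The expected variant allele fraction of a mutation at cancer cell
fraction $f$, multiplicity $m$, purity $\rho$ and local total copy number
$\mathrm{CN_t}$ is

$$\mathrm{VAF} = \frac{f \rho m}{\rho\,\mathrm{CN_t} + 2(1-\rho)}.$$

Multiplicity is estimated by rounding
$\mathrm{VAF}/\rho \cdot (\rho\,\mathrm{CN_t} + 2(1-\rho))$, capped at the
major allele copy number (a mutation cannot occupy more copies than the
major allele provides — the cap removes most rounding artefacts at low
purity), floored at 1; CCF follows by inversion and is clipped to
[0, 1.2] with values above 1 flagged. On noise-free input this estimator
inverts the generator's VAF model exactly, which the test suite asserts at
1e-6.

A mutation is clonal when present in every region with CCF ≥ 0.9 in each
("close to 1"; 0.9 is the common multi-region convention — the threshold
is configurable). Clonal mutations are timed against genome doubling:
per region, early if $m \ge 2$ in a doubled region, late if $m = 1$ while
the major copy number is ≥ 2, uninformative if the major copy number is 1.
The aggregate label needs a strict majority of the *timeable* regions;
ties and no-information cases give "clonal untimed". Clonal arm gains are
timed by the median multiplicity of clonal mutations on the arm (≥ 2 →
early); clonal losses by LOH in every region.

Clone clustering replaces Dirichlet-process machinery with a
deterministic two-stage procedure: group mutations by their region
presence pattern, then split each pattern on the mean CCF across present
regions with a one-dimensional Gaussian mixture (shared variance,
component count by BIC, at most four components per pattern; patterns
under eight mutations use gap partitioning at 0.15 instead). The mixture
criterion was chosen over a plain k-means spread rule because read
sampling noise at depth ~120 and purity down to 0.3 spreads a single
clone's CCF estimates over several tenths: a spread rule either shatters
one clone or misses a small truncal subpopulation beside a large
subclonal cloud, while the mixture likelihood handles both. Only cluster
mean CCFs are consumed downstream, so nothing finer is needed.

Trees are rooted at a germline node above the truncal cluster. Truncal
means mean CCF ≥ 0.85 in every region — cluster means sit slightly below
1 under noise, hence the small allowance relative to the 0.9 per-mutation
rule — and all clusters passing it are merged, since clones
indistinguishable from full clonality cannot be ordered. If no cluster
passes, a full-presence cluster (CCF ≥ 0.7 everywhere) that contains every
other cluster within tolerance is accepted as the root; failing that the
tree is not buildable and the error says so. Other clusters attach to the
smallest cluster that contains them (CCF ≥ theirs in every region within
a 0.1 tolerance). Trunk mutations are the truncal cluster's members;
everything else is branch.

Driver fold enrichment downsamples 12 patients (of ≥ 12) without
replacement, 100 times by default; each replicate builds the 2×2 table of
driver vs non-driver mutations by trunk vs branch with a Haldane–Anscombe
0.5 correction, recording the odds ratio (capped at 100 when degenerate)
and the fold enrichment of driver mutations in each category relative to
the overall driver proportion. The trunk and branch fold distributions
are compared by a two-sided Wilcoxon test — unpaired rank-sum by default,
paired signed-rank by flag, since the pairing convention is a genuinely
open choice; both statistics are exposed.

## Replicate-free differential expression

With a Poisson read-count likelihood and flat prior, the posterior of a
gene's normalised expression given count $k$ and size factor $s$ is
$\Gamma(k+1, \mathrm{rate}=s)$. The conservative signed log2 fold change
is the 1% posterior quantile of $\log_2(\lambda_t/\lambda_n)$ when that
quantile is positive, the 99% quantile when negative, else 0. Because the
ratio of independent Gamma variables is a scaled beta-prime variable, the
quantile has a closed form through `qbeta`; the analytic path is exact and
deterministic and is the default, with a Monte-Carlo path (10,000 draws,
seeded) retained as an independent cross-check — the tests compare the
two. Size factors default to library-size ratios: with one tumour and one
normal there are no replicates for median-of-ratios. DEGs are
|statistic| > 2; shared DEGs must recur with the same sign in every lesion
of a patient. Lesion clustering uses average-linkage hierarchical
clustering on Euclidean distances between log2 fold-change vectors
(linkage and metric are configurable; nothing in the data dictated
another choice) and reports mean intra- vs inter-patient distances plus
the fraction of patients whose lesions form a clade.

## Methylation

The DMR universe is the merged union of significant peaks (q < 0.01)
across samples; a region is private when exactly one sample's significant
peaks overlap it, shared at two or more. The phyloepigenetic distance
matrix is Euclidean on enrichment-fold vectors over the private regions,
where a sample's fold at a region is the maximum over *all* its peaks —
including sub-threshold ones — and 0 when it has none: sub-threshold
enrichment at a sister lesion's private region is exactly the signal that
binds a patient's lesions into a clade. Trees are neighbour joining
(UPGMA by flag), rooted at the matched normal when one is named.
Hypermethylation similarity takes each sample's top 2000 regions by fold
over the merged universe and reports pairwise Jaccard indices; when a
sample covers fewer regions, all are used with a warning.

## Integration and clinical statistics

Cross-omics association is per-gene Spearman rank correlation
(tie-corrected, asymptotic p, Benjamini–Hochberg across genes within each
layer pair); constant layers are skipped with a note rather than given an
undefined coefficient. The concordance screen flags genes whose value
satisfies the stated direction in all but at most one sample (tolerance
configurable), the pattern of a biomarker consistently lost across a
cohort.

The clinical module ships a 19-patient table as a plain-text fixture.
Average CNV burden is dichotomised by a strict median split (high means
strictly greater; the tie rule is documented and tested) and, for
survival, by a strict top-quartile split at the type-7 interpolated 75th
percentile. Fisher tests are two-sided by the probability-mass rule.
DFS events are relapse or metastasis with death censored at its time by
default; counting non-relapse death as an event is available by flag, and
both conventions are reported by the acceptance script because the choice
is not derivable from the data. The patient who died of a non-disease
cause within a week of surgery carries missing survival times and is
excluded from survival analyses while remaining in every contingency
table. Kaplan–Meier estimation and the log-rank test are delegated to the
`survival` package.

## The synthetic cohort generator

`simulation_config()` defaults define the study conditions: 19 patients,
2–4 lesions each, 3–6 clones on a random rooted tree with a single
truncal clone, purity uniform on 0.3–0.8 (the cohort the package is
modelled on reports no per-lesion purities; this range is a choice
covering typically stroma-rich pancreatic resections), mean depth 120
reads, 200–320 mutations per patient with ~8% truncal (yielding the
branch-dominant architecture of multi-region PDAC), driver mutations
planted at 4-fold boosted odds on the trunk, 40% genome-doubled patients,
2000 expression genes with 5% patient-level DEGs (log2 shifts of 3.5–5),
an 800-region methylation universe with 40% reserved for per-lesion
private DMRs, and a per-percent log-hazard of 0.06 linking burden to
simulated disease-free survival. Branch clone fractions come from a
stick-breaking draw that respects containment and caps branch CCF at 0.7
of the parent, so planted branch clones are never confusable with the
trunk. One global seed drives everything; subsidiary generators draw
sub-seeds from it, and identical configurations reproduce byte-identical
cohorts.

What the generator deliberately does **not** emulate: mapping artefacts
and sequencing error (read counts are exactly binomial around the model
VAF), subclonal copy number below whole-arm/partial-arm integer states,
realistic mutational spectra or signatures, overdispersed expression
counts (Poisson, not negative binomial), and peak-calling noise in
methylation. Passing tests therefore demonstrate that each analysis
inverts the stated generative model at realistic noise levels — not that
it is robust to artefacts these simplifications exclude.

Problem sizes in the test suite and acceptance script are scaled for a
desk run: full cohorts of 19 patients for single-cohort checks, 25–50
regenerated cohorts for detection-rate estimates, 1000 genes for null
calibration, and 100,000-draw Monte-Carlo oracles for the fold-change
statistic.

## Known limitations

* Clone trees are built from cluster mean CCFs only; no cross-patient
  transfer or variational refinement of assignments is attempted.
* The CNV-burden definition reuses the arm-event log2 cutoffs; published
  burden values computed with other thresholds will differ in magnitude.
* The gene-wise weighted multi-omics score of dedicated integration
  packages is not reproduced; rank correlation plus the concordance
  screen are the supported integration statistics.
* Arm boundaries are hg19; other builds need a user-supplied arm table.
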