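---
title: "Methods: heterozygosity-corrected WGBS quantification and methylation-expression integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heterozygosity-corrected WGBS quantification and methylation-expression integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, parameter
choices, numerical conventions and limitations. It states no empirical
result that the test suite does not itself compute.

## 1. The measurement model and the heterozygosity bias

Bisulfite conversion turns an unmethylated C into T while a methylated C
stays C. At a site with true methylation level $p$ and conversion rate $c$,
a read reports "methylated-looking" (C) with probability

$$q = p + (1 - p)(1 - c).$$

At a C/T heterozygous site in a diploid, reads split between alleles. A
read from the T allele is genuinely T: it always looks unmethylated,
regardless of conversion. With a fair allele split the methylated-looking
probability halves:

$$q_{\mathrm{het}} = \tfrac{1}{2}\left[p + (1-p)(1-c)\right].$$

This is the bias the package corrects: naive quantification treats
T-allele reads as converted cytosines and underestimates $p$ at every such
site. The correction is categorical, not model-based — every cytosine
whose position carries a C/T variant (forward-strand C) or G/A variant
(reverse-strand C) with genotype het or hom-alt is *masked* and excluded
from all level computations. Hom-alt sites are masked because the
individual carries no cytosine there at all; keeping them would be pure
artefact. For the naive estimator over $N$ sites with uniform coverage the
expected genome-wide deficit is approximately
$f_{\mathrm{het}} \cdot \tfrac12 \cdot \bar p_{\mathrm{het}}$, where
$f_{\mathrm{het}}$ is the heterozygous fraction of the context's sites —
the closed form the bias-recovery test checks against.

**Context assignment.** Contexts are read from the two bases 3' of the
cytosine *on its own strand*: next base G → CG; else next-next base G →
CHG; else CHH. A cytosine is excluded only when its 3-base window runs off
the chromosome end in its own 3' direction or contains an N. (One of the
worked examples this design was drawn from excludes a reverse-strand
cytosine at the last base of a contig; that window in fact points toward
the interior and is valid, so the strand-aware rule is used.)

**Weighted levels.** All level summaries are read-count weighted:
$\sum_i m_i / \sum_i (m_i + u_i)$ over eligible sites, never a mean of
per-site fractions. Per-site inclusion requires the site to be unmasked
and covered by at least `min_coverage` reads (default 4, the conventional
WGBS floor; the source study does not state one).

## 2. Differential methylation

Replicates are pooled per condition before testing — the standard choice
for plant WGBS designs with few replicates; replicate-aware beta-binomial
models are an explicit non-goal. Per unmasked site covered ≥ 4× in both
pooled groups, a two-sided Fisher exact test is run on the 2×2
methylated/unmethylated × control/treated table; BH-FDR is applied per
context; DMPs additionally require a per-context minimum level difference
(CG 0.4, CHG 0.2, CHH 0.1 — conventional context-scaled floors, config
keys).

DMRs are called independently of DMPs (both are reported as separate
tallies): chromosomes are tiled into non-overlapping 100-bp windows; a
window with ≥ 4 testable sites is tested on its summed counts; BH runs
across windows per context; significant same-direction windows separated
by ≤ 100 bp merge into one region. The merged region's level difference
and p-value are recomputed from the merged counts; its q-value is the
*minimum* over member windows — FDR control lives at the pre-merge window
stage, and the minimum identifies the strongest constituent without
pretending a second adjustment happened. The exact test is implemented
in-package (vectorised hypergeometric enumeration with the same 1e-7
relative tie tolerance as `stats::fisher.test`) because per-site calling
visits up to millions of tables; `stats::fisher.test` is retained as the
independent oracle in the tests.

Annotation assigns each DMR the highest-priority overlapping feature
region — promoter ([TSS − 2 kb, TSS), transcriptional orientation) >
gene body > downstream ([TES, TES + 2 kb)) > distal intergenic — with
ties broken by nearest TSS, then lexicographic feature id.

## 3. Metagene profiles

Profiles pool read counts (not feature means) into 10 × 200 bp bins per
flank and 20 length-scaled body bins, oriented 5'→3' per feature and
mirrored for minus-strand features; a site on a bin boundary belongs to
the right-open bin containing it. Bins are 1-based; the mirror identity is
`bin + mirrored_bin = n_bins + 1`, which the tests assert exactly.
Upstream bin 1 is the most distal position. Bins that receive no eligible
read are reported missing rather than zero.

## 4. The synthetic world

The generator states the conditions the validation runs under; its
defaults are fixed once and are not free to move per run.

* **Genome**: 1.5 Mb over 3 chromosomes, i.i.d. bases at GC 0.40; 240
  genes (1–2 kb) and 80 TEs placed with ≥ 2 kb clearance from each other
  and from chromosome ends so every 2 kb flank is on-genome.
* **Methylome**: per-site true levels are Beta with means mCG 0.90,
  mCHG 0.70, mCHH 0.08 — the magnitudes reported for the corrected tea
  methylome — and concentration 30. Each gene additionally carries a small
  uniform per-(region, context) effect (scales 0.08/0.15/0.05 for
  CG/CHG/CHH) shared by both conditions. These latent effects exist so
  that cross-gene methylation–expression correlations are definable at
  all: coupling only fold-changes to planted DMRs cannot produce a
  level-versus-expression correlation across genes, which the validation
  requires with p < 0.01 at n ≥ 200. Expression baselines add
  $1.0 \cdot \mathrm{sign}(\text{class}) \cdot z$ per class in log2 units;
  with $z \sim U(-1,1)$ and baseline SD 1.0 the implied per-class Spearman
  correlation is $0.577 / \sqrt{1 + 5 \cdot 0.577^2}
  \approx 0.35$, clearing the p < 0.01 bar at n = 240 with a wide margin
  instead of sitting at the noise floor.
* **Heterozygosity**: every C (either strand) becomes a het C/T (G/A)
  variant independently at rate 0.01; allele fraction is fixed at 0.5
  (diploid expectation). Incomplete conversion is one global rate, 0.995
  (standard WGBS error model; the source study is silent on both).
* **Pileup**: coverage Poisson(20) per site per replicate; read-level
  methylated-looking probabilities as in Section 1 (the compound
  allele-then-conversion Bernoulli is sampled as a single binomial, which
  is distributionally identical). Samples follow the study layout —
  control-0d, treated-3d, treated-7d, 3 replicates each — with one treated
  methylome underlying both treated timepoints.
* **Planted DMRs**: 8 genes per class in each of the five
  region × context classes, |Δ| = 0.4. Directions per class are chosen to
  (a) be realisable: a hyper shift from the 0.90 CG baseline would clip to
  0.10 and be undetectable at the CG floor of 0.4, so CG shifts down and
  CHH up; and (b) balance the induced up/down expression effects: in a
  240-gene universe an unbalanced set of 8-fold changes shifts CPM
  composition by over one log2 unit and attenuates the opposite direction
  — an artefact of the miniature universe, not of the method. The CHG
  classes therefore shift up from 0.70, clipping to ≈ +0.3, still well
  above the CHG floor of 0.2; at least 20 planted regions carry the full
  0.4.
* **Expression**: the assayed transcriptome is larger than the simulated
  contigs — 1760 background genes (never perturbed, never coupled) join
  the 240 on-genome genes, so CPM library composition stays stable the way
  it does in a genome-scale experiment. log2 baselines are N(9, 1.0) plus
  the coupling above; NB counts with dispersion 0.01 across replicates
  (clean biological replicates; the DEG-caller contract's detectability
  example presumes small dispersion). A fraction 0.8 of planted-DMR genes
  is mediated: their treated mean is scaled by $2^{\pm 3}$ at both day 3
  and day 7, with sign from the class pairing rule (they are core DEGs by
  construction). A disjoint pool of 300 unmediated DEGs — about 15% of
  the transcriptome, the scale severe salt/alkali stress produces —
  receives day-specific effects, same direction on both days with
  probability 0.3, otherwise one random day, exercising
  core/period-specific/discordant classification. DEG effects are planted
  only on genes whose *smaller* group mean stays at or above 2^6 counts
  (for a down-shifted gene that is the treated mean): below that, NB
  draws of near-zero counts inflate the replicate variance and no
  3-replicate location test can see the gene, so including such genes in
  the truth table would measure small-sample power rather than pipeline
  correctness — the analogue of the universal low-count filter in RNA-seq
  practice. Three power facts shaped these values and are worth recording:
  a Welch test at n = 3 can have as few as 2 degrees of freedom whenever
  one group's sample variance is small, making its minimum attainable
  p roughly $t^{-2}$; the BH rejection threshold scales with the number of
  true effects over the number of tests; and planting large fold-changes
  on a sparse DEG set in a small universe shifts CPM composition and
  attenuates the opposite direction. A realistic DEG fraction, a stable
  composition and modest dispersion jointly put every truth-table gene
  comfortably inside the caller's power envelope, so the recovery
  criteria measure pipeline logic, not test power.
* **Determinism**: every stage derives its own seed from the master seed;
  identical configs give byte-identical bundles and run manifests
  (checksummed, asserted in the tests).

What the generator does **not** emulate: read-level artefacts (mapping
bias, PCR duplicates, M-bias), non-binary allele fractions, linked
variants, spatial autocorrelation of methylation beyond the planted
regions, and realistic gene-density landscapes. A green suite therefore
establishes the *logic* of masking, calling and integration on data whose
statistical structure matches the stated model — it does not certify
performance on real libraries.

## 5. Design decisions on open points

* **DEG caller**: a deliberately minimal Welch t-test on log2(CPM+1) with
  BH, used only so the synthetic pipeline closes end-to-end; external DEG
  tables are accepted as-is and are the intended path for real data. With
  single replicates the caller degrades to a flagged fold-change-only
  mode.
* **Mediation sign rules**: the pairing (negative-correlation classes:
  hyper↔down, hypo↔up; positive class reversed) is inferred from the
  correlation signs plus the existence of both down- and up-mediated
  tallies; it is a config-overridable rule table
  (`allow_custom_combos`), not hard-coded doctrine.
* **Discordant genes** (opposite directions at day 3 vs day 7) are
  excluded from both core and period-specific sets and reported
  separately, keeping the three parts a partition.
* **Variants that alter context bases** (e.g. a downstream T→G) do not
  remask or reassign contexts by default; only cytosine-destroying C/T
  (G/A) variants are masked, matching the correction's stated scope.
* **Flank overlap**: with 2 kb clearance between features, a gene's 2 kb
  flank can overlap a neighbour's flank; latent effects of both genes then
  mix in the shared span, slightly diluting the flank-class correlations
  (the body classes are immune). This is accepted as realistic — real
  genomes overlap regulatory regions too — and is visible as the
  flank classes' somewhat weaker correlations.

## 6. Numerical conventions

Internal coordinates are 0-based half-open everywhere; conversion happens
exactly once, at file boundaries (CX reports and VCF are 1-based, GFF3
1-based closed, BED native). Weighted levels of empty site sets are
errors, not zeros. Fisher ties are resolved with a 1e-7 relative
tolerance, matching `stats::fisher.test`. BH is applied per context (and
per window set for DMRs). Zero-coverage CX rows are preserved through the
pipeline — they carry context information and keep the site universe
conserved, which the tests assert.
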