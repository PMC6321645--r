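---
title: "Homoeolog-aware bulked segregant analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homoeolog-aware bulked segregant analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bulked segregant analysis (BSA) localizes a selected locus by sequencing two
pools of individuals drawn from a segregating population — carriers and
non-carriers of the target allele — and contrasting their allele frequencies.
At a biallelic SNP site the **SNP-index** is the fraction of reads carrying
the alternate allele, `K / D` for `K` alternate reads out of depth `D`. The
**delta-SNP-index** is the carrier-bulk index minus the non-carrier-bulk
index: near zero at unlinked sites, near one at sites tightly linked to the
selected locus.

In an allopolyploid such as synthetic hexaploid wheat (AABBDD), RNA-seq reads
from the A and B subgenomes align to D-genome transcript references and
masquerade as SNPs. These **homoeologous polymorphisms** are fixed subgenome
differences, not segregating alleles; they dilute the frequency signal and,
left unrecognized, flood the candidate list. polyBSA implements the
homoeolog-aware variant of BSA: it classifies every site as D-genome-specific
allelic variation, homoeologous polymorphism, or unclassified before
averaging the delta-SNP-index, using two evidence sources:

* a **parental-pairwise SNP list** — sites known to differ between the two
  diploid D-genome donor accessions (parents "A" and "B"); and
* **tetraploid-reference alignments** — reads of an AABB tetraploid aligned
  to the same D transcript references; the tetraploid has no D genome, so any
  SNP it shows is homoeologous.

A site in the pairwise list only is `D_SPECIFIC`; in the tetraploid calls
only, `HOMOEOLOGOUS`; in neither, `UNCLASSIFIED`. A site carrying both kinds
of evidence defaults to `HOMOEOLOGOUS` (a site polymorphic in tetraploid
reads cannot be distinguished from homoeologous signal); the precedence is
configurable and both flags are always reported.

## The experimental design being simulated

The synthetic-data module reproduces the structure of the emulated
experiment: an F1 between two D-genome donors is advanced by single-seed
descent with heterozygote selection at the causal locus through F4; two
sibling F5 populations are founded by independently drawn heterozygous F4
plants (offspring of one F3); from each population, one bulk of ten
carrier-homozygotes and one of ten non-carriers is formed. Each bulk is
aligned against both parents' transcript references, giving eight
bulk-by-reference alignment pairs; each population contributes a
delta-SNP-index per reference, four values per site, and the per-site
average of the available values is the mapping statistic.

Under selfing with no selection, a locus heterozygous in the F1 is
homozygous in generation *g* with probability `1 - (1/2)^(g-1)` — 87.5% for
an F4 plant (`expected_homozygosity(4)`). This is why unlinked
D-genome-specific sites frequently show a delta of exactly zero: both bulks
of a population descend from one F4 founder, and wherever that founder is
already fixed the two bulks are identical. The delta distribution is
therefore zero-inflated and "not continuous", with drift noise confined to
the minority of loci where a founder was still heterozygous.

## Polarization: averaging across two references

The four delta values at a site are computed against two different
references whose reference/alternate orientation swaps at parent-divergent
sites; averaged naively they cancel. All indices are therefore first
**polarized** to the donor-parent (carrier-allele) frequency: unchanged when
the alignment reference is the non-donor parent, `1 - index` when it is the
donor parent. The same swap is why the non-redundant merge treats a site's
identity as its unordered allele set: two tables reporting `A→G` and `G→A`
at one genome coordinate describe the same biallelic site, and only a third
base makes it multi-allelic (multi-allelic sites are kept but excluded from
delta averaging by default, because the SNP-index is defined for a single
alternate allele).

Missing data follow an available-pairs rule: an index is missing (not zero)
below the depth floor, a delta is missing if either input is, and the
per-site average uses the non-missing values, with `n_informative`
recorded. The alternative (treating missing as zero) would shrink averages
toward zero in proportion to coverage, confounding depth with signal.

## The synthetic genome and its site types

`genome_config()` defines seven 600-Mb chromosomes ("1D".."7D") with 4000
SNP sites each, a causal locus at 82.55 Mb on 2D, and a 81.8-83.3-Mb target
interval on 2D holding 20 extra sites (fine-mapped target intervals are
SNP-dense relative to a desk-scale uniform background). Sites come in four
types, chosen so that the three classification categories have well-defined
ground truth:

* **P** (25%): parent-divergent, with no alignable/expressed homoeologous
  copy — true D-specific allelic variants; contamination `rho = 0`.
* **H** (55%): parents identical, homoeolog divergent — true homoeologous
  polymorphisms, visible in bulks through contamination and in the
  tetraploid sample directly.
* **B** (10%): divergent both between parents and versus the homoeolog
  (homoeolog base fixed to the parent-B allele to keep sites biallelic
  against either reference) — both evidence flags, homoeologous by default
  precedence.
* **U** (10%): homoeolog divergent but the homoeologous copy is not
  expressed in the tetraploid reference library (expression is
  tissue- and library-dependent) — contaminated in bulks yet invisible to
  the tetraploid evidence, hence truly unclassifiable.

Homoeologous contamination `rho` is drawn per site from Beta(2, 5) at
homoeolog-covered sites, giving the site-to-site variability that makes
homoeologous indices hover near `rho` in both bulks and cancel in the
delta. Classification identifiability rests on the P/U coverage asymmetry,
which is the biological reason the tetraploid filter works at all: a
homoeolog that never aligns cannot leave tetraploid evidence.

## Depth and crossover models

Sequencing depth per site and library is negative binomial (mean 30,
dispersion 5 per run) — overdispersed, as RNA-seq coverage is. Each bulk
library is sequenced in **two runs whose alignments are merged**, matching
the emulated design, so bulk depths are the two-run sum (NB with mean 60,
size 10); the tetraploid library is a single run. The merged-depth choice
also sets the noise floor of the averaged delta: with four informative
pairs the homoeologous class settles at a mean absolute delta of about
0.03-0.045, comfortably "approximately zero".

Crossovers per chromosome per meiosis are Poisson with mean 1.0, no
interference. Their positions are **distally concentrated** by default: 90%
fall in the two terminal windows of 10% of the chromosome each, the rest
uniform. Large cereal chromosomes recombine almost exclusively in their
distal regions; a uniform-position model at this physical scale would erode
the selected heterozygous block around the causal locus far faster than the
real system does, and with it the chromosome-wide delta signal that makes
the localization test decisive. With the causal locus just proximal to the
distal window, the selected block reliably spans a large fraction of the
causal chromosome, while unlinked chromosomes are either fully fixed
(delta exactly zero) or carry whole-chromosome drift blocks of small
magnitude. A `"uniform"` density remains available.

Selection during line advancement is applied at the causal site only — the
minimal faithful version of selecting on a marker-delimited region. One
consequence is honest stochasticity: in a few percent of pedigree draws the
heterozygous block around the causal locus collapses to a narrow interval,
the chromosome-wide signal weakens, and the all-pairs rank test can fail to
separate the causal chromosome from the strongest drift chromosome. The
real experiment is a single draw of the same process.

## Calling, anchoring and accounting

SNP calling applies the emulated thresholds: minimum depth 10, minimum
alternate fraction 0.1, both boundaries inclusive; these are configurable
and monotone (raising either never adds sites). Calls are made in
transcript coordinates and then anchored to genome coordinates through the
anchoring table (one genome location per transcript position, strand `+`/`-`
with bases reverse-complemented on `-`); sites without an anchor row are
counted separately, and anchor collisions with conflicting reference bases
are excluded and reported. Coordinates are 1-based and intervals closed
throughout. The per-stage counts (input, called, anchored, unanchored,
conflicts) are kept on the scan object and must reconcile.

## Localization: the Steel-Dwass all-pairs test

D-specific sites are grouped by chromosome and every chromosome pair is
compared with the Steel-Dwass procedure: joint midranks with tie-corrected
variance, statistic `t = (R_i - m(m+n+1)/2) / sqrt(Var)`, and `sqrt(2)|t|`
referred to the studentized range with `k` groups and infinite degrees of
freedom. Ties are severe in this application (the zero spike), which is why
the tie-corrected variance matters. An exact mode enumerates the
permutation distribution of the pairwise statistic for small groups; it
reports the unadjusted two-sided permutation p-value, whereas the
asymptotic mode carries the studentized-range family adjustment — the two
agree as tests of a pair but differ by the multiplicity correction, which
is the documented semantics of each mode. No sliding-window smoothing is
applied; the per-site averages are the plotted and tested quantities.

## Candidate selection and dCAPS design

Within the target interval (closed, 81.8-83.3 Mb by default), D-specific
sites with averaged delta strictly greater than 0.38 are candidates, ranked
by delta. Each candidate is converted, where possible, into a CAPS or dCAPS
assay: the design searches both strands and all placements of each enzyme's
recognition window over the SNP, introduces at most one primer mismatch
(never at the SNP, never at the 3'-terminal base, confined to the 3' half
of the primer — standard assay practice), and accepts a design only if
in-silico digestion of the two allelic amplicons yields different fragment
multisets, which is the defining dCAPS property and the only validation
used. Natural CAPS designs (zero mismatches) are preferred. Primer
thermodynamics are reduced to a GC-content preference (40-60%); full
melting-temperature modelling is out of scope. Digestion cuts at the 5'
start of every IUPAC match on either strand — one fixed convention for all
enzymes, sufficient for fragment-length discrimination though not for
sticky-end chemistry. The built-in enzyme table (StyI `CCWWGG`, HpaII
`CCGG`, HinfI `GANTC`, and a few additions) is a plain data frame and
user-extensible.

## Linkage validation

Selected markers are genotyped in a freshly simulated F2 of 788 individuals
and placed by two-point maximum likelihood: EM over the nine codominant
two-locus genotype classes (the double heterozygote mixes parental and
recombinant gamete pairs), LOD against independence, and map distances by
Kosambi (conventional in wheat mapping; Haldane available). The
recombination fraction between two positions follows from the crossover
model, so simulated estimates can be checked against a closed form.

## Problem sizes and numerical choices

The shipped tests run the full default experiment (7 x 600 Mb, ~28,000
sites, 40 bulked plants, 10 libraries) once, in roughly 15 seconds, and use
a three-chromosome, 2400-site experiment for most property checks; the
Monte-Carlo checks use 200 replicate pedigrees and 10,000 selfing loci.
EM convergence tolerance is `1e-8` on the recombination fraction with the
estimate clamped to `[1e-9, 0.5]`; permutation enumeration is capped at
2e5 splits; exact-zero variance pairs return `t = 0, p = 1`. Seeds fan out
deterministically from one user seed per stage, so identical seeds
reproduce byte-identical fixture bundles.

## What the simulation does not capture

Read-level artefacts (mapping bias, base-call errors, indels), expression
differences between alleles, more than one contaminating homoeolog base per
site, genotype-by-environment effects on the selected phenotype, and
QTL-seq-style confidence envelopes for the delta under the null are all out
of scope. Passing the shipped tests therefore shows that the analysis
recovers what this generative model encodes — frequency signal under
selfing, selection, drift and homoeologous contamination — not that it is
robust to alignment artefacts in real read data.
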