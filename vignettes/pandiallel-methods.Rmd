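---
title: "Models and methods behind pandiallel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pandiallel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pandiallel)
```

`pandiallel` implements the computational layer of a multi-parental
trait-dissection framework: a core panel of fully inbred founders whose
genomes have been assembled and compared against one reference, crossed in
all pairwise combinations, with the resulting variant catalogue projected
onto every cross. This vignette records the models, conventions and the
genuinely open design choices, in enough detail that each number the
package produces can be traced to a stated rule.

## Variant integration

### Input dialect and coordinates

Per-accession calls arrive as Assemblytics-style TSV tables (header
optionally prefixed `#`; columns `reference`, `ref_start`, `ref_stop`,
`ID`, `size`, `strand`, `type`, gap sizes, query coordinates, method).
Six types are retained and normalized — insertion, deletion, and the
repeat/tandem expansion/contraction subtypes; anything else (inversions,
translocations in other dialects) is dropped with a logged count, because
only InDel-like variation is projected onto crosses. Internally all
coordinates are 0-based half-open (unambiguous arithmetic: a deletion spans
`start < end`, a pure insertion has `start == end`); the VCF writer
converts back to 1-based.

### Allele-to-site convergence

Real assembly panels report both allele counts and a smaller number of
*sites* after merging, but the merging rule itself is rarely stated. We
use the standard multi-sample SV-merging construction and expose every
tolerance:

1. alleles cluster into one site when they share chromosome and breakpoint
   polarity (insertion-like vs deletion-like) and their **start**
   breakpoints chain within `breakpoint_tol` (default 10 bp,
   single linkage). The start breakpoint anchors the locus, so a 50-bp and
   a 300-bp deletion at the same position converge to one multi-allelic
   site — the behaviour the multi-allelic site counts of assembly panels
   imply;
2. within a site, member alleles share an alternate allele when their
   sizes agree within `size_similarity` (relative, default 0.1) or
   `breakpoint_tol` bp absolute, whichever is larger — again single
   linkage, with the representative size taken as the group median and
   alternate alleles ordered by size;
3. exact duplicate calls are deduplicated; when one accession contributes
   two distinct alleles to a site (tandem nearby calls) the larger is kept
   and logged.

Alleles are canonically sorted before clustering, making the result
independent of input row order; the test suite checks the whole
construction against an exhaustive graph-clustering oracle on random
pools. Because single linkage only merges as tolerance grows, the site
count is monotone non-increasing in `breakpoint_tol` (also tested). We do
not attempt to reproduce any published site count from real data — those
depend on the unpublished merging rule and the data themselves.

The short-InDel class is 15–2000 bp **inclusive**. Published descriptions
of such catalogues vary between a 10- and a 15-bp lower bound; we follow
the methods-grade statement (15 bp, the PCR-markerable range) and expose
both bounds as arguments.

## Diallel projection

`enumerate_crosses()` returns the n(n−1)/2 unordered pairs in
lexicographic canonical order (25 founders → 300 crosses; 20 → 190). A
site is polymorphic in a cross iff the parents carry different allele
indices, so alt-vs-different-alt counts at multi-allelic sites; analyses
restricted to bi-allelic sites set `biallelic_only = TRUE`. Because
founders are inbred and assembly-based calls carry no explicit missing
state, an absent call is reference (index 0); this is the one place where
a no-call and a true reference allele are indistinguishable, and it is
logged as a convention rather than patched. Per-bin totals use 1-Mb
fixed-width bins from the chromosome start (the bin width used in binned
polymorphism figures is typically unstated; 1 Mb is exposed as an
argument). Parental genetic distance is 1 − identity-by-state over shared
non-missing markers — the simple distance used with genome-wide SNP
genotyping panels.

## Pan-variant analysis

A site's carrier count is the number of accessions holding any alternate
allele; *rare* means exactly one carrier. The rarefaction curve draws
random founder orderings and counts cumulative distinct sites; with N ≤ 6
founders all N! orderings are enumerated instead (the default flips
automatically). Percentile "boxes" on such curves are read as **central**
intervals holding 50% and 99% of permutation values, i.e. the 25th–75th
and 0.5th–99.5th percentiles, computed with linear interpolation between
order statistics (R quantile type 7) — stated here for bit
reproducibility, since figure legends rarely define them. The permutation
mean is validated against the closed form

E[S(g)] = Σ_s (1 − C(N−c_s, g) / C(N, g)),

the hypergeometric probability that a site with c_s carriers is missed by
a random g-subset. The saturation point is the smallest g whose *mean*
curve reaches the target fraction of the pan total; whether published
"g genomes capture x%" statements refer to the mean curve or one ordering
is ambiguous, and we declare the mean.

## Segregation machinery

F2 expectations come from exhaustive enumeration of equiprobable gamete
combinations (4 cells for one locus, 16 for two). Epistasis is modelled as
*genotype-class masking*: when the masking locus carries the declared
genotype class (e.g. homozygous recessive), the masked locus's phenotypic
contribution is forced to its recessive state. This single rule reproduces
the classical modified ratios — a dominant locus masked by a recessive
second locus segregates 9:7 — and matches the pattern where the
homozygous-recessive marker class is uniformly wild-type while carrier
classes remain mixed.

Goodness of fit uses the chi-square statistic without Yates correction
(expectations come from an explicit model, not from estimated marginals),
df = classes − 1. An exact multinomial p (total probability of outcomes no
more probable than the observed one) is computed when feasible (n ≤ 200,
≤ 4 classes, by composition enumeration) and selected automatically when
any expected count drops below 5. Contingency tables for marker–trait
association switch to Fisher's exact test under the same small-expectation
rule; Fisher tests are two-sided without mid-p correction (conservative,
standard).

The allelism test treats any wild-type F2 segregant as an exception
(tolerance 0 by default; a phenotyping-error allowance is an argument) and
reports the Clopper–Pearson upper bound on the complementation segregation
fraction: with zero exceptions in n, fractions above 1 − α^(1/n) are
excluded (n = 100 → ≈ 3%).

Mode of inheritance uses the dominance degree d/a (a = half the parental
difference, d = F1 deviation from mid-parent) with declared bands —
|d/a| ≤ 0.2 additive, ≤ 0.8 partial dominance, ≤ 1.2 dominant, beyond that
over-/underdominant by sign — and a significance gate: an F1 not
significantly different from mid-parent (one-sample t-test, parent means
treated as known) is called additive. Published inheritance-class figures
rarely define their bands; ours are configuration, not inference. Tail
selection takes the families in the q-tail of **both** generations
(`floor(q·n)` per generation, stable tie-break by value then family
identifier), giving the expected q²·n joint tail under independence and
the full tail under perfect correlation.

## Haplotype mapping

Gene haplotypes are *exact-match* groups of accession allele vectors — no
mismatch clustering, so a "three main haplotypes" structure on a fixture
is reproduced structurally, never by threshold tuning. Accessions
exceeding the missing-call budget are dropped; an accession with missing
calls joins a group only when compatible with exactly one, otherwise it is
flagged ambiguous (compatible with several) or founds its own group
(compatible with none).

Substitution mapping assumes a declared single-locus model (default
dominant mutant allele from parent B; switchable). Candidate locus
positions are the markers and the gaps between adjacent markers; a
candidate is feasible when every line's phenotype is explained by its
genotype at (or flanking) that position. The reported interval is bounded
by the markers just outside the feasible region — with no recombinants it
spans the whole region, and with no feasible position the lines violating
the best candidate are reported as error/non-parental candidates. An
exhaustive interval-scan oracle over all single-breakpoint configurations
of up to 8 markers verifies that error-free data always bracket the causal
position.

Coding effects are classified strand-aware against a declared gene model:
CDS SNPs are translated codon-locally (checked against a full-CDS
retranslation oracle and a reverse-complement symmetry test), CDS InDels
are frameshift iff length mod 3 ≠ 0, intronic positions within 2 bp of an
internal CDS junction are splice-site-adjacent (a declared rule — pooled
"synonymous or splice-site" tallies in the literature do not pin down the
window), transcript positions outside the CDS span are UTR, and InDels
straddling a CDS boundary are flagged unclassified rather than guessed.

## The synthetic generator

The generator exists so that every downstream stage is testable without
external assemblies; its defaults are the study conditions the analyses
assume, chosen once:

* 25 founders split 17/8 between two subpopulation labels, mirroring a
  melon-like core collection (17 ssp. *melo*-type; the feral accession is
  grouped with the smaller *agrestis*-like cluster for the two-label
  emulation), over 12 chromosomes × 30 Mb — the melon karyotype at reduced
  scale;
* InDel sizes log-uniform on 15–2000 bp (assembly-called InDel size
  spectra are heavy-tailed; log-uniform is the minimal one-parameter-free
  choice on the declared range);
* singleton fraction 0.47 among non-divergent sites for short-InDel
  scenarios ("almost half rare" is the observed skew for bi-allelic short
  InDels) and 0.63 for the large-SV scenario; shared sites draw carrier
  counts from a geometric decay (parameter 0.35), keeping the spectrum
  low-frequency-skewed;
* a small fraction (default 0.02) of sites fixed-different between the
  subpopulations, emulating subspecies-differential rearrangements.

Crosses recombine under the **Haldane** map function (no interference) —
interference is irrelevant to every analysis tested here, and Haldane
keeps the inverse closed-form, which the tests use to recover a 10-cM
distance from simulated F2s within three standard errors. `"RIL-k"`
denotes the F_k generation reached from the F2 by single-seed descent
(k − 2 selfing rounds), so `"RIL-7"` is a classical F7 RIL population with
expected residual heterozygosity 0.5^(k−1) ≈ 1.6% — the convention under
which the k = 7 decay test is asserted. Family structure within RIL
generations (which F2 family a line descends from) is not modelled; lines
are independent single-seed-descent chains. Trait noise is Gaussian on the
latent scale and binary traits are thresholded, which expresses
mottled/resistance-type dichotomies without extra parameters; epistatic
masking and locus effects are applied before noise, noise last.

What the generator does **not** emulate: linkage disequilibrium between
variant sites and population structure beyond the two-label split,
assembly errors and missing calls, reference bias, segregation distortion,
and genotyping error in marker panels. Passing tests therefore demonstrate
the correctness of the algorithms under clean Mendelian assumptions, not
robustness to real-data pathologies.

## Numerical and scale choices

Every stochastic operation requires an explicit integer seed and restores
the caller's RNG state, so identical seeds give byte-identical output (the
fixture-bundle writer is checksum-stable). Problem sizes used by the test
suite and the acceptance script — 10^4 individuals for segregation-ratio
recovery, 10^4 null replicates for type-I calibration (at n = 100 per
goodness-of-fit replicate and n = 200 per contingency replicate, sizes at
which the chi-square approximation's exact size sits within Monte-Carlo
error of the nominal 5%), 1000 permutations for the 25-founder rarefaction
check, 1000 simulated panels for substitution-mapping coverage — were
chosen as the smallest sizes at which the binomial/Monte-Carlo tolerances
stated with each check are meaningful. Degenerate inputs (constant
distances or trait values, all-missing markers, zero-expectation classes
with observed counts) return flagged `NA`s or switch to exact tests with a
warning rather than erroring mid-pipeline.
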