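---
title: "Phasing CNV-carrying haplotypes in nuclear families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasing CNV-carrying haplotypes in nuclear families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvphase)
```

## The problem

SNP genotyping arrays report, inside a copy-number variant (CNV), not the
usual two-letter genotype but a *multiploid* genotype: the allele multiset
pooled over both homologous chromosomes. A marker inside a heterozygous
duplication may read `ABB`; inside a hemizygous deletion, `A`; inside a
homozygous deletion, `–`. Callers such as QuantiSNP, PennCNV and the
Birdsuite tools emit these CNV genotypes together with diploid copy-number
(CN) calls, but they do not say how the allele copies are distributed over
the two homologs. `cnvphase` answers that question deterministically for
nuclear families: it reconstructs, for every family member, the *normal*
(haploid copy number cn = 1) and *CNV-carrying* (cn = 0, 2 or 3)
haplotypes across a CNV region, identifies which parental haplotype each
child received, and recognises the simplest non-Mendelian transmissions —
de novo deletions, de novo intra-/inter-chromosomal duplications, and
uniparental iso- and heterodisomy — when Mendelian inheritance cannot
explain a child.

## The model

A CNV region is a genomic interval over which every family member has a
constant diploid copy number (2 unless a call says otherwise), with an
ordered set of markers. The observed data for member $i$ at marker $j$ is
an allele multiset $G_{ij}$ over $\{A, B\}$ with $|G_{ij}| = CN_i$.

A *haplotype* is a haploid copy number $c \in \{0,1,2,3\}$ plus one allele
tuple of size $c$ per marker. A *parent phase* is an unordered haplotype
pair whose per-marker multiset union equals the parent's observed
genotypes; the allowed copy-number splits are fixed by the parent's CN
(CN 0 → 0+0, 1 → 0+1, 2 → 1+1, 3 → 1+2, 4 → 1+3 or 2+2; rarer splits
such as 0+2 or 0+3 can be enabled through `phasing_config(cn_splits =)`).
A *gamete formation scheme* says how one parental gamete was formed:

* **Mendelian** — one haplotype transmitted unmodified;
* **de novo deletion** — a uniform copy-number reduction of one source
  haplotype (any per-marker sub-multiset of that haplotype);
* **de novo duplication** — one extra allele copy per marker added to a
  source haplotype, drawn at every marker either from the source
  haplotype's own alleles (intra-chromosomal) or from the other
  homolog's (inter-chromosomal), capped at cn 3;
* **uniparental disomy** — the child receives two copies of one
  haplotype (isodisomy) or both haplotypes (heterodisomy) of a single
  parent and nothing from the other; this is a pairing-level event.

The scheme is constant across the region for each (child, parent) but may
differ between children of the same family.

### Scoring and ambiguity

Every combination of parental phases and per-child schemes is scored
lexicographically by *(number of unexplainable member × marker genotypes,
number of non-Mendelian events)*, and all score-minimal solutions are
reported. Because children are conditionally independent given the two
parental phases, the family optimum decomposes into per-child optima,
which the engine exploits; it also tries Mendelian pairings first and
expands the non-Mendelian space only for children Mendelian pairings
cannot fully explain — a pure optimisation, since a zero-unexplained
Mendelian child scores (0, 0), which nothing can beat. Solutions
identical up to relabelling a parent's two haplotypes (or permuting
identical haplotypes, or attributing a gamete to either of two equally
compatible sources) are collapsed to one canonical representative. A
region is *unambiguous* when exactly one solution remains; otherwise all
co-optimal solutions are returned, which is the honest answer when, for
example, only monomorphic genotypes are present or a de novo deletion
could sit on either of two identical parental haplotypes.

Unexplainable cells are counted per (member, marker); every non-Mendelian
gamete counts one event, and one uniparental disomy counts one event per
child by default (`count_upd_as = 2` makes it two). Ties between
co-optimal solutions are broken only for output order, by canonical
serialisation — the method deliberately does not prioritise one
non-Mendelian event kind over another by assumed frequency.

### De novo annotation

For de novo schemes in a reported solution, the parent-of-origin is the
scheme's parent, flagged *undetermined* when the two parents' phases are
identical at every retained marker (then the mirrored solution is also
co-optimal and the attribution carries no information). A duplication is
typed intra-chromosomal when every extra allele is drawable from the
source haplotype and at least one marker excludes the other homolog,
inter-chromosomal in the mirrored case, and ambiguous when both
explanations fit everywhere. The intra/inter/ambiguous subtype is a
deterministic annotation of a solution's content, not part of solution
identity.

## Upstream filters

The pipeline reproduces the standard array-CNV quality ladder before any
phasing:

* **sample QC** (PennCNV metrics): pass iff LRR\_SD ≤ 0.25, BAF\_SD ≤
  0.05, BAF\_DRIFT ≤ 0.002 and |GCWF| ≤ 0.04 (all inclusive, exactly as
  printed by the tool);
* **caller intersection**: two callers' raw calls are merged per
  individual as the coordinate intersection of same-type (gain/loss)
  overlapping calls (≥ 1 shared bp, 1-based inclusive coordinates); on a
  same-type cn discordance the primary caller's cn is kept and the
  discord logged;
* **external confirmation** (optional): the same overlap-and-type rule
  against a validated call set, keeping the internal coordinates;
* **call filters**: autosomes only; length ≥ 1000 bp and LBF ≥ 5, both
  boundaries strict on the removal side ("shorter than 1000 bp", "less
  than 5");
* **family convergence**: overlapping member calls merge into one region
  whose interval is the intersection of the carrier calls; the region is
  dropped if any family member has a raw single-caller call overlapping
  it (so non-carriers are proven call-free in both callers), if ≥ 2
  carriers' calls share fewer than 3 markers, or if a member has
  overlapping calls of different cn (a mosaic-like state the
  constant-CN model cannot phase);
* **marker selection**: a marker is dropped family-wide when any member
  has a no-call or a call probability below 0.95 (strict), when its
  allele union over the family is monomorphic, or when a member's
  genotype size contradicts that member's regional CN. A region left
  with no markers is retained, flagged `uninformative`: copy numbers
  alone can still force a unique transmission.

## The transmission and variability analytics

Transmissions are counted only in unambiguously phased single-carrier
(group A) regions: one event per child per region, *cnv* when the gamete
from the carrier parent has cn ≠ 1, *normal* when cn = 1; non-Mendelian
gametes are not transmissions and are skipped. Counts are stratified by
deletion/duplication and CNV length (half-open bins [0,10kb), [10,30kb),
[30,100kb), [100kb,∞)). Deviation from the Mendelian 50:50 expectation is
tested with Pearson's chi-square; the Yates continuity correction is the
default because it reproduces the reference p-values for the published
group-A count pairs (580/671 → 0.011, 70/98 → 0.037) where the
uncorrected statistic gives 0.010/0.031 — `correct = FALSE` provides the
uncorrected test. Per-bin p-values are Bonferroni-adjusted (the most
conservative choice; Holm and BH are available). Double-carrier (group B)
regions are excluded from the bias analysis: when both haplotypes of a
parent carry the variant, a normal haplotype cannot be transmitted at
all.

For allelic variability, every parental haplotype with cn ≥ 2 in a
phased solution is classified as *between*-informative when the parent's
two haplotypes differ in allele *types* at ≥ 1 marker (a pure copy-count
difference does not make a marker polymorphic between haplotypes) and
*within*-informative when the gain haplotype carries a heterozygous
tuple at ≥ 1 marker — the latter demonstrates alternative allelic copies
inside one multi-copy haplotype.

## The simulator

`simulate_dataset()` draws one CNV region per family. Defaults emulate a
family SNP-array study: 60/20/12/5/3% of families with 1–5 children;
3–8 usable markers per region; carrier configurations 70% single-parent
deletion, 13% + 5% single-parent duplication (haploid cn 2 or 3), 4.5%
double-carrier deletion, 7.5% no carrier; B-allele frequency 0.4 shared
by all copies (no LD model — informativeness is what matters here);
non-Mendelian event probabilities per child of 2% (deletion), 1% + 1%
(intra/inter duplication) and 0.5% + 0.5% (iso-/heterodisomy). At most
one non-Mendelian event is drawn per child; a drawn event is *redrawn*
when the resulting child genotypes are also explainable by purely
Mendelian transmission of some parental partition (such an event is
unobservable in principle), which is what makes "the simulated truth is
among the co-optimal solutions" a meaningful, testable contract. Noise
(no-calls, low-confidence cells, single-allele flips) is injected after
the truth is fixed. One root seed drives everything; per-family
sub-seeds are derived by counter so a family's region does not depend on
how many families precede it.

What the simulator does not model: linkage disequilibrium between
markers, allele-frequency differences between markers, BAF/LRR signal
noise structure, caller disagreement, or genuinely mosaic copy numbers.
Passing the recovery suite therefore demonstrates the correctness of the
combinatorial engine under its model assumptions, not array-level
performance on real intensity data.

## Numerical and design choices

* Coordinates are 1-based and inclusive; overlap means ≥ 1 shared bp.
* Genotype strings canonicalise A-before-B; `-` encodes CN 0; `NC` a
  no-call. Engine arithmetic runs on (size, B-count) integer pairs.
* Haploid copy numbers are capped at 3 and diploid at 4; de novo gains
  add one copy per marker (`allow_multistep_dup` enables two-step
  gains).
* The search is exhaustive under a budget (`max_combinations`, default
  10^6 enumeration steps); beyond it the region errors rather than
  silently approximating.
* The brute-force oracle re-implements the whole search over explicit
  character multisets, enumerating ordered splits and the full
  non-Mendelian space with no fast paths; engine and oracle share only
  the canonical serialisation used to compare solution sets.
* Verification scales used by the test suite: 500 seeded event-rich
  regions (≤ 4 markers, CN ≤ 4, 5% genotype noise) for engine/oracle
  set equality; 1000 noise-free default-parameter regions for truth
  recovery; 10,000 replicates of 150 events for the type-I-error
  calibration of the 50:50 test (the corrected test's exact size at
  n = 150 is 0.041).

## Known limitations

Regions with many heterozygous markers and high copy numbers grow
combinatorially and may hit the search budget — subsampling markers is
the intended recourse. Recombination within a region, mosaicism,
population-LD-based phasing and sex chromosomes are out of scope. When
all markers are filtered away, distinct copy-number-consistent phases
can remain co-optimal, and the region is reported ambiguous rather than
resolved by convention.
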