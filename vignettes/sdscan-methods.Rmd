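---
title: "Methods: pooled-sex scanning for presence/absence sex determiners"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-sex scanning for presence/absence sex determiners}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdscan)
```

## The model

`sdscan` targets monofactorial XX/XY sex determination mapped with
pooled-sex sequencing. Each pool — tens of same-sex individuals
sequenced as one library — is genotyped as a *single diploid sample*.
Under that reduction, a sex-linked causative site produces one of three
characteristic pooled-genotype patterns:

* **Y-specific allele** (`Y_ALLELE`): all X chromosomes carry one
  allele and the Y another, so the female pool is called homozygous and
  the male pool heterozygous.
* **X-null locus** (`X_NULL`): the locus exists only on the Y. Female
  pools have no reads at all (`./.`), male pools are called homozygous
  (their X contributes nothing).
* **Y-null locus** (`Y_NULL`): the mirror case — the locus is missing
  from the Y, females are heterozygous, males homozygous.

Homozygosity is allele-agnostic (`0/0`, `1/1`, `2/2` all qualify): at
an X-null site, one species' males may be called `0/0` against the
reference and another's `1/1`, yet both represent the same biology.
The three predicates are mutually exclusive by construction, which the
test suite verifies by exhaustive enumeration against an independent
predicate evaluator.

The power of the method comes from the *cross-species concordance
filter*: a causative variant of a system shared by several species must
fit the **same** model in **every** species. In the bundled worked
example this reduces tens of thousands of window variants to six, and
in synthetic windows it reduces hundreds of decoys to exactly the
planted set.

Two annotations qualify surviving sites without filtering them:

* **Male-allele conservation** compares the unordered pair of male
  allele *sequences* across species (indices are not comparable between
  per-species VCFs at multiallelic sites). A site can be concordant yet
  non-conserved — e.g. a tri-allelic site where different species'
  males carry different alternative bases. Such sites stay in the
  report, flagged.
* **Region labels** from 1-based inclusive gene intervals; boundary
  positions belong to the interval, unannotated positions are
  `intergenic` with nearest flanking genes.

## Coordinate, genotype and file conventions

All coordinates are 1-based inclusive; no half-open interval appears in
any public contract. Amplicon size is therefore `end − start + 1`.
Genotype separators `/` and `|` are equivalent; half-missing calls
(`./0`) collapse to the null call, so a pool call is either fully
observed or fully missing. The spanning-deletion ALT `*` is an ordinary
allele. FILTER and QUAL are ignored by default (model filtering is the
filter; a `pass_only` flag exists). Non-diploid GT fields are rejected:
the pooled-genotype models are defined on diploid calls only.

## Tunable parameters

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| window | LG1:25,400,000–28,700,000 | bp | the mapped critical sex region on the *O. aureus* assembly |
| `female_ceiling` | 0 | reads | "male-specific" means literally no female reads |
| `male_floor` | 3 | reads | mirrors the three-read detection limit |
| `min_length` | 200 | bp | suppresses short stochastic coverage gaps |
| `merge_gap` | 100 | bp | bridges isolated cross-mapping positions |
| `word_size` | 64 | bp | exact-seed proxy for high-identity BLASTN matching |
| `min_reads` | 3 | reads | presence call threshold in genomic libraries |
| barcode threshold | 1 | % | conventional cox1 interspecies floor |

The depth-track thresholds beyond "no female reads" are package
decisions (the discovery observation was qualitative); they are
configurable and the detector is provably monotone in them — tightening
either threshold never enlarges an interval, which is property-tested.

## Electronic PCR

A read is a hit when it shares at least one exact `word_size`-mer with
the probe on either strand; each read counts once, matching how
detection is quoted in read units. This deliberately approximates
seeded alignment without extension or scoring: for presence/absence of
a near-identical locus, exact long words are a faithful, deterministic
proxy. Ambiguity codes never match. RPKM uses the conventional
definition `hits × 10⁹ / (total_reads × probe_bp)` with *total supplied
reads* in the denominator (whether a mapped-read denominator was used
upstream is unknowable from a printed value alone; the choice is
documented here). The duplex genotype caller returns `yy?` — with the
query mark — when only the y-form probe amplifies, because a diploid
assay cannot distinguish yy from xy allele dropout.

## Fisher exact test

`fisher_two_sided` enumerates all 2×2 tables with the observed margins
using log-factorial (`lgamma`) arithmetic and sums the probabilities of
tables no more probable than the observed one (probability-mass
two-sided criterion, the dominant convention), with a relative tie
tolerance of 10⁻⁷ against floating-point equality. `stats::fisher.test`
serves as an independent oracle in the tests over all margins with
N ≤ 40 — never as the implementation, so the dual-route check stays
meaningful. Reported p-values keep full precision; 4-decimal rounding
(with a `<0.0001` floor) happens only at report formatting. Note that
two of the bundled family tables print differently in their original
report than exact enumeration gives (their full-precision values are
~10⁻⁸ and ~2×10⁻⁵); the package reports the computed values.

## Barcode distances

Distances are uncorrected p-distances: mismatching comparable columns
over comparable columns, where a column is comparable only if both
sequences carry an unambiguous base (gaps and ambiguity codes are
excluded from numerator *and* denominator — the treatment upstream
tools used for the printed figures is unstated, so the stricter
exclusion is adopted and documented). Pairs are flagged when the
declared species relation contradicts the distance call in either
direction: different labels below threshold (misidentified duplicates)
or one label above it (a cryptic split). No multiple-hit correction is
applied because the reported quantities are raw percent differences,
and no trees are built.

## The synthetic-data generators

The generators' defaults are the study conditions: three species × two
pools, the 25.4–28.7 Mbp window, six planted concordant sites (four
Y-allele including multiallelic/spanning-deletion cases, two X-null)
among decoys, a 2664 bp zero-female interval at ~26.49 Mbp with ~30×
pooled depth, 147 bp probes in 150 bp reads, and family tables matching
the bundled counts.

Design choices that make truth sets *exact* rather than probabilistic:

* decoy genotypes are drawn from classes non-concordant by construction
  (monomorphic, model-in-one-species-only, both-sexes-heterozygous),
  and every emitted site is re-checked against the model predicates at
  generation time;
* background reads are rejection-sampled so no background read shares a
  `word_size`-mer with the probe on either strand;
* female background depth is `1 + Poisson(λ−1)` — strictly positive —
  so at `female_ceiling = 0` the planted interval boundaries are
  recovered exactly, by construction.

Depth tracks are generated densely over a 100 kb sub-window around the
planted locus rather than the full 3.3 Mb window: boundary-recovery
behaviour is identical and the tracks stay cheap to scan repeatedly.
Property tests run 20 seeds × 500-site windows for variant recovery;
these sizes exercise every code path while keeping the default suite
fast on one CPU.

All randomness flows through a seed carried in the configuration;
generators isolate RNG state with `withr::with_seed` (sub-generators
use fixed small offsets from the seed), so identical configurations are
byte-identical and never perturb the caller's RNG.

What the generators do **not** emulate — and what passing tests
therefore do not show about real data: sequencing error and quality
scores, alignment artefacts (mismapping, paralog collapse) that create
soft decoys *correlated* between sexes, coalescent structure within
pools, allele-frequency noise of finite pools (a real pool's GT call
can be wrong near 50% frequency), and reference bias at the window
scale. The concordance filter's false-negative behaviour under those
noise sources must be assessed on real alignments.

## Degenerate inputs and tie-breaks

Sites with no alternative allele fit no model. An all-zero 2×2 table is
an error (the test is undefined), as is a barcode pair with no
comparable columns. Gene models violating canonical `gt`…`ag` splice
boundaries or ORF rules are *constructed with violations recorded*, not
rejected — real noncanonical introns need to be inspectable. Merged
male-specific intervals report their realized `min_male_depth`, which
can dip below `male_floor` inside bridged gaps; the merge semantics are
intentional and the depths are reported honestly.

## Known limitations

* The pipeline consumes VCFs and depth tracks; alignment and variant
  calling are upstream, and their artefacts dominate real-data error.
* Window coordinates are configuration constants; no synteny liftover
  between assemblies is performed.
* Pool genotypes are treated as diploid truths; no allele-frequency
  model of pool composition is fitted.
* Counts quoted from full-scale runs of the original discovery (e.g.
  the ~66k pre-filter variant total, transcript-level coverage/RPKM)
  require the original read libraries and are out of desk-scale scope;
  the acceptance script exercises the same code paths on bundled and
  synthetic inputs instead.
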