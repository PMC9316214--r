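# sdscan

Discovery of sex-determination loci from pooled-sex sequencing data.

## The problem

In many fishes, sex is set by a single master regulator gene, but which
gene — and on which chromosome — differs even between closely related
species. In tilapia and other cichlids, a presence/absence locus on
linkage group 1 (LG1) drives an XX/XY-type system (written `xx/xy`): males
carry a gene on the y form of LG1 that is entirely absent from the x
form, so females have *no reads at all* over the locus.

`sdscan` implements the comparative-genomics strategy that localizes such
a regulator from pooled-sex whole-genome sequencing — one female pool and
one male pool per species, each genotyped as a single diploid sample —
and the downstream validation steps:

1. **Concordance filtering** (`scan_window`). Every variant site in the
   candidate window is classified against three pooled-genotype models
   of an XX/XY system:
   * `Y_ALLELE` — females homozygous, males heterozygous
     (F `a/a`, M `a/b`): the Y carries a distinct allele;
   * `X_NULL` — females null (`./.`), males homozygous: the locus is
     missing from the X;
   * `Y_NULL` — females heterozygous, males homozygous: the locus is
     missing from the Y.

   A site survives only if the *same* model holds in *every* species —
   the causative variant of a shared system must be shared. Surviving
   sites are annotated with male-allele conservation (comparing allele
   sequences, not indices) and gene context.
2. **Male-specific interval detection** (`find_male_specific_intervals`):
   maximal genomic runs with zero (configurable) female coverage and
   solid male coverage, from per-pool depth tracks.
3. **Electronic PCR** (`probe_hits`, `epcr_report`, `duplex_genotype`):
   presence/absence of a locus in raw read libraries by exact shared
   64-mers with a probe on either strand, a three-read detection
   threshold, and RPKM (`hits × 10⁹ / (total reads × probe bp)`).
4. **Gene-model validation** (`build_gene_model`, `translate_cds`,
   `check_amplicon_table`): exon/intron size arithmetic, canonical
   `gt`…`ag` splice boundaries, ORF translation, and primer-amplicon
   coordinate arithmetic (1-based inclusive, `size = end − start + 1`).
5. **Sex association** (`tabulate_calls`, `fisher_two_sided`): two-sided
   Fisher exact tests of genotype-by-sex 2×2 tables, by exact
   hypergeometric enumeration with log-factorial arithmetic.
6. **Barcode identity checks** (`compare_barcodes`,
   `compare_barcode_set`): uncorrected cox1 p-distances against the ~1%
   interspecies threshold, flagging misidentified libraries.

A seeded synthetic-data module (`sim_config`, `generate_vcf`,
`generate_depth_tracks`, `generate_reads`, `generate_family`,
`generate_gene`, `generate_barcode_pair`) produces every input the
pipeline consumes, with exact truth sets, so all stages are testable
offline.

## Worked example

The package bundles the published worked-example data for the LG1
figla-like locus: the six candidate-site genotypes from three pooled-sex
library pairs (As, Sm, Cz), gene annotations, segment sizes, primer
coordinates and family counts.

```r
library(sdscan)
design <- lg1_study_design()
scan_window(lg1_candidate_sites(), design, lg1_gene_annotations())
#> <concordance_scan> 6 concordant site(s) of 6 scanned
#>   chrom      pos ref alt As_F Sm_F Cz_F As_M Sm_M Cz_M    model conserved
#> 1   LG1 25672475   C T,G  0/0  0/0  0/0  0/1  0/2  0/1 Y_ALLELE     FALSE
#> 2   LG1 26488670   T   A  1/1  1/1  1/1  0/1  0/1  0/1 Y_ALLELE      TRUE
#> 3   LG1 26490716   G   C  ./.  ./.  ./.  0/0  1/1  1/1   X_NULL     FALSE
#> 4   LG1 26490863   C   T  ./.  ./.  ./.  0/0  1/1  1/1   X_NULL     FALSE
#> 5   LG1 26509215   A   C  0/0  0/0  0/0  0/1  0/1  0/1 Y_ALLELE      TRUE
#> 6   LG1 26510329   C *,T  0/0  0/0  0/0  0/1  0/2  0/1 Y_ALLELE     FALSE
#>                region     flank5     flank3
#> 1      depdc7a exon 8
#> 2          intergenic      csmd1 figla-like
#> 3   figla-like exon 2
#> 4 figla-like intron 2
#> 5          intergenic figla-like       chs1
#> 6          intergenic figla-like       chs1
```

Four sites fit the Y-allele model and two fit the X-null model; the two
X-null sites land inside the figla-like gene — the reads for that region
simply do not exist in females, which is what singles it out as the
male-determining candidate. The tri-allelic `depdc7a` site is concordant
but its male allele *sequences* differ between species
(`conserved = FALSE`), so it is annotated rather than promoted.

Association of the duplex presence/absence genotype with sex:

```r
sex_association_report(association_family_counts())
#>       family xy_females xy_males xx_females xx_males      p_value p_display
#>  OmI_Family1          0        8          7        0 1.554002e-04    0.0002
#>  OmI_Family2          0        8          6        0 3.330003e-04    0.0003
#>           Sg          0       15         18        1 8.620841e-09   <0.0001
#>           Cz          0        9         13        0 2.010374e-06   <0.0001
#>           As          0       58         33        0 1.509663e-25   <0.0001
#>           Cs          2       11         12        0 2.019114e-05   <0.0001
```

`p_value` is the exact two-sided enumeration at full precision;
`p_display` is the 4-decimal report rounding.

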