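# markerforge

Genome-wide design of **InDel**, **CAPS** and **tagged amplicon-SNP** PCR
markers from a multi-sample VCF and its reference genome.

Plant breeders and geneticists routinely need hundreds of cheap gel- or
sequencing-scorable assays that distinguish two groups of samples (two
cultivars, or the allele classes of a mapping population). General primer
tools design against one sequence at a time; `markerforge` instead walks a
whole VCF: it finds every site where two sample groups are fixed for
different alleles, classifies what kind of marker the site can support,
builds a masked design template around it, and emits validated primer pairs
in a tab-delimited report.

## Method at a glance

For each variant site with genotypes G over samples S:

1. **Grouping.** Auto mode emits one grouping per allele pair (i, j) with
   `A_i = {s : G_s = i/i}`, `A_j = {s : G_s = j/j}` both non-empty;
   heterozygous/missing samples join neither group. User mode tests one
   claimed split and vetoes on any unusable member.
2. **Screening.** InDel: `size_min ≤ |ℓ(a) − ℓ(b)| ≤ size_max`. CAPS: some
   enzyme's IUPAC site (both strands) occurs ≥1× in one allele-realized
   target (variant ± 20 bp) and 0× in the other. SNP: both grouped alleles
   are single distinct bases.
3. **Template.** Target ± 500 bp, with excluded regions for nearby
   segregating variants (REF span ± 1 bp), low-depth runs
   (`depth < min_depth`), and previously rejected primers. CAPS templates
   are trimmed so exactly one cut site remains.
4. **Design.** An exhaustive nearest-neighbor engine (SantaLucia 1998
   unified parameters; `Tm = 1000·ΔH / (ΔS' + R·ln(C_T/4)) − 273.15` with
   salt-corrected ΔS') enumerates primers outside all exclusions, pairs
   them under the product-size window and ranks by penalty.
5. **Validation.** Genome-wide binding-site scan (exact 3'-terminal 15-mer,
   ≤2 mismatches in the 5' remainder); any facing pair with implied product
   ≤ 10 kb besides the intended one rejects the pair, as do primer dimers
   and hairpins (run-length complementarity, 8-bp threshold). Rejected
   footprints become exclusions and design repeats (≤10 iterations).
6. **Output.** TSV report: locus, alleles, primers, Tm, product size,
   enzyme + digestion fragments per allele (CAPS), CS1/CS2 tag status
   (SNP), amplicon sequence. `filterPanel()`/`spaceMarkers()` then select
   multiplex amplicon panels (GC 40–60%, 150–175 bp, ~2-Mb spacing).

## Worked example

Everything below is generated from one seed — no downloads. `fixtureMixed()`
creates a 200-kb genome with 30 planted loci, a 4-sample VCF and a depth
track; the pipeline is then run in SNP mode.

```r
library(markerforge)

dir <- file.path(tempdir(), "demo")
fx  <- fixtureMixed(dir, seed = 1)
cfg <- markerConfig(vcf = fx$vcf, ref = fx$fasta,
                    out = file.path(dir, "snp_markers.tsv"),
                    marker_type = "snp", depth = fx$depth, min_depth = 5)
res <- runPipeline(cfg)
res$counters
#> sites_seen     grouped screened_in    designed    rejected   exhausted
#>         30          25          16          15           0           1
```

30 sites were read; 25 could be grouped (the monomorphic and
all-heterozygous plants cannot); 16 passed the SNP screen; 15 designed
cleanly and 1 — a locus planted inside a zero-depth hole — correctly
exhausted. The first reported rows:

```r
res$report[1:3, c("marker_id", "pos", "left_primer", "left_tm", "product_size")]
#>       marker_id   pos                                 left_primer left_tm product_size
#>  ctg1_61001_SNP 61001  ACACTGACGACATGGTTCTACATCCTCCCTCGCATGTACTCA   60.03          206
#>  ctg1_67001_SNP 67001  ACACTGACGACATGGTTCTACATCACAGCGGACAATGTCGAA   59.97          212
#>  ctg1_73001_SNP 73001 ACACTGACGACATGGTTCTACAGGACATCGCCGACTCCATAAT   60.00          264
```

Each left primer starts with the 22-nt CS1 tag
(`ACACTGACGACATGGTTCTACA`); the remainder is the locus-specific primer with
Tm ≈ 60 °C. A CAPS run on the same fixture reports the enzyme and the
expected gel pattern per allele:

```r
caps <- runPipeline(markerConfig(vcf = fx$vcf, ref = fx$fasta,
                    out = file.path(dir, "caps_markers.tsv"),
                    marker_type = "caps", depth = fx$depth, min_depth = 5))
caps$report[1:2, c("marker_id", "enzyme", "digested_allele", "fragments_a", "fragments_b")]
#>        marker_id enzyme digested_allele fragments_a fragments_b
#>  ctg1_13001_CAPS   RsaI               A      45,112         151
#>  ctg1_31001_CAPS   AluI               B         264     139,137
```

The first marker's group-A allele cuts into 45 + 112 bp while group B runs
as one 151-bp band; fragment sizes always sum to the allele-realized
product length.

A shell entry point wraps the same API
(`inst/scripts/markerforge.R run|panel|fixtures`):

```sh
Rscript inst/scripts/markerforge.R run --vcf v.vcf --ref g.fa \
    --marker-type snp --depth depth.tsv --min-depth 5 --out report.tsv
```

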