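---
title: "Designing InDel, CAPS and amplicon-SNP markers from multi-sample VCFs"
author: "markerforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing InDel, CAPS and amplicon-SNP markers from multi-sample VCFs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markerforge)
```

# The problem

Breeding and genetics programs need cheap, reliable PCR assays that
distinguish two groups of samples — typically two parental cultivars, or the
two allele classes segregating in a mapping population. Given a multi-sample
VCF and the reference genome it was called against, `markerforge` finds the
variant sites at which two sample groups are fixed for different alleles and
designs primer pairs for three marker chemistries:

* **InDel markers** — the two alleles differ in length, so the PCR products
  separate on an agarose gel.
* **CAPS markers** (cleaved amplified polymorphic sequence) — the variant
  creates or destroys a restriction site, so digestion of the product
  distinguishes the alleles.
* **Amplicon-SNP markers** — primer pairs carrying universal 5' tags (CS1/CS2)
  for multiplex PCR target amplicon sequencing.

The pipeline is `runPipeline()`; every stage is also exported on its own.

# Sample grouping

A site is usable only when each group is *fixed*: every member homozygous for
one allele, the two groups for different alleles. Two modes exist:

* **User mode** (`groupUser`): the caller claims two disjoint sample sets. A
  single heterozygous or missing genotype among the claimed samples vetoes
  the site — the user asserted those samples must be scorable.
* **Auto mode** (`groupAuto`): every unordered pair of alleles (i, j) with at
  least one sample homozygous for each defines one grouping; the groups
  contain *all* samples homozygous for the respective allele. Heterozygous
  and missing samples belong to neither group — co-dominant marker scoring
  requires fixed alleles, so a heterozygote cannot anchor a group. We
  deliberately do not treat a heterozygous genotype as its own allele class;
  grouping is by allele identity, which bounds the enumeration at
  C(n_alleles, 2) pairs per site.

Phased (`|`) and unphased (`/`) genotype separators are equivalent: only
allele content matters. Records with symbolic alleles (`<DEL>`, breakends)
are skipped — the design stages need literal allele sequences.

# Target and template geometry

All internal coordinates are 0-based half-open; conversion to the 1-based
conventions of VCF and FASTA happens only at the I/O boundary, which removes
a whole class of off-by-one slicing errors.

For each grouped variant the **target sequence** covers the variant span
plus 20 bp of reference on each side, realized once per allele (the two
realizations differ only inside the allele span). The **template** extends
the target by 500 bp on each side and is what the design engine sees; the
target sub-interval is the mandatory amplified region. Contig edges clip
these windows and set a flag instead of failing.

# Marker-type screening

* **InDel**: pass when `size_min <= |len(a) - len(b)| <= size_max`
  (defaults 3–50 bp). A `[min, max]` window subsumes an exact size
  (`min = max`).
* **CAPS**: an enzyme qualifies when it cuts one allele-realized target at
  least once and the other not at all. Because the 20-bp flanks are
  identical between realizations, any count difference is attributable to
  the allele — scanning the full realized target is exactly "at the locus".
  Recognition sites are IUPAC motifs matched on both strands (real CAPS
  assays cut double-stranded DNA); `N` or any ambiguity code in the
  *scanned* sequence never matches. The shipped table
  (`loadEnzymes()`) is a curated set of 30 common 4- and 6-cutters; users
  can supply their own TSV. Double digests and dCAPS are out of scope.
* **SNP**: both grouped alleles are single, distinct bases. The grouped
  allele pair decides, not REF/ALT — a multi-allelic record grouped on two
  one-base ALTs passes.

# Exclusion masking

Primers must bind identically in all assayed samples, so regions that are
not sequence-identical across the grouped samples are excluded from primer
placement (the amplicon may still span them):

* **Nearby variants**: any other VCF site overlapping the template that is
  not monomorphic across the union of the two groups masks its REF span
  plus a 1-bp guard. Heterozygous or missing genotypes count as polymorphic
  (conservative). Sites segregating only among *unselected* samples do not
  mask — only the assayed material matters. Non-marker positions are
  realized with the reference allele; homozygous-alternate neighbors are
  masked rather than substituted.
* **Low depth**: with a depth source and `min_depth > 0`, every maximal run
  of positions below the threshold is excluded. Depth from multiple BAMs is
  pooled as the per-position *minimum* across files — the conservative
  reading when the threshold protects against unreliable reference
  sequence. A plain-text interval dialect
  (`contig TAB start TAB end TAB depth`) is accepted in place of BAMs.
* **Rejected primers**: during redesign (below), the footprints of a failed
  pair are excluded so the engine cannot return it again. Exclusion totals
  are monotone across iterations, which (with the iteration cap) guarantees
  termination.

Exclusions are stored merged, sorted and disjoint; masking is idempotent.

# CAPS template trimming

A CAPS assay needs exactly one cut site in the product. If the
digested-allele-realized template carries additional sites of the marker's
enzyme, the template is shortened so that the nearest extra site on each
side — *including the site itself* — is removed. Removing the site is the
only reading of "remove the sequence upstream/downstream of the recognition
site" that guarantees uniqueness; leaving a partial site could recreate a
cut within an amplicon. When more than one site overlaps the target region
itself, uniqueness is unattainable and the candidate is dropped. After a
successful trim, a re-scan asserting exactly one site is a hard internal
invariant.

# The design engine

No primer3 binding is used; the engine is part of the package.

**Melting temperature** uses the SantaLucia (1998) unified nearest-neighbor
parameters with the salt correction applied to the entropy term,
`dS' = dS + 0.368 (N-1) ln[Na+_eq]`, and divalents folded in as
`[Na+_eq] = [mono] + 120 sqrt([Mg2+] - [dNTP])` (concentrations in mM).
Defaults are 50 nM oligo, 50 mM monovalent, 1.5 mM Mg2+, 0.6 mM dNTP —
ordinary PCR design practice. `Tm = 1000 dH / (dS' + R ln(C_T/4)) - 273.15`.
The implementation was cross-checked against an independent
nearest-neighbor implementation with the same parameter set; two frozen
values are asserted in the test suite. Because the parameter table is
duplex-symmetric, a primer and its reverse complement melt identically,
which lets the engine evaluate right primers directly on the template
strand. Windowed Tm over a template is O(1) per candidate via cumulative
dH/dS arrays.

**Candidate enumeration** is exhaustive over the template: left primers end
before the target, right primers start after it; each must avoid every
excluded base (O(1) via cumulative masks), contain no `N`, and satisfy the
length (18–25, optimum 20), GC (20–80%) and Tm (55–65 °C, optimum 60)
windows. Individual penalty is `|Tm - Tm_opt| + 0.2 |len - len_opt|`; pair
penalty adds `0.5 |Tm_L - Tm_R|`. The best 120 candidates per side are
paired under the product-size window (default 120–300 bp) and the best 50
pairs returned, penalty-ascending with coordinate tie-breaks so the order
is total and runs are deterministic end to end.

**Specificity** is checked genome-wide with a 3'-anchored rule that mirrors
extension chemistry: a binding site requires the primer's 3'-terminal
15-mer to match exactly, with at most 2 mismatches in the 5' remainder.
Every facing combination of the two primers' sites — plus-strand hit
upstream of a minus-strand hit, 3' ends pointing at each other — with an
implied product of at most 10 kb is a potential off-target amplicon
(`product = minus-hit 3' end - plus-hit 5' start`, 1-based inclusive). The
intended product is the one pair whose *both* binding sites overlap the
template's genomic interval (tolerant of near-duplicate mappings at the
locus); a facing pair with only one anchor at the locus is a genuine
chimeric off-target and is reported. An external alignment tool could
substitute for this scan, but the self-contained rule keeps runs hermetic
and reproducible; it is deliberately an explicit, documented stand-in
rather than a BLAST re-implementation.

**Secondary structures** are screened with run-length complementarity in
the classic primer-design ALIGN style: a pair fails when any self- or
cross-dimer alignment contains a contiguous antiparallel complementary run
of 8+ bases, or when either oligo can fold a hairpin with a stem of 8+
pairs enclosing a loop of 3+ bases. This is not a thermodynamic fold — a
full nearest-neighbor structure model is intentionally out of scope — but
it rejects the classic failure modes (perfect dimers, long inverted
repeats) while passing typical primers. Checks run on the *synthesized*
oligo: in SNP mode the tags are prepended first, since tags can dimerize.

**Redesign loop**: take the engine's best pair; if it off-targets or fails
the structure screen, exclude both footprints (reason `rejected_primer`)
and re-run the engine; stop at the first clean pair, at engine exhaustion,
or at the iteration cap (default 10 — in practice exhaustion, not the cap,
is what terminates hopeless templates).

**Tags**: in SNP mode the universal adapter tags CS1
(`ACACTGACGACATGGTTCTACA`) and CS2 (`TACGGTAGCAGAGACTTGGTCT`) are prepended
to the left and right primer so a second PCR can attach sequencing
adapters and indices. Footprints, product size and the genomic-part Tm are
unchanged.

# Panel tools

`filterPanel()` keeps rows whose amplicon GC and product size fall in
user windows (defaults 40–60% and 150–175 bp, typical amplicon-sequencing
settings). GC is computed over the full genomic amplicon — primers
included, tags excluded — since the tags are constant across a panel.
`spaceMarkers()` thins markers to a minimum spacing (e.g. 2 Mb) by greedy
left-to-right selection per contig: deterministic, order-independent of
marker density, and the natural reading when no selection algorithm is
otherwise specified. `predictFragments()` cuts an allele-realized product
at every recognition site (top-strand cut offset; bottom-strand sites map
through `site_length - offset`) and always conserves total length; CAPS
report rows carry fragments for both alleles so gel patterns are
predictable.

# The synthetic fixture generator

`makeGenome()`, `plantVariants()` and `makeDepth()` build complete,
self-contained inputs from one seed; `fixtureMixed()` bundles the standard
study fixture: a 200-kb i.i.d. random contig (GC 0.5) with 30 planted loci
— 10 InDels (7 inside the 3–50 bp window, 3 not), 10 engineered CAPS SNPs
(7 recoverable; one all-heterozygous, one monomorphic, one with no
differential enzyme site), and 10 SNPs (7 clean homozygous splits, one
monomorphic, one all-heterozygous, one buried in a zero-depth hole), plus a
uniform depth-30 track. Samples emulate four inbred-line-like genotypes
(first half homozygous REF, second half homozygous ALT at split loci).
CAPS engineering writes a concrete recognition site into the reference and
chooses the substitution that destroys it, verifying one site in the REF
target and none in the ALT target.

The truth table records, per locus and marker type, whether the pipeline
should recover it under the stated settings. InDel and SNP truth follow
directly from grouping and the screens. CAPS truth additionally requires
that the unique-cut-site trim succeeds and that the trimmed template still
admits a candidate pair under the design windows: frequent cutters (4-bp
sites recur every ~256 bp in random sequence) can trim the template below
the product-size window, and the truth table must predict that outcome.
The specificity, structure and redesign stages are deliberately kept *out*
of the truth computation; they are validated by their own independent
oracles.

What the fixture does **not** emulate: repeat families and paralogs (beyond
explicitly planted duplications), GC heterogeneity and compositional bias,
genotyping error, heterozygous residual segments in real inbred lines, and
VCF representation quirks (un-normalized indels). Passing the fixture
therefore demonstrates the pipeline's internal correctness, not marker
success rates in real material, where unknown polymorphisms under primer
sites and PCR-efficiency differences dominate failure.

# Numerical choices and scale

Reported Tm values are rounded to 2 decimals at row construction so the
TSV report round-trips losslessly. Candidate order uses penalty with
coordinate tie-breaks; every stage is deterministic, so identical inputs
and configuration give byte-identical reports. The test suite exercises a
200-kb/30-locus genome-wide run in all three modes and a 400-kb run with
55 markers, nearby heterozygous variants and shallow-depth pockets — sizes
chosen so the full property suite stays a desk-scale computation while
still covering every masking reason and both trim directions.

# Known limitations

* The structure filter is a complementarity-run heuristic, not a
  thermodynamic hairpin/dimer model; borderline structures near the
  threshold are resolved differently than a dG-based filter would.
* Specificity uses a 3'-anchored near-exact rule, not local alignment;
  binding sites with indels or with 3+ scattered 5' mismatches that might
  still prime under permissive conditions are not flagged.
* One enzyme per CAPS marker (the first qualifying table entry);
  double-digest assays and isoschizomer preferences are not modeled.
* Cross-marker primer-dimer screening of a pooled multiplex panel is not
  performed; per-marker PCR-efficiency balancing is out of scope.
* VCF records are assumed normalized (left-aligned, non-overlapping);
  upstream callers own that contract.
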