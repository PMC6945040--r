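---
title: "Methods: recessive variant prioritization in a nuclear family"
author: "mendelsieve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recessive variant prioritization in a nuclear family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mendelsieve)
```

## The analysis model

`mendelsieve` prioritizes candidate causal variants for a fully penetrant
autosomal recessive trait segregating in a single nuclear family. The
motivating study design is a sire × dam mating with a mixed litter: two
affected and three unaffected offspring, with whole-genome genotypes
available for the dam and all five offspring but not the sire. Under the
recessive model every affected individual is homozygous for the causal
allele, both parents are obligate heterozygous carriers, and no unaffected
sibling can be homozygous for it.

The pipeline is a funnel of set-reducing filters applied in a fixed order:

1. **Catalog subtraction** — remove every site already present in a
   population-scale background catalog, leaving variants private to the
   family. Matching is at site level by (chromosome, position), mirroring
   the `--diff-site` semantics of vcftools, which compares files by
   position; an allele-aware mode matching (chrom, pos, ref, alt) is
   available behind a flag but off by default.
2. **Quality** — remove sites with a depth statistic below 20 reads,
   any missing genotype among the affected offspring, or more than two
   missing genotypes across the genotyped family.
3. **Affected homozygous-alternate** — every affected sample must be
   `hom_alt`.
4. **Carrier parent** — the dam must be `het` (a missing dam genotype
   fails). Ungenotyped parents impose no constraint; when a genotyped sire
   is supplied he must be `het` too, since he is an obligate carrier — an
   extension beyond the motivating single-genotyped-parent design.
5. **Unaffected not homozygous-alternate** — no unaffected sibling may be
   `hom_alt`; `het` and `hom_ref` are both consistent with the model.
6. **Impact triage** — retain variants classified MODERATE or HIGH by the
   simplified coding-impact classifier; HIGH coding variants are the
   headline candidates.

Stages 3–5 commute (they are conjunctions of per-sample predicates); the
order is fixed anyway so that funnel reports are comparable across runs.
Every run emits a `funnel_report` whose counts are asserted non-increasing.

An `affected_only` mode drops stages 4 and 5, emulating a design in which
only the affected individuals were sequenced; its survivor set is always a
superset of the full-family set.

### Interpretation choices in the quality stage

Published filter descriptions rarely state whether a depth cut-off is
per-sample or per-site. We interpret the 20-read minimum as a *site-level*
statistic, by default the mean per-sample `DP` across genotyped family
members, falling back to the record's INFO `DP` when no per-sample depth
was recorded. The mean is robust to single-sample dropout; the statistic
and all three thresholds are configurable through `quality_policy()`. A
site with no recorded depth at all fails whenever a depth minimum is in
force: read support is never invented. Removal is strict (`< 20` fails,
exactly 20 passes).

Missingness rules default to `max_missing_affected = 0` (any missing
affected genotype disqualifies, because the affected-homozygote filter
cannot be evaluated reliably) and `max_missing_pedigree = 2`.

### Multiallelic sites and ploidy

Multiallelic records are split at read time into one row per alternate
allele, with genotype states computed per allele; any *other* alternate
allele counts as non-carrier for the allele under consideration. This is
our choice — variant-calling pipelines differ here — and it makes the
genotype-pattern logic exact per allele. Phased separators (`|`) are
accepted and treated as unphased. Ploidy other than 2 is a parse error:
the model assumes diploid autosomes. Exact duplicate (chrom, pos, ref,
alt) records are an input error, never silently de-duplicated.

## Coding-impact classification and frameshift consequences

The classifier (`classify_impact()`) is a deliberate simplification of
full-transcriptome effect predictors, because the cascade only needs
MODERATE/HIGH retention semantics: one transcript per gene, no
splice-site model, and a compact consequence table (frameshift, stop_gain,
start_lost, stop_lost → HIGH; inframe_indel, missense → MODERATE;
synonymous, exonic-noncoding → LOW; intronic/intergenic → MODIFIER).
Minus-strand genes are handled by mapping the variant into transcript
orientation (reverse complement) before any codon arithmetic.

`frameshift_consequence()` applies an insertion or deletion to the CDS,
translates from the original start codon, and names the result in HGVS
style. Two conventions matter:

* **fsTer counting** — in `p.(AaaPosBbbfsTerN)` the first changed residue
  counts as 1 and the premature stop as N, so the stop lands at residue
  `Pos + N - 1` and the truncated protein retains `Pos + N - 2` residues.
  `truncation_fraction()` implements exactly this arithmetic.
* **3'-normalization** — insertions are shifted to their most-3' position
  at the nucleotide level before naming, and the reported first changed
  residue is the first residue that *actually* differs between the
  original and edited translations (a shifted frame often re-encodes one
  or more of the original residues before diverging).

Degenerate cases are named explicitly rather than erred on: a shifted
frame with no downstream stop yields `fsTer?` with an undefined truncated
length; an edit whose shifted frame reproduces the entire original
protein (possible in the final codons) yields `p.(=)` with the full
length retained; a frameshift whose first changed residue is itself a
stop yields `p.(AaaPosTer)`. Edits of length divisible by 3 always take
the in-frame path and never carry `fs` notation.

## qPCR delta-Ct

Candidate-gene expression is compared between phenotype groups with the
standard ΔCt normalization: technical replicates are averaged
(arithmetic mean of Ct) per sample and assay, then
`ΔCt = Ct_target − Ct_housekeeping`. Higher ΔCt means lower relative
expression. Two reference modes are provided: `per_gene` (default, one
ΔCt per housekeeping assay, matching panel-per-gene plots) and `mean`
(one ΔCt per sample against the mean housekeeping Ct). Per-sample
constant offsets cancel exactly, and replicate averaging commutes with
subtraction; both are asserted by property tests.

`summarize_by_phenotype()` is deliberately descriptive only — n, mean,
min, max per group. No hypothesis test is computed: the motivating
comparison had two samples in one group, and with either group below
n = 3 the function attaches and prints a notice instead of a p-value.
No ΔΔCt or fold-change is derived.

## What the synthetic generator emulates

`simulate_bundle()` produces a complete, self-contained analysis input
with known truth. Its defaults are the study conditions, chosen once:

* **Genome**: 3 chromosomes × 400 kb, 30 genes with CDS of 100–400
  codons over 1–3 exons with short UTR flanks, mixed strands. This gives
  a coding fraction of roughly 2%, matching the genome-wide expectation
  that exonic candidates are rare among private variants.
* **Background**: 10,000 biallelic SNVs; founder alternate-allele
  frequencies from Beta(0.5, 2) (a rare-skewed site frequency spectrum);
  founder genotypes Hardy–Weinberg; offspring by random Mendelian
  transmission of one allele per parent.
* **Catalog membership** 0.99 per background variant: catalogs at the
  scale the subtraction step assumes (tens of millions of sites) leave
  well under 1% of a family's called variants private, and the tens of
  thousands of private variants reported in family studies against such
  catalogs imply the same order. Extra catalog-only sites are added so
  the catalog is not a subset of the family VCF.
* **Noise**: per-sample depth Poisson(30 reads); genotype dropout at 5%
  per call, which reproduces roughly the ~10–20% attrition a
  depth-and-missingness quality stage produces on real family data.
* **The plant**: exactly one 1-bp insertion inside a CDS (never at an
  exon junction, never in the start codon), sire and dam het, both
  affected offspring hom_alt, unaffected offspring drawn from het×het
  transmission *conditioned on not hom_alt* — sampled, not hard-coded, so
  unaffected genotypes vary across seeds the way a real litter would. By
  default one in-frame 3-bp insertion decoy with the same segregation
  pattern exercises the triage stage (it survives to the end but is
  MODERATE, not HIGH). The planted sites are exempt from depth and
  missingness noise so that recovery is deterministic; `hard_mode = TRUE`
  removes the exemption for robustness experiments.

All sampling derives from the configuration seed (the genome from
`seed`, the family from `seed + 1`, in documented draw order), so a
configuration reproduces its bundle byte-for-byte; `write_fixture_bundle()`
records MD5 checksums in a manifest and the test suite asserts their
stability.

What the generator does **not** emulate: linkage disequilibrium and
haplotype structure, read-level errors (no FASTQ/BAM), indel-rich
backgrounds, multi-transcript genes, population history, and genotyping
error correlated with depth. Passing tests therefore demonstrate that the
cascade's logic is correct under the recessive model and realistic
marginal noise — not that the pipeline is robust to every artifact of a
real variant-calling chain.

## Problem sizes used by the checks

The packaged checks run the generator at its default scale (10,000
background variants) across 20 seeds for recovery, 50,000 uniform random
genotype configurations for the segregation-selectivity estimate
(expected pass rate 8/729, verified exactly by enumeration of all 3^6
called configurations), and 1,000 random CDS/insertion pairs against a
brute-force translate-the-edited-CDS oracle. Module tests use smaller
bundles (hundreds of variants) where only logic, not statistics, is under
test.

## Known limitations

* One transcript per gene; a variant is attributed to the first gene
  whose span contains it, so overlapping genes are not resolved.
* The impact table intentionally collapses splice, UTR and regulatory
  categories; a real annotation run will classify more variants as
  HIGH/MODERATE than this simplification does.
* Catalog subtraction at site level discards a family variant whose
  position coincides with a different cataloged allele — faithful to
  position-based comparison semantics, but allele-aware mode exists when
  that is not wanted.
* The recessive model is the only one implemented: no compound
  heterozygotes, no dominant or X-linked filtering.
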