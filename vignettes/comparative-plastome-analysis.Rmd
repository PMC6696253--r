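---
title: "Comparative plastome analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative plastome analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastcompare)
```

## Scope and model

`plastcompare` compares two closely related, co-linear chloroplast genomes
(plastomes) — the motivating system is the pair of sugarcane ancestors
*Saccharum officinarum* (Badila) and *S. spontaneum* (Yunnan 83-184), whose
plastomes differ by a handful of point substitutions and short indels over
~141 kb. A plastome is modelled as a circular molecule with the canonical
quadripartite architecture: a large single-copy region (LSC), an inverted
repeat (IRb), a small single-copy region (SSC), and a second inverted
repeat (IRa) that is the exact reverse complement of IRb. All analyses
assume this regime: no rearrangements, divergence well below saturation,
and annotation supplied externally (FASTA + GFF3); the package does not
predict genes.

Coordinates are 1-based inclusive everywhere, the R/Bioconductor and GFF3
convention, so no conversion happens at file boundaries; every report
header states the convention.

## Whole-genome alignment

Because the two genomes are nearly identical, a full dynamic-programming
alignment is unnecessary. `anchor_align()` uses shared k-mers that are
unique in both genomes as anchors (k = 21 by default: 21-mers are
effectively unique at 140 kb scale), keeps the longest strictly increasing
anchor chain, merges contiguous same-diagonal anchors into exact blocks,
and closes the short inter-anchor segments with a banded global aligner
(match +1, mismatch −1, linear gap −2, band half-width 64). Linear rather
than affine gap costs are adequate at this divergence (<0.1%); the scores
and band are arguments for other regimes. Ambiguous bases (N) score 0.
A chain covering less than half of either genome aborts with a
co-linearity error rather than producing a misleading alignment — that
situation indicates a rearrangement or reverse-complemented input, which
this aligner deliberately does not model. The test suite checks the
implied alignment score of `anchor_align()` against a full
Needleman–Wunsch oracle on randomly edited pairs.

## Nucleotide diversity and hotspots

`sliding_pi()` computes nucleotide diversity in sliding windows (600 bp
window, 200 bp step by default — the conventional DnaSP-style setting for
plastome scans). For two sequences Pi reduces to the per-window
p-distance. Columns with a gap or N in either sequence are excluded from
numerator and denominator alike (pairwise complete deletion), which keeps
Pi within [0, 1]; a window with no valid site reports `NA`, never 0.
Windows tile genome A's ungapped coordinates and trailing partial windows
are retained and flagged. `detect_hotspots()` flags windows with Pi
strictly greater than the threshold (default 0.006; the strictness of the
inequality matters at the boundary) and merges adjacent flagged windows
into regions, reporting each region's maximum.

## Genetic distance and selection

`k2p_distance()` implements Kimura's two-parameter distance from the
transition proportion P (A↔G, C↔T) and transversion proportion Q:

    d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)

When the logarithm arguments are non-positive the sequences are saturated
and a distance is refused rather than reported as NaN. By construction
d ≥ P + Q; the suite asserts this and cross-checks against an independent
K80 implementation.

`ng86_kaks()` implements Nei–Gojobori (1986): fractional synonymous site
counts per codon (changes producing a stop count as nonsynonymous),
averaged over both sequences; observed differences resolved by averaging
over all minimal substitution pathways, discarding pathways through stop
codons (all pathways are used only if every one passes through a stop);
and the Jukes–Cantor correction d = −3/4 ln(1 − 4p/3) applied to pN and
pS. NG86 was chosen because it is the canonical counting method and makes
no model assumptions a two-sequence comparison cannot support; results can
differ from γ-series or ML estimators, which is why the method is named in
every output. One numerical consequence worth knowing: an isolated
single-codon pair whose only difference is synonymous at a fully
degenerate site (e.g. GGC→GGT) has pS = 1, so the correction saturates
and the package raises an error instead of inventing a finite Ks; embedded
in any realistic gene the same substitution yields an ordinary Ks > 0.
The implementation is checked against an exhaustive pathway-enumeration
oracle over all 3,721 ordered non-stop codon pairs.

`classify_selection()` follows the usual reading: Ka/Ks > 1 positive,
= 1 neutral, < 1 purifying; Ka = 0 with Ks > 0 is reported as strong
purifying selection, and Ks = 0 leaves the ratio undefined rather than
infinite.

## SNP records

`call_snps()` aligns each shared spliced CDS pair and emits one record per
mismatching gap-free column, with positions on genome A's spliced,
strand-corrected coding sequence (the coordinate style gene-level SNP
tables are printed in). IR-duplicated genes yield records per copy.
Mismatches adjacent to gap runs are skipped with a warning — indel edges
are alignment artefacts, not substitutions. A codon hit by several
substitutions produces one record per changed base, all inheriting the
whole-codon amino-acid comparison; the summary reports such multi-hit
codons and codons carrying both a transition and a transversion
separately, because per-base and per-codon counting conventions genuinely
diverge there and published totals are not always derivable from either
convention alone.

## Codon usage

`count_codons()` records the first codon of every CDS separately and
assigns it to a three-codon methionine family {AUG, AUA\*, GUG\*}
(starred = recoded starts): plastid genes initiate at AUA/GUG yet are read
as Met, and published plastome codon tables list AUA under both Ile and
Met accordingly. Stop codons form a terminator family and are included in
the codon total — this is required for published amino-acid percentages
(e.g. leucine 2175/19,994 = 10.88%) to reproduce. RSCU is count divided by
the family mean; zero-total families report `NA`. Display rounding is
half-up to 3 decimals for RSCU and four significant digits for
percentages, matching the precision such tables are printed at.
Trans-spliced genes (rps12) are excluded by default wherever CDS are
consumed, consistent with their exclusion from published intron
statistics; the flag is exposed because the convention is not universal.

## Quadripartite structure and junctions

`find_inverted_repeats()` finds the longest pair of disjoint segments
where one is the exact reverse complement of the other, seeded by k-mers
shared between the genome and its reverse complement and extended
maximally. Exact matching is the default because the two IRs of these
genomes are identical; a mismatch-tolerant mode is not needed for the
supported regime and was left out rather than shipped untested. The longer
inter-IR segment is the LSC; the IR downstream of the LSC is IRb.
Circularity is handled by retrying detection on a half-rotated copy, so an
IR spanning the origin is still found, and detection is rotation-invariant
up to the coordinate shift. Junctions (JLB, JSB, JSA, JLA) are the first
base of the downstream region in LSC→IRb→SSC→IRa order.

`junction_offsets()` reports, per junction, genes within a 1000 bp flank:
a gene overlapping a junction is an expansion and reports the bp on each
side (the ndhF situation: in the SSC but extending 29 bp into IRb); a gene
falling short is a contraction and reports the gap in bp (rps19 35 bp,
psbA 90 bp, rps15 153 bp in the motivating pair). For rpl22-style genes
the published phrasing does not name the junction the contraction is
measured from; the gap to the nearest junction (JLB) is used and the
interpretation is stated here rather than hidden.

## SSR scanning

`find_ssrs()` is a MISA-style perfect-repeat scanner. Three presets mirror
the common parameter sets (unit size / minimum repeats): `strict` 1/10,
2/6, 3/5, 4/5, 5/5, 6/5; `melotto_modified` 1/8, 2/5, 3/3, 4/3, 5/3, 6/3;
`relaxed` 1/10, 2/5, 3/4, 4/3, 5/2, 6/2. A maximal run is attributed to
its smallest repeating unit (a poly-AT stretch is one dinucleotide SSR,
not six mononucleotide pairs); runs are trimmed to whole repeats; when
runs of different unit sizes overlap, the smaller unit wins. Under the
very permissive `relaxed` thresholds (two repeats of a penta- or
hexanucleotide) the smallest-period rule materially affects counts —
which abundance ranking one obtains at 2-repeat thresholds is a
convention, not a biological finding. `join_compounds()` groups SSRs
separated by at most 100 bp (the customary compound rule) and constituent
SSRs keep their individual identity, so compound members are counted
individually in totals — the counting convention that reconciles published
row counts with published totals. Motif classes merge rotations and
reverse complements (A and T repeats are one A/T class). The scanner is
checked against a backreference-regex oracle for all unit sizes and all
three presets.

## The synthetic plastome pair

`generate_pair()` builds genome A as LSC + IRb + SSC + revcomp(IRb) over
an i.i.d. uniform background (GC skew is not modelled: every statistic
computed here is composition-agnostic), plants genes (mixed strands, a
two-exon gene, a trans-spliced flagged gene, an IR-duplicated gene, and
one boundary gene per junction at configurable offsets), plants SSRs in
intergenic zones with their periodic continuation broken at both flanks,
and derives genome B by applying the SNP and indel specifications exactly.
The default desk-scale configuration is a 14 kb genome (LSC 8400, IR 2100,
SSC 1400) with 12 genes, 24 coding SNPs mirroring the class mix observed
between the two sugarcane ancestors (12 transitions / 12 transversions,
6 synonymous / 18 nonsynonymous by per-base classification), three small
intergenic indels, five SSR plantings including a (T)10 + 8 bp + (T)10
compound, and boundary-gene offsets of 58/29/153/90 bp matching the
published junction geometry. A full-scale 140 kb configuration with the
same structure is available (`scale = "full"`). Two deliberate
regularities keep the truth table exact: at most one planted SNP per
codon (so per-base and per-codon effect classifications coincide), and
chance complementarity at the IR boundaries is broken so maximal exact
extension recovers exactly the planted partition.

What the generator does not emulate: real base composition and GC skew,
tRNA/rRNA genes, sequencing or assembly error, rearrangements, imperfect
or interrupted repeats, and IR copies that differ between genomes.
Passing the recovery suite therefore demonstrates correctness of the
measurement machinery under the stated regime, not robustness to
annotation error or structural variation.

```{r example}
pair <- generate_pair(synthetic_config(seed = 42))
bundle <- run_compare(pair$genome_a, pair$genome_b,
                      pair$annot_a, pair$annot_b, min_ir_len = 500)
bundle$structure
bundle$snp_summary$ts_tv_ratio
```

## Problem sizes and runtime choices

The validation suite runs at desk scale: 14 kb synthetic genomes for
pipeline recovery, 2 kb pairs for alignment-oracle comparisons, 10 kb
random sequences for the SSR oracle, and the complete 61 × 61 codon-pair
grid for the NG86 oracle. These sizes were chosen so each property is
exercised in full while the whole suite stays interactive; the full-scale
140 kb generator path is exercised once. The one validation that needs
external data — SSR counts on the deposited accessions MN204507/MN204508 —
runs only when those FASTAs are placed under `inst/extdata/accessions/`,
and its expectation is recorded as failing otherwise rather than silently
skipped.

## Known limitations

- Ka/Ks is NG86 only; no ML or γ-corrected estimators.
- The aligner refuses rearranged genomes instead of modelling them.
- IR detection is exact-match; plastomes with diverged IR copies are out
  of scope.
- SNP calling is CDS-centric; intergenic variants appear only through the
  Pi track and the alignment's gap table.
- Published aggregate SNP counts that depend on unstated de-duplication
  rules (absolute Ts/Tv splits across IR-duplicated copies) are not
  reproduced; the package reports per-record classifications and the
  conventions it uses.
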