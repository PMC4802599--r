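---
title: "Methods: small RNA, degradome and phenotype analysis of maize leaf senescence"
author: "senmiR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA, degradome and phenotype analysis of maize leaf senescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senmiR)
```

## The scientific problem

Maize grain yield depends on how long the ear leaf stays photosynthetically
active after pollination. Comparing an early-senescing inbred line (ELS-1)
with a stay-green line (Yu87-1) at 20 and 30 days after pollination (DAP)
lets one ask which microRNAs change expression specifically where senescence
is happening. `senmiR` implements that comparison end to end: small-RNA read
processing, known and novel miRNA identification, an RPM-based two-genotype
contrast that defines candidate senescence-associated miRNAs (SA-miRNAs),
degradome (PARE) cleavage-site calling for their targets, and the supporting
wet-lab arithmetic (2^-ddCt relative quantification and spectrophotometric
chlorophyll determination).

Because the deposited study libraries are not part of the package, every
stage is validated against a synthetic study with planted ground truth
(`generate_toy_genome()` and friends) plus a packaged transcription of the
study's printed novel-miRNA abundance table (`load_table1_fixture()`,
164 records).

## Clean-read pipeline

`trim_and_quality_filter()` removes the 3' adapter as the longest read
suffix that exactly matches an adapter prefix, requiring at least 6 nt —
reads carrying fewer adapter bases cannot be distinguished from insert
reliably and are left alone (such reads are removed later by the length
window instead). Reads containing N, or with mean Phred below 20 over the
trimmed insert, are discarded; the log records counts per reason so the
filter is auditable. The quality rule itself is a package decision: the
source protocol says only that "low-quality" reads were removed.

`length_filter_and_collapse()` keeps 18-32 nt inserts (both boundaries
inclusive) and collapses identical sequences into unique tags with
per-library counts. `map_tags()` performs exact full-length matching on
both genome strands via an 18-mer anchor index; no mismatches are allowed
because the study names no aligner or mismatch policy and exact matching is
fully reproducible on a synthetic genome. All hit positions are reported;
multi-mapping tags are counted once per library in expression totals (not
once per hit), so read mass is never double counted. `remove_ncrna()`
discards tags occurring as exact sense-strand subsequences of the
rRNA/tRNA/snRNA/snoRNA/cis-regulatory reference, mirroring an Rfam screen
without the external database. Survivors mapped to the genome are the
*candidate miRNA reads*, and their per-library totals are the RPM
denominators.

Internally all coordinates are 0-based half-open; human-readable reports
are 1-based.

## Known and novel miRNA identification

`annotate_known()` assigns a tag to a reference mature if the two are
identical up to end shifts of at most 2 nt at the 5' and 3' ends with no
internal mismatches — the conventional isomiR tolerance. Counts of all tags
assigned to one mature id are summed; families are parsed from ids
(`zma-miR159a-3p` -> `zma-miR159`).

`call_novel_mirnas()` evaluates each unassigned, genome-mapped tag of
18-26 nt at each of its loci. Two precursor windows are extracted
(tag on the 5' arm with 150 nt downstream, tag on the 3' arm with 150 nt
upstream), and a locus is called when:

* a star region on the opposite arm pairs antiparallel with the mature with
  at most 4 unpaired positions (G:U wobbles count as paired) and no
  unpaired run longer than 2 nt, separated from the mature by a loop of at
  least 3 nt. The star is found by scanning *every* candidate window
  directly with the duplex scorer rather than by reading the fold's
  partner table — base-pair maximization is opportunistic about long-range
  pairings and unreliable for this bookkeeping. Star windows of mature
  length plus or minus 1 nt are considered, so single 1-nt bulges are
  recognized; larger indel bulges are not searched (the planted generator
  uses substitution-only stars, and real bulged plant precursors are the
  minority);
* no *competing* star — within one mismatch of the best — exists outside
  the chosen stem's neighborhood (single-major-stem rule; a second
  comparable complementary region indicates a repeat-like, multi-stem
  context). Windows that merely pass the 4-mismatch ceiling do not
  compete, because a single bulged alignment against random sequence
  reaches that ceiling by chance;
* the exact mature..star region folds with a stability score of -18 units
  or lower.

`fold_hairpin()` is a pseudoknot-free base-pair maximization
(Nussinov-style dynamic programming in C++, minimum loop 3, A-U/G-C/G-U
pairs) with a deterministic traceback that prefers the outermost partner,
keeping contiguous stems intact. The score is
`-(pairs + 0.5 * stacked pairs)`, scaled so that canonical miRNA hairpins
(stems of roughly 13 bp and up) score below -18. The backend sits behind a
plain function so a thermodynamic folder could replace it under the same
contract. All thresholds live in `novel_criteria()` because the study
delegates its prediction criteria to an external tool whose parameters are
not reproduced; the defaults follow common plant-miRNA practice.

## Expression contrast

`compute_rpm()` scales counts to reads per million mapped candidate reads.
The study's one mention of "RPKM" is read as RPM: length normalization is
meaningless for collapsed ~21-nt tags. `apply_floor()` keeps miRNAs
reaching 5 RPM in at least one library. `log2_fold_change()` adds a
pseudocount (default 1 RPM) before taking ratios, since the printed novel
table contains many exact zeros and the study does not say how log2 of zero
was computed; `select_sa_mirnas()` therefore attaches a sensitivity report
over pseudocounts 0.5/1/2 RPM to every contrast. A miRNA is a candidate
SA-miRNA when |log2FC| strictly exceeds 1.5 between 30 and 20 DAP in ELS-1
and does not exceed it in Yu87-1 (the removal rule). Note a non-obvious
property verified in the tests: the candidate set is *not* monotone in the
threshold, because raising it also weakens the removal arm.

## Degradome analysis

`score_duplex()` scores a miRNA against a reverse-oriented target site with
plant-target penalties: mismatch 1.0, G:U wobble 0.5, gap 1.0 (at most one
1-nt gap), all doubled at miRNA positions 2-13. `find_target_sites()`
reports every window scoring at or below 4.0 and predicts cleavage at the
transcript base pairing miRNA position 10. `build_tag_profile()`
exact-matches degradome tags (36-nt 5'-end reads; tags shorter than 15 nt
after 3'-end truncation are ignored as unmappable) and accumulates 5'-end
counts per transcript position. `assign_category()` classifies the signal
at a predicted site: category 4 for a single raw read, 0 for a unique
transcript-wide maximum, 1 for a shared maximum, 2 above the median of
positions with at least one read, 3 otherwise (the median is over nonzero
positions only). Every constant is configurable because the source tool's
version-specific defaults are unpublished; outputs echo the configuration
used.

## Wet-lab quantification

`chlorophyll_concentrations()` uses Arnon-type coefficients for 645/663 nm
absorbances — `Ca = 12.7 A663 - 2.69 A645`, `Cb = 22.9 A645 - 4.68 A663`,
`Ctot = 20.2 A645 + 8.02 A663` (mg/L) — because the cited extraction
method's formulas are not printed; the coefficients live in
`chl_coefficients()` so alternative solvent systems can be swapped in. The
2x2 system is exactly invertible (`absorbance_for_chlorophyll()`), which
both the simulator and the tests exploit. Concentrations are reported in
mg/L of extract as printed in the study; the recorded 0.2 g fresh mass in
20 mL would support a per-gram conversion, and `senescence_contrast()`
works on either scale since only ratios of decline rates matter.
`delta_delta_ct()` averages replicate Ct values per sample and gene before
differencing (three replicates per sample), and `direction_concordance()`
compares the sign of the qPCR trend between 20 and 30 DAP with the
sequencing log2 fold change, treating zero as agreeing with either sign.

## The synthetic study and what it does (not) show

`sim_config()` fixes the study conditions: a 200 kb toy genome carrying 40
reference ("known") and 10 unannotated ("novel") miRNA hairpins and 20
structural-ncRNA loci; four libraries of 50,000 reads (2 genotypes x 2
timepoints); 8 planted SA-miRNAs with 4-fold effects in ELS-1 only; a
degradome library with 70% of a targeted transcript's tags at the planted
cleavage site; chlorophyll trajectories anchored at the published values
(chlorophyll a 25.58 -> 0.35 mg/L across 25-30 DAP in ELS-1 against
27.41 -> 23.01 mg/L in Yu87-1); and Ct tables encoding the planted
expression through the ddCt model.

Counts are negative binomial around the expected RPM shares. The default
dispersion is 0.002: each library is a single pooled pool (the design has
no biological replicates), so the count noise represents technical
resampling, which is near-Poisson; at the simulated coverage this gives a
per-count coefficient of variation of 5-15% and places the planted 4-fold
effects more than four standard deviations from the 1.5 log2 selection
threshold, so recovery tests are sharp rather than borderline. Planted
up- and down-effects are mass-balanced before normalization — otherwise
renormalization would compress the up-regulated fold changes toward the
threshold and the planted flags would not be a fixed point of the selection
rule. Hairpin stars carry 1-2 substitutions so that each mature occurs at
exactly one genomic position (a perfect star would be an exact minus-strand
copy), which the generator verifies by exhaustive search.

The generator deliberately omits ligation bias, PCR duplicates,
sequencing-error substitution profiles, and the explicit mixing of
biological replicates before pooling. Passing recovery tests therefore
demonstrates that the *rules* are implemented correctly and are mutually
consistent at realistic effect sizes — not that the pipeline is robust to
artifacts real libraries contain.

Problem sizes in the shipped tests: the full-scale run uses the default
configuration above (about 20 seconds end to end); unit and property tests
use a 40 kb genome with 16 loci and 6,000-read libraries; oracle-equivalence
suites run at least 1,000 randomized instances per operation, with folding
checked exhaustively on sequences up to 25 nt.

## Known limitations and open points

* The study reports both "81 miRNAs" (abstract) and "80 miRNAs" (results)
  after the floor; the pipeline reports its own count and takes no side.
* Whether multi-mapping tags were discarded or distributed is unstated in
  the source; counting each tag once per library is the package default
  and documented above.
* The printed novel-miRNA table is treated as normalized abundances as
  printed; its row 37 states length 21 for a 20-nt recoverable sequence,
  and the packaged transcription records the consistent value 20.
* Novel-locus calling recognizes only single 1-nt bulges in the
  mature/star duplex; heavily bulged precursors would be missed.
* Exact-match mapping is by design; genomes with sequencing errors or
  polymorphism relative to the reads need an external aligner upstream.
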