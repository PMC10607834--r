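---
title: "isoAPA: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{isoAPA: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical procedures implemented in
`isoAPA`, the parameters that matter and their defaults, what the
synthetic-data generator does and does not emulate, and the design
choices made where more than one reasonable reading existed.

## Data model and coordinates

All coordinates are **1-based, closed on both ends** — the native
GTF/GRanges convention in the R/Bioconductor ecosystem. BED input and
output (0-based half-open) converts at the file boundary. This is a
deliberate deviation from a half-open internal convention: in R the
surrounding ecosystem (rtracklayer, GenomicRanges, Biostrings) is
1-based closed, and converting only at the BED boundary removes the
largest class of off-by-one errors for this implementation language.
An intron between exons `(s1,e1)` and `(s2,e2)` is `(e1+1, s2-1)`; a
read's cleavage position is its 3'-most aligned base (highest
coordinate on `+`, lowest on `-`).

Gene assignment of a read 3' terminus uses the gene span extended
`downstream_slack` (default 1000 nt) past the annotated 3' end, because
real cleavage frequently occurs beyond annotated ends. When two
same-strand genes both contain a terminus, the gene with the closer
annotated 3' end wins; exact ties are left unassigned rather than
guessed.

## Poly(A)-site calling

Per gene, on pooled counts across all samples:

1. **Greedy clustering.** Repeatedly take the unconsumed position with
   the highest count (ties: lowest coordinate) as a representative and
   absorb all positions within ±`assignment_halfwidth` (12 nt). Then any
   representative within `min_separation` (30 nt) of a stronger one
   hands its reads to the nearest retained representative, so retained
   sites are pairwise >30 nt apart. Both passes are deterministic; the
   position→site assignment is retained so per-sample count tables
   exactly partition the gene's reads.
2. **Usage filter.** usage = site count / gene count, computed before
   filtering; sites with usage strictly greater than `min_usage` (0.05)
   are kept, in one pass (no iteration), and usages are renormalized
   over survivors. A gene losing all sites is dropped and logged.
3. **Major site.** Highest pooled count; ties go to the 3'-most site in
   transcription direction, which keeps the rule symmetric under strand
   reflection.
4. **Normalization.** The source protocol normalizes "based on read
   count from the highest sites and library size", which underdetermines
   a formula. We emit both readings: median-library scaling
   `raw × median(lib)/lib(sample)` per sample, and the within-gene ratio
   of each site's pooled count to the major site's count.
5. **Intronic sites.** A site is intronic when strictly inside an intron
   of the gene's reference transcript, taken as the transcript with the
   largest summed exon length (the annotation does not say which isoform
   defines "intronic"; the longest-exonic transcript is the most
   inclusive stable choice).

The usage denominator pools all samples; per-sample usage is available
from the count table. Whether a site catalog should be built per sample
and merged, or on pooled reads, is not specified by the source protocol;
we pool, and keep per-sample matrices for the differential tests.

## Differential poly(A)-site usage

For each retained site of a multi-site gene and each consecutive stage
pair, the 2×2 table is (site reads, other-site reads) × (stage A, stage
B), replicates pooled within stage. The two-sided Fisher exact p-value
sums hypergeometric probabilities of all margin-preserving tables no
more probable than the observed one (with the customary `1e-7` relative
slack against floating-point ties). Calls are made at uncorrected
p < 0.05 to mirror the source protocol; a Benjamini–Hochberg column is
always included so users can apply FDR control instead. Site-vs-rest
tables were chosen over proximal-vs-distal pairing because the protocol
names only "differential APA sites"; for two-site genes the two per-site
tables are mirror images with identical p-values, which the acceptance
computation accounts for by counting one test per gene.

Fisher's exact test is conservative on a discrete lattice: at 500
reads/stage its achieved size is ≈0.042 rather than 0.05. The null
calibration cohort therefore uses 1,000 reads/stage (achieved size
≈0.048). A reported type-I error slightly *below* the nominal binomial
band at some seeds reflects this conservativeness, not an error-control
failure.

## Alternative splicing events and PSI

Events are local, defined between isoform pairs of one gene and
deduplicated by (gene, type, defining coordinates); identical events
found between different pairs merge their isoform sets. The seven types
follow the standard local-event scheme: RI (an isoform's exon exactly
spans another's intron plus flanking exons), SE (an internal exon
skipped between shared flanking introns), A5/A3 (two introns sharing one
boundary, with the variable boundary exonic in the shorter-intron
isoform — this last condition is what separates A5/A3 from AF/AL), AF/AL
(non-overlapping alternative first/last exons sharing the splice
boundary into/out of the gene body), MX (two non-overlapping internal
exons with shared outer flanks that never co-occur in any isoform).
A5/A3 and AF/AL are named relative to transcription direction, so on the
minus strand the genomically right-hand variable donor is still A5.

Inclusion-form conventions (needed for a signed PSI): RI — the
intron-retaining isoform; SE — the exon-containing isoform; A5/A3 — the
shorter-intron isoform; AF — the isoform whose first exon is 5'-most in
transcription; AL — 3'-most last exon; MX — the isoform using the
5'-most exon. PSI = Σ inclusion / (Σ inclusion + Σ exclusion) abundance
and is undefined (NA) at zero denominator.

The test suite checks the classifier against a brute-force enumerator
written independently in transcription coordinates (minus-strand
structures are negated so each rule exists once); the two
implementations agree on 500+ random multi-isoform genes.

Differential PSI is a plainly labelled permutation test on
|mean(groupB) − mean(groupA)|: exhaustive over label assignments when
`choose(n, nA)` fits the permutation budget (then the p-value is the
exact enumeration fraction), otherwise `n_perm` random permutations with
an add-one correction. It is a substitute for, not a replication of,
model-based differential-splicing machinery.

## Sequence profiles

Splice-site matrices use 6 exonic + 5 intronic columns at donors and
5 intronic + 6 exonic at acceptors, mirroring the conventional
`XXXXXX|GT...` / `...AG|XXXXXX` consensus display; windows are
configurable. Columns renormalize after excluding N; consensus ties
break in fixed base order A < C < G < T. Cleavage-site composition
profiles are strand-aware (minus-strand windows reverse-complemented) so
negative offsets always mean upstream in transcription direction.
Poly(A)-signal k-mers (AAUAAA, UGUA; U mapped to T) are counted with
overlaps inside a −40..−10 window upstream of cleavage — the canonical
placement of plant poly(A) signals; the exact window used by the source
study is unstated, so this default is an assumption and is configurable.
De-novo motif discovery is deliberately out of scope; fixed-k-mer
counting is deterministic and sufficient to test planted-signal
recovery.

## lncRNA structural filter

The filter sentence "transcripts with only one exon and exon lengths of
<200 bp were filtered out" is read conjunctively (mono-exonic AND
<200 nt removed); the disjunctive reading is available via
`rule = "disjunctive"`. The boundary is strict: exactly 200 nt is
retained. Coding-potential prediction and expression testing belong to
external tools and are not reimplemented.

## The synthetic world

The generator's defaults state the validation world: 200 genes on four
chromosomes (both strands), four stages × three replicates × 200 reads
per gene, 1–3 terminal poly(A) sites per gene (probabilities
0.6/0.3/0.1) spaced ≥60 nt, base usage 0.7/0.3 for two-site genes with
30% of APA genes interpolating to the reversed usage across stages,
Gaussian 3'-end jitter with sd 5 nt (rounded), uniform 5' truncation
within the first exon, AATAAA written at −30..−25 of every site for 60%
of genes, one additional intronic site centred in a deliberately long
intron (2–4 kb vs 150–600 nt background) for 15% of genes, and seven
dedicated genes carrying one canonical AS event each. All introns are
written GT..AG. Everything is deterministic given a seed.

What the simulator does **not** emulate: sequencing error, chimeras,
internal priming, incomplete (non-full-length) reads that lose introns,
expression-level variation between genes, overlapping genes, and
alternative 3' ends coupled to splicing (except the AL gene). A green
recovery test therefore establishes correctness of the algorithms under
clean, known-truth input — not robustness to artefacts the upstream
tools (mapping, error correction) are responsible for.

One honest consequence surfaced by the tests: when AS events are
classified on *collapsed read models* rather than the annotation, RI is
systematically under-recovered, because its exclusion isoform is
mono-exonic and jittered read termini break the exact
boundary-match rule. Event recovery criteria are therefore evaluated on
the planted annotation; classification over collapsed models is
supported and behaves as real data would.

## Numerical and tie-break choices

* Clustering order: descending count, ties ascending coordinate;
  merge pass assigns a displaced representative's reads to the nearest
  retained site.
* Major-site ties: 3'-most in transcription direction.
* Consensus ties: A < C < G < T.
* Fisher p-values: `dhyper` sums with `1e-7` relative slack; degenerate
  margins give p = 1 by convention; the reported odds ratio is the
  sample odds ratio `ad/bc`.
* Permutation p-values: add-one corrected unless exhaustive.
* Collapse termini: widest 5'/3' ends among supporting reads (the
  source protocol does not state its convention).
* Mono-exonic reads: grouped at ≥50% reciprocal overlap; they form
  isoforms but never AS events.

## Known limitations

* Gene assignment ignores antisense overlap structure beyond the
  same-strand rule; unassigned reads are counted and logged, not
  rescued.
* The per-sample count table drops reads whose only site failed the
  usage filter (they are usage-denominator reads but belong to no
  retained site), matching the single-pass filter semantics.
* `differential_apa` pools replicates within stage, as the source
  protocol does; no replicate-level dispersion model is fitted.
* The intronic-site flag depends on the chosen reference transcript;
  genes whose longest-exonic transcript lacks the host intron will not
  flag sites that are intronic relative to a shorter isoform.
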