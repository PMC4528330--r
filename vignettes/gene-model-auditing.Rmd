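---
title: "Auditing exceptional gene models: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing exceptional gene models: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GeneModelAudit)
```

GeneModelAudit treats exceptional gene models — polycistronic
transcripts, shared and frame-conflicting coding overlaps, noncanonical
splicing, trans-splicing, and the translation exceptions — as first-class,
*declared* annotation rather than as errors to be silently repaired. This
vignette documents the model behind each classifier, every tunable
parameter, the conventions adopted where the underlying curation practice
leaves the arithmetic open, what the synthetic fixtures do and do not
emulate, and the known limitations.

## Coordinate and data model

All internal coordinates are zero-based, half-open `[start, end)` on an
explicit strand; GFF3 input/output converts to and from 1-based inclusive
coordinates at the file boundary, and BED junction input is already
half-open. This makes interval lengths, adjacency and intersection free of
off-by-one corrections, which matters for classifiers that count single
nucleotides (the 40-nt multiphasic rule, one-base-off junctions).

A transcript owns an ordered list of exons (5′→3′ in transcript order) and
zero or more ORFs, one per encoded gene. Standard GFF3 cannot attach two CDS
groups of one mRNA to two different genes, so multi-gene transcripts use a
small dialect: comma-separated `Parent` on the mRNA naming every owning
gene, a `gene=` attribute on each CDS feature naming its owner, and an
`exon_order=` attribute that makes mixed-strand (trans-spliced) exon order
explicit. Translation exceptions are declared as attributes on the first
CDS line of a group (`start_codon=`, `readthrough_codons=`,
`selenocysteine_codons=`, `frameshift_codon=`, `incomplete_stop=`,
`genetic_code=`); passthrough flags (`trans_spliced_transcript`,
`endonuclease_spliced_intron`, `mutation in strain`,
`genomic sequence error or gap`) sit in a `flags=` attribute. Unknown
exception tokens are errors: the flag vocabulary is closed, and every
emitted token matches it character for character (including the
hyphen/underscore mix of `non-canonical_start_codon` versus
`non_canonical_splice_site`).

Two deliberate strictness rules: a transcript may mix strands **only** when
it carries the declared trans-splice flag (undeclared mixed-strand input is
rejected, because such models are routinely assumed to be errors and we
require explicit opt-in), and a CDS must lie within its transcript's exon
union. `N` bases propagate from the genome into spliced sequences, and any
codon containing `N` translates to `X`.

## Cistronic classification

The cistronic arity of a transcript is its number of ORFs; a gene's profile
collects the arities over all of its transcripts, and a gene is
*exclusively polycistronic* exactly when no isoform is monocistronic.
Noncoding isoforms contribute no arity.

The intercistronic distance between consecutive ORFs is measured on the
**mature transcript** (the practice being modeled does not state whether it
is measured on the transcript or the genome; the mature transcript is the
biologically meaningful frame for ribosome reinitiation or IRES-mediated
initiation, and it makes the metric invariant under upstream intron
insertion — a property the test suite asserts). The convention: distance =
(transcript coordinate of the first base of the downstream start codon) −
(transcript coordinate of the last base of the upstream stop codon) − 1, so
an immediately adjacent stop/start gives 0 and overlapping coding regions
give negative values, matching the sign of the curated −34 nt lower
bound. The stop codon is part of the annotated CDS.

Small-polypeptide bins split at 25 and 45 amino acids (stop excluded),
the screening classes under which small-ORF cistrons were found.

## Overlap classification

The substrate for all same-strand coding comparisons is the **codon offset
map**: for each genomic base of a spliced CDS, its position within its codon
(0, 1, 2) counted 5′→3′ along the transcript, continuing across introns.
Between two ORFs, shared genomic bases with *equal* offsets form same-frame
CDS overlap runs ("Genes with CDS overlap"); shared bases with *unequal*
offsets form multiphasic regions. Every shared coding base therefore falls
in exactly one of the two classes — a partition property tested over
randomized ORF placements.

Multiphasic regions are classified with the standardized comments, in this
precedence order (the source practice does not order its rules; the order
below resolves the two ambiguities):

1. cross-gene regions get the shared-coding-region comment;
2. within-gene regions touching the first coding exon get the
   first-coding-exon comment (involvement of the first coding exon is
   treated as more informative than the extent rule when both apply);
3. within-gene regions shorter than 40 nt that include a stop codon get
   "Alternative translation stop created by use of multiphasic reading
   frames within coding region" — the extent *includes* the stop codon, so
   <40 nt corresponds to strictly fewer than 13 amino acids
   (`multiphasic_aa_bound(40)`);
4. everything else gets the generic multiphase-exon comment.

Regions longer than 63 nt (>20 aa) carry an additional `long_overlap` mark.
The 40-nt rule is applied within genes only; whether it also applies to
cross-gene regions is left open by the comment vocabulary itself, whose
cross-gene text mentions no extent. Both thresholds live in `audit_config()`
with the curation thresholds as defaults.

Opposite-strand CDS intersections are reported as bidirectional regions
with their own verbatim comment. Same-strand gene pairs that share **no**
coding base (and no transcript) are classified on their terminal exons:
"shared promoter" is operationalized as an identical 5′-most exon start
coordinate on the same strand (no distance threshold is defined; exact
coordinate equality is the conservative choice), a shared 3′-terminal exon
gives `shared_3_utr`, and both at once gives `complex_atypical`. Two
configurations are recognized but deliberately emit no comment, mirroring
the decision that they are not unruly enough to flag: a gene nested in
another gene's intron on the same strand, and a 3′ UTR running over the
downstream gene's 5′ UTR.

## Splice-site classification

The candidate noncanonical set is derived, not hard-coded: all
donor–acceptor pairs at Hamming distance 1 from GT–AG with the donor G held
invariant, minus the two canonical pairs — exactly eight, verified in the
tests against an exhaustive 256-pair enumeration. AT–AC introns are their
own class (two bases off), subtyped U12/U2 by the 5′ consensus. The U12
consensus defaults to the regular expression `[GA]TATCC` anchored at the
intron start — donor dinucleotide followed by ATCC — because the minor
spliceosome's 5′ signal is the practical discriminator; branch-point
matching is omitted and the pattern is configurable. CA–TG boundaries with
a declared `endonuclease_spliced_intron` flag are the HAC1-type
(Ire1-processed) class; nonconforming introns on transcripts declared to
cross assembly gaps or strain variation are "convenience" splices; anything
else is `other_nonconforming`.

A *similar alternative splice* for a noncanonical intron is defined as an
annotated canonical intron of the same gene sharing exactly one boundary
(same donor position with a different acceptor, or vice versa); no window
is imposed beyond the gene. The nearest alternative boundary wins, ties
break toward the smaller coordinate shift and then toward the upstream
(5′-ward) option.

Junction audits check, in precedence order: exact coordinate match
(`matches_annotated`, the only verdict with offset 0); an unstranded or
opposite-strand AT–AC call coinciding with an annotated GT–AT intron
(`strand_flip_gt_at` — reading a GT–AT intron on the other strand yields
AT–AC, the classic unstranded-data artifact); whole-junction ±1 nt
displacement from a canonical annotated intron (`off_by_one_artifact`);
culling by read count < 2 or score < 0 (`low_frequency`; the source
practice culls "low-frequency" calls without printing numbers, so these are
config defaults); both boundaries within 6 nt of an annotated intron
(`misaligned_near_annotated`); otherwise `unsupported_noncanonical`. The
census's junction-support column counts exact coordinate matches regardless
of reported strand; near-misses are reported separately by the auditor
rather than folded into support.

The census table mirrors the reference layout: one row per noncanonical
pair (AT–AC split by U12/U2), a Total row that always equals the column
sums of the main rows, and U12-consensus GT–AG / GC–AG introns as footer
rows outside the Total. Intron context is assigned per supporting
transcript: introns 5′ of the CDS start count as 5′-UTR, introns of
ORF-less transcripts as lncRNA, everything else (including introns at or
past the CDS start, and hence 3′-UTR introns) as coding; an intron
supported by both coding and noncoding isoforms counts as coding.

## Exception-aware translation

Translation applies, in order: incomplete-stop completion, the +1
frameshift, then codon-by-codon translation. A declared non-AUG start
translates as methionine (near-cognate starts still pair with the
initiator Met-tRNA); a declared `undetermined` start translates from the
annotated first codon and records a caveat event only. Declared
selenocysteine stops become `U`, declared readthrough stops become `X`
(translation continues to the next declared or terminal stop; the
annotation must carry the final stop, since readthrough extents here come
from curation, not from re-prediction — conservation-based discovery is
out of scope, though `readthrough_extension_candidate()` lists the next
in-frame genomic stop as a curation aid). An *undeclared* internal stop is
an annotation inconsistency and errors with its codon index, as does a
declared exception pointing at a non-stop codon.

The +1 frameshift keeps the first `codon_index` codons, skips one
nucleotide, and resumes — the single supported geometry, after the one
known programmed case. Consequently a frameshifted CDS is 1 mod 3
nucleotides long in annotation coordinates, and validation checks the
*effective* (post-shift) length. Mitochondrial ORFs translate under NCBI
table 5 (AGA/AGG→S, AUA→M, UGA→W); a trailing `T` or `TA` is completed to
`TAA` by appended `A`s — any other remainder cannot arise from
polyadenylation and is an error. Genetic-code tables come from Biostrings'
registry; the package's own translator is checked against
`Biostrings::translate` as an independent oracle on 1000 random
exception-free ORFs.

## Flags and reports

Classifications bind to gene-level SO terms and transcript-level flag
tokens exactly as tabulated in `gene_so_vocabulary()` and
`transcript_flag_vocabulary()`; a CUG start implies both the generic
unconventional-start term and the CUG-specific term. Gene- and
transcript-level assignments are kept consistent by construction (a gene
carries SO:0000697 exactly when one of its ORFs declares readthrough, and
so on), and a test asserts each pairing. Multiphasic, bidirectional and
shared-exon findings become gene-model *comments*; the affected transcripts
are deliberately not flagged, since no translation rule changes. A-to-I
editing sites are genome-level passthrough only: overlapping genes are
tagged SO:0000548 and sites SO:0000250; edited transcript or polypeptide
sequences are never constructed.

Emitted FASTA headers use a fixed-order `key=value` grammar with a
semicolon-joined `flags` field (the upstream header grammar is only
proposed, so this grammar is the package's own, documented here). Reports
(JSON + TSV) have stable ordering; identical inputs give byte-identical
outputs, which the acceptance suite verifies.

## The synthetic fixtures

`generate_fixture()` plants, by default, one locus of every exception
category — mirroring that several phenomena have exactly one or two known
representatives (one endonuclease-spliced intron, one programmed
frameshift, a handful of selenoproteins, three mitochondrial
incomplete-stop genes) — plus two plain control genes, each laid out on a
~16 kb main contig with 150 nt of random spacer, and one mitochondrial
gene on a separate circular contig. Planted ORFs are constructed codon-wise
from non-stop codons, so expected peptides are computable at planting time;
loci that couple two reading frames (multiphasic, overlapping cistrons,
bidirectional) fix the required motifs (starts, stops, splice
dinucleotides, the alternative AG acceptor) and resample the free positions
until both frames are stop-free. Intron interiors are resampled so they
never accidentally match the U12 consensus unless a U12 intron was
requested. Two construction details differ deliberately from the simplest
reading of the scenario they emulate: the within-gene multiphasic locus
shifts its alternative acceptor by 2 nt rather than 1 (two overlapping AG
acceptors one base apart cannot coexist on one sequence), and similar
alternative splices are only planted for GT-donor pairs — donor-variant
(GA–AG, GG–AG) and AT–AC/U12 introns get none, matching the reported
exceptions to the similar-alternative pattern.

The fixtures emulate structure, not statistics: background composition is
uniform, codon usage is uniform over sense codons, intron lengths and
expression are unrealistic, and junction calls are planted rather than
derived from reads. Passing the closed loop (audit of a generated fixture
reproduces its manifest exactly, over 20 seeds) therefore demonstrates that
the classifiers implement their rules correctly on unambiguous input — not
that they are robust to noisy junction data, assembly errors, or the
annotation ambiguities of a real genome.

## Problem sizes and numerical choices

The test suite and acceptance script use desk-scale problems chosen as the
smallest sizes that exercise every rule: ~42-gene fixtures over 20 seeds
for recovery, 1000 random ORFs (4–80 aa) for the translation oracle, and
the reference per-pair census as a 12-row arithmetic fixture. Genome-scale
figures (tens of thousands of introns, hundreds of readthrough genes)
depend on an external curated annotation release and are deliberately not
reproduced. There is no floating-point arithmetic anywhere in the
classifiers — coordinates, counts and thresholds are integers, so all
comparisons are exact; determinism comes from fixed iteration orders,
sorted identifiers and binary-mode writes (LF line endings everywhere).

## Known limitations

* Readthrough, selenocysteine, non-AUG starts and frameshifts are taken
  from declarations; the package does not predict them (no PhyloCSF-style
  conservation, no SECIS or IRES modeling, no ribosome profiling).
* Junction auditing classifies provided calls; it does not call junctions
  from reads, and repeat-driven spurious calls across tandem paralogs are
  reported only as `unsupported_noncanonical`.
* The U12 tag uses the 5′ consensus only; a `[GA]TATCC` match in a U2
  intron would be mis-tagged, and a degenerate U12 5′ end missed.
* Edited (A-to-I) transcript sequences are not represented, only flagged.
* GTF/GenBank flat files are out of scope; input is the documented GFF3
  dialect.
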