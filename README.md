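# GeneModelAudit

Genome annotations are written for well-behaved genes: one gene per mRNA, one
ORF per transcript, GT–AG introns, an AUG start and a stop codon that stops.
Real genomes bend every one of those rules. A small but important set of gene
models carry polycistronic (mostly dicistronic) transcripts, exons shared
between neighboring genes, coding regions translated in more than one reading
frame ("multiphasic") or on both strands ("bidirectional"), noncanonical or
endonuclease-processed splice sites, U12-type introns, trans-spliced
transcripts, non-AUG translation starts, selenocysteine recoding, stop-codon
readthrough, programmed +1 ribosomal frameshifting, and mitochondrial
transcripts whose stop codon only exists after polyadenylation. Naive
pipelines silently mistranslate or discard these models.

GeneModelAudit is an R package for curators and pipeline authors that makes
these exceptions explicit. It reads a genome (FASTA) and gene models (GFF3,
with a small documented dialect for multi-gene transcripts and declared
exceptions) and:

* classifies transcripts and genes by **cistronic arity** and computes
  intercistronic distances on the mature transcript (0 at stop/start
  adjacency, negative for overlapping ORFs);
* classifies **same-strand and opposite-strand overlaps**: shared 5′/3′
  noncoding exons, same-frame CDS overlap, multiphasic regions (with the
  <40 nt "alternative translation stop" rule — equivalently <13 aa, stop
  codon included — and the >63 nt long-overlap mark), and bidirectional
  coding regions;
* classifies every **intron boundary pair**: canonical GT–AG / GC–AG, the
  eight candidate one-base-off pairs with invariant donor G, AT–AC with
  U12/U2 subtyping by the 5′ consensus (`[GA]TATCC` by default),
  HAC1-type endonuclease-spliced introns (declared), and "convenience"
  splices drawn across sequence gaps; finds similar alternative canonical
  splices and produces a per-pair census table;
* **audits RNA-seq junction calls** against the annotated introns,
  recognizing the common artifact classes: strand-flipped AT–AC calls over
  GT–AT introns, one-base-off junctions near canonical splices,
  low-frequency calls, and slightly misaligned junctions;
* **translates every ORF under its declared exceptions**: non-AUG starts
  become methionine, readthrough stops become `X`, selenocysteine becomes
  `U`, the +1 frameshift reframes the CDS, mitochondrial CDSs use NCBI
  translation table 5 and have incomplete stops completed to UAA;
* binds every classification to **Sequence Ontology terms** (e.g.
  `gene_with_dicistronic_mRNA` SO:0000722), the standardized
  transcript-level **flag vocabulary** (e.g. `stop_codon_read_through`),
  and the standardized gene-model comment strings, and emits flagged
  transcript/protein FASTA plus JSON/TSV reports;
* ships a **deterministic fixture generator** that plants every exception
  category in a synthetic genome together with a ground-truth manifest, so
  the whole pipeline is testable end to end without any external data.

A-to-I editing sites are passed through at the genome level only: overlapping
genes are tagged `gene_with_edited_transcript` (SO:0000548) and sites
`modified_RNA_base_feature` (SO:0000250); edited transcript sequences are not
represented.

## Worked example

```r
library(GeneModelAudit)

fix <- generate_fixture(fixture_spec(seed = 1))   # synthetic genome + models
aud <- audit_annotation(fix$set, fix$genome,
                        junctions = fix$junctions,
                        editing_sites = fix$editing_sites)
print(aud)
#> annotation_audit
#>   genes: 42  transcripts: 43  introns: 26
#>   polycistronic transcripts: 4
#>   noncanonical introns: 10
#>   genes with SO terms: 19
#>   flagged transcripts: 23
```

42 genes were planted (two plain controls plus one locus per exception
category); the audit recovers 4 polycistronic transcripts (di-, tri-,
tetracistronic and a frame-overlapping dicistronic pair), 10 noncanonical
introns and 19 genes deserving a Sequence Ontology tag. The splice census
mirrors the annotated introns per donor–acceptor pair:

```r
aud$census
#>           pair n_introns n_junction_support n_similar_alternative ...
#> 3        GT-TG         1                  1                     1
#> 8        GA-AG         1                  1                     0
#> 11       Total        10                 10                     6
#> 12 GT-AG (U12)         1                  1                     0
```

Only GT-donor pairs have a similar alternative canonical splice — GA–AG and
U12-type introns do not, which is exactly the pattern the census is designed
to surface. Every planted expectation is checked against the manifest:

```r
verify_audit(aud, fix$manifest)[c("n_checks", "n_failed")]
#> $n_checks [1] 266     $n_failed [1] 0
```

On real data, `read_genome()`, `read_annotation()`, `read_junctions()` and
`read_editing_sites()` load the inputs, and `emit_report()` /
`emit_flagged_fasta()` write the audit artifacts. A command-line front end
with subcommands `audit`, `translate`, `splice-census`, `junctions` and
`fixtures` is installed at `inst/cli/gene-model-audit.R`.

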