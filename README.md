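# tnseqr

Gene-essentiality analysis for transposon insertion sequencing (Tn-seq)
with TA-targeting transposons (TcBuster, Sleeping beauty and relatives)
in compact yeast genomes.

## The problem

In a saturated transposon mutant library, insertions that disrupt an
essential gene remove that cell from the pool, so essential genes show
far fewer surviving insertions than dispensable ones. Sequencing the
transposon–genome junctions locates every insertion; the analytical task
is to turn raw junction reads into a per-gene essentiality call while
correcting for how many insertion targets (TA dinucleotides) each gene
offers, for the transposons' sequence and chromatin biases, and for the
fact that insertions near a gene's 3′ end are often tolerated even in
essential genes.

`tnseqr` implements the full path:

1. **Genome model** — index every TA dinucleotide (the only possible
   insertion sites) and define each gene's *effective region*, the
   5′-most 90% of its span.
2. **Junction processing** — trim the transposon terminus and sequencing
   adapter off each read, map the genomic fragment requiring a unique
   best ungapped alignment (≤ 3 mismatches; ties discarded as
   multi-mapped), snap the junction to its TA site, and collapse
   duplicates into an insertion-site library. Libraries from multiple
   pools can be merged, compared (Venn overlaps), and assessed for
   saturation.
3. **Per-gene statistics** — for each gene, the Gene Insertion Index

   GII = (no. of unique insertions in the effective region × K) / (no. of TA sites),

   with K the genome-average TA count per gene (72 for the genome this
   analysis was designed around), and the read density
   (reads in the effective region / TA sites) as a secondary feature.
4. **Essentiality model** — a two-feature L2-regularized logistic
   regression on standardized (GII, read density) returning the
   non-essentiality probability

   NEP = 1 / (1 + exp(−(β₁x₁ + β₂x₂ + β₀))),

   with the published coefficients (5.737, 0.082, 2.098) available as a
   built-in. Genes are classified **putatively essential** (NEP < 0.03),
   **ambig1** (0.03 ≤ NEP < 0.5), **ambig2** (0.5 ≤ NEP ≤ 0.9) or
   **putatively non-essential** (NEP > 0.9); genes with fewer than 15 TA
   sites, marker genes, and genes with undefined features are excluded
   with a reason.
5. **Condition comparison** — genes non-essential under one growth
   condition (NEP > 0.9) but required under another (NEP < 0.5) are
   condition-specific candidates (e.g. a glucose vs methanol screen).
6. **Simulator** — generates genomes, annotations, biased insertion
   libraries and junction-read FASTQ with known ground truth, so every
   stage of the pipeline can be validated end to end.

## Worked example

A fully synthetic run: simulate a 300 kb genome with 300 genes (20%
essential), draw 6,000 insertions, emit junction reads, run them back
through the pipeline, train the classifier, and classify the genome.

```r
library(tnseqr)

cfg <- simulation_config(seed = 42, chromosome_lengths = c(150000L, 150000L),
                         n_genes = 300L, n_insertions = 6000L)
sim <- simulate_genome(cfg)
ta  <- index_ta_sites(sim$genome)
ta
#> TA site index: 26138 sites on 2 chromosome(s)
#>   chr1: 13169 sites
#>   chr2: 12969 sites

labels <- simulate_gene_labels(sim$genes, fraction_essential = 0.2, seed = 43)
ins <- simulate_insertions(sim$genome, sim$genes, labels, cfg)

spec <- junction_read_spec()   # TcBuster-style terminus + adapter
fq <- tempfile(fileext = ".fastq")
simulate_junction_reads(ins$library, sim$genome, spec, seed = 44,
                        fastq_path = fq)
lib <- call_insertion_sites(
  map_fragments(trim_junction_reads(fq, spec), sim$genome), ta)
lib
#> Insertion library 'library': 5998 unique sites, 15568 reads

st  <- compute_gene_stats(lib, sim$genes, ta, constant_k = NULL)
fit <- fit_nep_model(st, labels, C = 10, repeats = 10, seed = 45)
fit
#> Fitted non-essentiality logistic model
#>   NEP = 1 / (1 + exp(-(4.791*x1 + 4.278*x2 + 10.347)))
#>   held-out accuracy: mean 0.982 (sd 0.009) over 10 splits

rec <- classify_essentiality(st, fit, min_ta = 15)
attr(rec, "summary")
#>     putatively_essential                   ambig1                   ambig2
#>                       38                       25                        2
#> putatively_non_essential                 excluded
#>                      235                        0
```

Reading the output: of 6,000 simulated insertions, 5,998 survive the
trim → map → call round trip (the two losses are multi-mapped
fragments). The fitted model separates the labelled classes with 98%
held-out accuracy on this draw, and the genome-wide classification
recovers the simulated truth almost exactly — cross-tabulating against
the ground-truth labels:

```r
validate_against_labels(rec, labels)$error_rate
#> 0.003
```

i.e. 1 of 300 genes lands in the confidently-wrong category; the rest
are correct or fall in the ambiguous bands.

With real data, `load_genome()` / `load_annotation()` take FASTA and
GFF3, `trim_junction_reads()` takes the sequencing FASTQ (or
`read_alignments_sam()` accepts any aligner's SAM), and
`published_nep_model()` classifies without retraining once
standardization parameters from a labelled set are supplied.

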