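# phamily

Discovery, classification, and biogeography of phage families from
metagenomic data — as one reproducible, fully testable R pipeline.

## The problem

A newly isolated phage often turns out to be the first cultured member
of a large, previously invisible family: profile searches with its
hallmark genes (terminase large subunit, major capsid protein,
bifunctional primase–polymerase) pull hundreds of related uncultivated
virus genomes (UViGs) out of metagenomic contig collections. Turning
that pile of contigs into a family description requires a chain of
analyses — quality filtering, dereplication, ortholog detection,
genus-level subgroup delineation, core-gene phylogenomics, integration
(prophage) analysis, and read-recruitment biogeography. `phamily`
implements that chain end to end for desk-scale data, with every
threshold recorded in a run manifest, and ships a synthetic
phage-family generator with complete planted truth so that each stage
is verifiable without any external database.

## The statistics at the core

* **AAI** (average amino-acid identity): mean percent identity over
  reciprocal-best-hit protein pairs between two genomes; with the
  shared-gene fraction (RBH count / smaller gene count) it delineates
  genus-level subgroups (`AAI > 60`, `shared > 0.5`, connected
  components).
* **Gene-sharing network**: for genomes with *a* and *b* protein
  clusters of which *c* are shared out of *N*, the edge weight is
  `max(0, −log10 P − log10 T)` with
  `P = Σ_{i=c}^{min(a,b)} C(a,i) C(N−a,b−i) / C(N,b)` and *T* the
  number of genome pairs.
* **Core-gene phylogenomics**: center-star MSAs of the six core genes
  (portal, TerL, capsid, PD-(D/E)XK nuclease, AAA ATPase, Prim-Pol),
  gap-trimmed, concatenated, neighbor joining on pairwise-deletion
  p-distance, column-bootstrap supports.
* **attP/attB detection**: maximal exact matches (≥ 12 bp) between
  phage and host, ranked by host-tRNA overlap, with Campbell-integration
  arithmetic predicting attL/attR; junctions are confirmed from
  soft-clipped read alignments.
* **RPKM biogeography**: read recruitment at ≥ 95% identity / ≥ 50 bp
  aligned / ≥ 80% read coverage, `RPKM = count / ((len/10³)(total/10⁶))`,
  environmental correlations, and a Mann–Whitney contrast between
  high- and low-G+C genomes.

See `vignettes/phage-family-pipeline.Rmd` for the full model and the
design decisions.

## Worked example

```r
library(phamily)

res <- run_pipeline(list(
  seed = 42, out_dir = "runs/demo",
  family = list(n_subgroups = 2, genomes_per_subgroup = 3,
                ancestor_gene_count = 15, genome_len_bp = 16000),
  decoys = list(n = 10, len_bp = 12000),
  thresholds = list(phylo = list(bootstrap_n = 50))))

str(res$manifest$summary[c("retrieval_precision", "retrieval_recall",
                           "n_core_genes", "subgroup_ari",
                           "min_subgroup_support")])
#> $ retrieval_precision : num 1
#> $ retrieval_recall    : num 1
#> $ n_core_genes        : int 6
#> $ subgroup_ari        : num 1
#> $ min_subgroup_support: num 100

head(res$stats, 4)
#>   genome_a genome_b  aai rbh_count shared_frac
#> 1   sg1_g1   sg1_g2 73.7        15       0.882
#> 2   sg1_g1   sg1_g3 74.9        15       0.882
#> 3   sg1_g2   sg1_g3 73.9        17       0.944
#> 4   sg1_g1   sg2_g1 36.3         9       0.692

res$subgroups
#>   genome subgroup
#> 1 sg1_g1        I
#> 2 sg1_g2        I
#> 3 sg1_g3        I
#> 4 sg2_g1       II
#> 5 sg2_g2       II
#> 6 sg2_g3       II
```

Reading the output: hallmark-profile retrieval recovered exactly the
six planted family genomes from the decoy pool (precision = recall
= 1); all six planted core genes came back as family-wide ortholog
groups; within-subgroup AAI sits at the planted ~75% versus ~36–44%
between subgroups, so the AAI/shared-gene gates split the family into
the two planted genus-level subgroups (adjusted Rand index 1 against
the generator's truth), and both subgroups are monophyletic in the
core-gene tree with 100% bootstrap support. The run directory contains
the corresponding TSV/FASTA/newick outputs plus `manifest.json` with
every threshold and a content hash of every file; rerunning with the
same seed reproduces the hashes byte for byte.

A thin command-line front end is installed with the package
(`inst/exec/phamily`): `phamily run --config cfg.json` and
`phamily synth family|lysogen|viromes --out DIR --seed N`.

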