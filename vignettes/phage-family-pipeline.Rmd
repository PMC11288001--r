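---
title: "Mining and characterising a phage family: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and characterising a phage family: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the pipeline does

`phamily` reconstructs, as one coherent and fully testable toolchain, the
standard desk workflow for characterising a novel phage family starting
from one isolate genome:

1. **Retrieval** — position-specific scoring models (PSSMs) built from
   seed alignments of hallmark genes (terminase large subunit, major
   capsid protein, bifunctional primase–polymerase) fish candidate
   family members out of a contig collection under a BLAST-style filter
   cascade (e-value ≤ 1e-3, bit score ≥ 50, identity vs nearest seed
   ≥ 25%, profile coverage ≥ 80%).
2. **Quality control** — a length-proxy completeness filter
   (completeness < 50% drops a genome) and CD-HIT-convention greedy
   dereplication (identity ≥ 0.95 with coverage of the shorter ≥ 0.8).
3. **Orthology** — an all-vs-all protein similarity graph (e ≤ 1e-3,
   identity ≥ 25%, query coverage ≥ 50%) clustered with Markov
   clustering; ortholog groups present in every genome are the core
   genes.
4. **Taxonomy** — average amino-acid identity (AAI; mean percent
   identity over reciprocal best hits) and the shared-gene fraction
   (RBH count over the smaller gene count) delineate genus-level
   subgroups as connected components over the gates AAI > 60 and
   shared fraction > 0.5; a hypergeometric gene-sharing network and a
   normalised proteomic distance provide two independent lines of
   evidence.
5. **Phylogenomics** — per-core-gene center-star alignments, gap-column
   trimming (> 50% gaps), fixed-order concatenation (portal, TerL,
   capsid, PD-(D/E)XK nuclease, AAA ATPase, Prim-Pol), pairwise-deletion
   p-distance, neighbor joining, and column-bootstrap supports.
6. **Lysogeny** — attP/attB attachment-site cores as maximal exact
   matches (≥ 12 bp) between phage and host, attL/attR junction
   detection from clipped read alignments, and prophage calls inside
   bacterial contigs (nucleotide identity ≥ 95%, phage-query coverage
   ≥ 50%).
7. **Biogeography** — read recruitment (≥ 95% identity, ≥ 50 bp
   aligned, ≥ 80% of the read), RPKM normalisation, environmental
   correlation/regression, and a Mann–Whitney contrast between high-
   and low-G+C genomes (split at 45%).

Every stage is driven through `run_pipeline()`, which records every
threshold and a content hash of every output in a JSON manifest; a rerun
under the same seed and configuration is byte-identical.

# The synthetic family generator

Real family discovery depends on external contig databases that cannot
ship with a package. `generate_family()` therefore produces a family
with *complete planted truth* so that every downstream stage can be
scored exactly.

The divergence model is star-within-star: one family ancestor proteome,
per-subgroup ancestors, then per-genome leaves. Mutated sites redraw
from the BLOSUM62 marginal residue background, so with `c = Σ f²`
(the chance two redrawn sites agree) the expected pairwise identity of
two leaves whose combined no-mutation probability is `A` is
`A + (1 − A)·c`. Branch rates are solved in closed form from the two
targets (within-subgroup mean identity, default 0.75; between-subgroup,
default 0.35) and then refined in two deterministic passes against the
package's own aligner: optimal local-alignment identity (the AAI
estimator) runs one-to-two points above per-site identity at high
divergence because the optimal alignment may trim and realign, so the
generator measures that offset on the ancestor proteome and re-solves
the closed form for the shifted target. Realized AAI lands within
about ±2 points of target.

Nucleotide sequences are produced by back-translation with synonymous
codon choice weighted `∝ exp(γ·GC(codon))`; γ is solved per genome
(uniroot on the expected coding G+C) so that coding sequence, AT-only
"stop islands", spacers and the tRNA locus jointly hit the per-subgroup
genome G+C target within ±0.03. Defaults span 0.38–0.62 across
subgroups, inside the 0.35–0.66 band the family is allowed to occupy.
Gene-length budgets target ~92% coding density (phage-like); every gene
is flanked by a 16-bp stop island (`TTAATTAATTAATTAA`, its own reverse
complement) that terminates reading frames on both strands so the ORF
caller recovers planted proteins exactly.

Gene content varies realistically: each subgroup loses ~8% of accessory
genes and gains three exclusive ones, each genome loses a further ~8%
sporadically, and a family integrase is carried with probability 0.85.
Every non-core gene is forced absent from at least one genome, so the
family-wide core is exactly the six planted hallmark/core genes.

`generate_lysogen()` plants a random att core (default 13 bp, matching
the length scale of tRNA-associated integration sites) once in the
middle of the host tRNA and once downstream of the phage tRNA, checks
genome-wide uniqueness (up to 100 redraws), forces mismatching flanking
bases so the maximal exact match is exactly the core, and performs
Campbell integration: the lysogen is
`host-prefix | core | phage-suffix | phage-prefix | core | host-suffix`,
so its length is exactly host + phage and each junction carries one
core copy.

`simulate_viromes()` draws samples along a northern-hemisphere latitude
gradient (5–70°); temperature is anti-correlated with latitude by
construction (28 − 0.33·lat plus noise) and salinity is uncorrelated.
Per-sample expected relative abundance is
`a ∝ base · exp(β·z + ε)` with `z` the standardized latitude, `β = ±1`
by G+C class (high-G+C genomes positive), `ε` lognormal with σ = 0.1,
and `base` optionally boosted for low-G+C genomes. Reads are drawn
multinomially ∝ abundance × length with substitution-only errors
(default 0.5%); an indel process is deliberately absent so that the
ungapped recruitment thresholds are crisp.

**What the generator does not emulate:** realistic phylodynamics (no
recombination, no rate heterogeneity, no insertions/deletions in
proteins), sequencing indels and quality-score variation,
amplification/G+C bias, chimeric contigs, and uneven genome
completeness. Passing the planted-truth suite therefore demonstrates
correctness of the algorithms under clean assumptions, not performance
on raw environmental data.

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| retrieval gates | e ≤ 1e-3, bits ≥ 50, id ≥ 0.25, cov ≥ 0.80 | — | standard hallmark-search cascade |
| completeness drop | < 0.5 | fraction of expected length | length proxy for model-based estimators |
| dereplication | id ≥ 0.95, cov-of-shorter ≥ 0.8 | fraction | CD-HIT `-c 0.95 -aS 0.8` convention |
| ortholog edges | e ≤ 1e-3, id ≥ 0.25, qcov ≥ 0.5 | — | BLASTp-style orthology gates |
| ortholog MCL inflation | 1.5 | — | granularity convention of ortholog-detection tools; 2.0 over-fragments genus-level families |
| network protein clusters | e < 1e-5, bits ≥ 50, inflation 2.0 | — | gene-sharing-network convention |
| subgroup gates | AAI > 60, shared > 0.5 | percent / fraction | genus-level demarcation |
| phylogeny | gap-column > 0.5 trimmed; ≥ 4 of 6 genes per genome; 100 bootstraps | — | tolerate occasional gene absence |
| att core | ≥ 12 bp exact | bp | one below the observed 13-bp case, found with margin |
| junction clips | ≥ 20 bp, ≥ 95% identity, ±3 bp clustering, ≥ 2 reads | — | soft-clip evidence conventions |
| prophage call | id ≥ 0.95, phage-query coverage ≥ 0.5 | — | a prophage is a full phage inside a long contig |
| recruitment | id ≥ 0.95, ≥ 50 bp aligned, ≥ 80% of read | — | read-mapping convention for species-rank abundance |
| G+C split | 0.45 | fraction | boundary between the high- and low-G+C ecological classes |

# Numerical and design choices

* **Identity** is matches over *all* alignment columns, gaps included
  (BLAST-report convention), because every threshold in the cascade
  descends from BLAST-style output. Coverage is per-sequence; where a
  gate says "alignment coverage" without a side, the query side is
  used.
* **Bit scores and e-values** use fixed published ungapped BLOSUM62
  Karlin–Altschul constants (λ = 0.318, K = 0.13) with search space
  |q|·|s|·n_subjects. They exist only to give the published-style
  threshold semantics; they are documented as approximate.
* **PSSM pseudocounts** are a unit mass distributed proportionally to
  the background (Henikoff-style), so an unobserved residue scores
  `log2(1/(n+1))` regardless of rarity; uniform Laplace smoothing would
  let rare unobserved residues outscore the observed consensus at small
  seed counts. PSSM scores are kept in half-bit units so the shared gap
  penalties (11/1) and bit mapping are commensurate with BLOSUM62.
* **Shared-gene fraction** uses the smaller gene count as denominator
  (detects containment of fragments).
* **RPKM denominator** is the per-sample total of *recruited* reads:
  the comparison is within the family-specific reference set. Raw
  library totals can be passed instead.
* **Equal-best recruitment ties** go to the lexicographically smallest
  reference id — deterministic rather than discarded.
* **Exact small-sample tests**: Mann–Whitney p-values are computed by
  full enumeration when both groups have ≤ 8 observations (midranks for
  ties); Pearson correlation p-values by full permutation when n ≤ 8.
  Above those sizes, the usual normal/t approximations (with tie
  correction) apply.
* **Center-star MSA + NJ** stand in for progressive ML phylogenomics:
  the package's claim is clade recovery on families with clear
  subgroup structure, not maximum-likelihood parity. Negative NJ branch
  lengths are clamped to zero; p-distances use pairwise deletion so
  all-gap padding for missing genes is tolerated; a pair with fewer
  than 10 comparable columns is an error naming the pair.
* **Gene calling** is a deterministic six-frame scanner (starts ATG/
  GTG/TTG, bacterial code, longest ORF per stop-bounded segment,
  ≥ 30 codons). It is a stand-in, not a contribution; real analyses
  can import an external GFF. A `suppress_shadows()` step drops calls
  largely contained in a clearly longer overlapping call (≥ 50%
  containment and ≥ 1.2× length); near-equal-length overlaps are
  resolved by a miniature coding-potential score — the KL divergence of
  the call's amino-acid composition from the background, which is near
  zero for genuine proteins and strongly positive for frame shadows of
  G+C-biased coding sequence. The generator also interleaves stop
  islands into any intergenic spacer longer than 64 bp, so no spurious
  intergenic ORF of ≥ 30 codons can arise.
* **Subgroup assignment** uses connected components over the AAI and
  shared-gene gates. Components are order-free; labels (roman numerals
  by decreasing size, singletons by member id) are re-derived from the
  partition, so the output is invariant to input order.
* **tRNA adjacency** is a *ranking* feature for att sites, never a
  filter — integration sites are often but not always tRNA-associated.
* **Determinism**: all stochastic entry points take an integer seed and
  route through one stated PRNG (Mersenne–Twister, inversion normals);
  derived stream seeds stay below 2^31.

# Problem sizes used by the test-suite

The default study conditions are 3 subgroups × 5 genomes of 57.7 kb
(63 ancestor genes), 80 decoy contigs for retrieval, a 60-kb host for
the lysogeny benchmark with 12,000 junction-detection reads, 12 virome
samples (2,000 reads each) for the gradient analysis, a 2-genome ×
4-sample × 20,000-read simulation for recruitment fidelity, and a
30 + 30 genome contrast (6-kb genomes, 3× planted low-G+C advantage)
for the abundance test. These sizes keep a full run on one CPU in the
minutes range while leaving all recovery margins wide.

# Known limitations

* The aligners are exact dynamic programming / ungapped seed-and-extend;
  there is no translated search, no composition-based statistics, and
  the nucleotide search performs no gapped extension — appropriate for
  the ≥ 95%-identity regimes it serves, not for distant nucleotide
  homology.
* The completeness filter is a length proxy; it cannot detect chimeras
  or contamination.
* The profile search is a PSSM, not a full profile HMM: no forward
  posterior, no per-domain envelopes, no iterative refinement.
* Connected-component subgroup assignment can chain two subgroups
  through a single borderline pair; the gene-sharing network and the
  tree are emitted alongside precisely so such cases can be inspected.
* Real-data performance (uneven completeness, indels, database-scale
  search) is out of scope for the bundled benchmarks.
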