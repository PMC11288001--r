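# Deposited-accession sequences (user-supplied)

The accession-based checks in the test-suite compare statistics computed
by this package against values reported for the deposited sequences of
the CRP-810 study system. The sequences are not redistributed with the
package; on a network-capable machine fetch them from GenBank and place
them here as plain FASTA:

| file | content |
|---|---|
| `crp810_genome.fasta` | phage CRP-810 complete genome (accession OR671924) |
| `crp810_terl.faa` | CRP-810 terminase large subunit protein |
| `htvc023p_terl.faa` | pelagiphage HTVC023P TerL protein |
| `crp810_tailfiber.faa` | CRP-810 tail fiber protein |
| `htvc025p_tailfiber.faa` | pelagiphage HTVC025P tail fiber protein |
| `fzcc0198_16s.fasta` | host FZCC0198 16S rRNA gene (accession PP816027) |
| `hkcca1288_16s.fasta` | reference strain HKCCA1288 16S rRNA gene |

For example, with NCBI EDirect or a plain efetch URL:

```sh
curl -o crp810_genome.fasta \
  'https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi?db=nuccore&id=OR671924&rettype=fasta&retmode=text'
curl -o fzcc0198_16s.fasta \
  'https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi?db=nuccore&id=PP816027&rettype=fasta&retmode=text'
```

The protein files are the translated CDS features annotated as
"terminase large subunit" / "tail fiber protein" extracted from the
corresponding GenBank records. Without these files the accession test
reports failure.
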