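# Deposited study data (not redistributed)

The D-loop analyses of the original Brandt's vole survey can be reproduced
from two files that this package does **not** bundle (the sequences live in
GenBank and the count table in the study's supplementary material; neither
is redistributed here and no network access is assumed at build or test
time):

- `dloop_haplotypes.fasta` — the 30 deposited haplotype sequences,
  GenBank accessions KY354521-KY354550, aligned (e.g. with `mafft --auto`)
  and with records renamed `H1` ... `H30` in accession order.
  One-time fetch, for example:

      for i in $(seq 521 550); do
        curl -s "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi?db=nuccore&id=KY354$i&rettype=fasta&retmode=text"
      done > raw.fasta
      mafft --auto raw.fasta > dloop_haplotypes.fasta

- `table_s5_counts.tsv` — haplotype occurrence counts per sampling site
  (TSV with header `haplotype	site	count`, haplotype ids `H1` ... `H30`,
  counts summing to 746), transcribed from the survey's supplementary
  haplotype-frequency table.

Place both files in this directory (or the installed package's
`extdata/deposited/`) and the D-loop reproduction tests in
`tests/testthat/test-acceptance.R` will pick them up.
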