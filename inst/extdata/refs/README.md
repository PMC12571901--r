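# Reference sequence cache

Two acceptance checks compare against RefSeq records that are not
redistributed with the package. To run them, download:

- `NC_004629.1.gb` — Pseudomonas phage phiKZ, complete genome (GenBank
  flat file, e.g. from NCBI efetch `db=nuccore&id=NC_004629.1&rettype=gbwithparts`).
- `PhiKZ155.faa` — protein sequence of the phiKZ155 CDS from NC_004629.1
  (FASTA).
- `PhiPA3_gp176.faa` — protein sequence of the gp176 CDS from NC_028999.1
  (FASTA).

Place them in this directory and reinstall the package; the corresponding
tests in `tests/testthat/test-acceptance.R` will then run. Without these
files those two tests report failure with instructions, and everything
else runs offline.
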