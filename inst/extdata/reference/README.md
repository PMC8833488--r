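# Optional reference data

The package never downloads data. Two integration checks in the test
suite reproduce published splice-score and protein-truncation values and
need externally obtained reference inputs placed in this directory. They
are not distributed with the package (the acceptor model tables are far
too large for a source package and the sequences should come from an
authoritative source); without them those two checks report failure with
a pointer to this file.

## `transcript_cds.fasta`

A FASTA file with the coding sequences (CDS, ATG..stop) of:

- `ENST00000261623` — CYBA (GRCh37/Ensembl)
- `ENST00000252826` — TRPM4 (GRCh37/Ensembl; NM_017636.4 equivalent)

Sequence names must start with the transcript ID. Obtainable from
Ensembl BioMart or `https://rest.ensembl.org/sequence/id/<ID>?type=cds`.

## `mes_acceptor_tables/`

The nine 3' splice-site maximum-entropy model tables of the published
MaxEntScan distribution, named `me2x3acc1` .. `me2x3acc9` (plain float
per line, k-mers in base-4 lexicographic order, A=0 C=1 G=2 T=3). These
files ship with the `fordownload` archive of the MaxEntScan `score3`
tool. They hold probability/background ratios, so they are loaded with
`tables_are_ratios = TRUE`.

## `trpm4_context.tsv`

Tab-separated, header `name	sequence	canonical_offset`, two rows:

- `wt`: GRCh37 genomic context spanning the TRPM4 intron 1 / exon 2
  boundary (at least 30 nt of intron and 14 nt of exon), with
  `canonical_offset` the 1-based position in `sequence` of the last
  intronic nucleotide (the G of the canonical acceptor AG).
- `mut`: the same context carrying c.25-1G>T, same offset convention.
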