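Place the public records for accession-based verification here:

  cds.fasta       nucleotide coding sequence of the recovered candidate
                  (e.g. the deposited GenBank CDS)
  ortholog.fasta  amino-acid sequence of the mammalian ortholog protein

Then run gcrescue::check_accession_targets(). No records are bundled and
the package performs no network access.
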