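Place a local copy of the public Hordeum vulgare chloroplast reference
here to enable the checks that depend on it:

  NC_008590.fasta   required (plain FASTA; the record is circular)
  NC_008590.gb      optional GenBank flat file -- supplies the CDS feature
                    table used by the exonic-annotation checks
  NC_008590.gff3    optional alternative to the .gb feature table

The lookup directory can be overridden with
options(plastotyper.reference_dir = "/some/dir"); see ?hv_reference_path.
These files are not redistributed with the package.
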