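Synthetic fixtures
==================

yprime_reference_synthetic.fasta
    Reference Y' element set generated by yprime_reference() from the
    built-in template family (build_templates(), default seed).  These are
    synthetic stand-ins for the S288C reference Y' elements, not real
    genomic sequence.

motif_36mer_synthetic.fasta
    The built-in degenerate 36-mer consensus (IUPAC codes) used to seed the
    internal-repeat scan; a synthetic stand-in for the published consensus,
    which is not reproduced here.

ca_patterns_synthetic.fasta
    The built-in CA-rich Pattern 1 (37 bp) and Pattern 2 motifs; synthetic
    stand-ins with the documented compositional properties.

All three files are reproducible from package code; they are shipped so
that command-line runs can point at concrete input files.
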