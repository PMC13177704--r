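>P1_synthetic
CAACCAAGCACCAATCAACCACAAGCAACCTCAGCAA
>P2_synthetic
CCAAACACAAGCCACAAGCAACCTCAGCAAA
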