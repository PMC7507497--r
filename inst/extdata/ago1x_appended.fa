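>AGO1x_appended nucleotides appended after the annotated AGO1 stop codon in the pIRES-Neo-FLAG/HA-AGO1x construct
aggcagaacgctgttacctcactggatagaagaaagctttccaagccccaggagctgtgccacccaaatccagaggaagcaaggaggagggaggtggggtag
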