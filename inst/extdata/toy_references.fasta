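>ref_dreissena_rostriformis
ACGTACGTGGCCAATTGGCCAATACGTACGTTGCAAGGTCCAATTGGCAACGTTACGGAT
>ref_dreissena_polymorpha
ACGTACGTGGCCAATTGGCCAATACGTACGTTGCAAGGTCCAATTGGCAACGTTACGGTA
>ref_lasmigona_costata
ACGTTCGAGGCCTATTGGACAATACGAACGTAGCAAGGACCAATAGGCAACCTTACGCAT
>ref_micropterus_nigricans
TTGGCCAACGGTTACGATCCGGATTACGGCATTAGCCATGGCTTAACGGATCCGTTAAGC
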