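>LI_attP_synthetic reconstructed 50-bp attP (arms P-prime|P; crossover at 25/26)
TTTAGTGTCACCAAAATGCTTATACGTACAAGCTTTTTGGTGATACTAAA
>LI_attB_synthetic reconstructed 50-bp attB (arms B-prime|B; crossover at 25/26)
TACAGTTTAGTGTCAAAGCTTATACGTACAAGCTTTGATACTAAACAGTC
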