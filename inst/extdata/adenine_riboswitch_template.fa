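>adenine_riboswitch_template pbuE adenine riboswitch PLOR template (T7 promoter on reverse complement)
CCGCGGATGCGGAAAAAAAATCCTGATTACAAAAAATGTCATAAACAAATTTTGTAATCA
GGATTTTACGGTTCCTGGTAGACACCCTCAAACCATATTATTGAGGTTATACAACTTCCC
TATAGTGAGTCGTATTATGGACTAGCTGAATCAGA
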