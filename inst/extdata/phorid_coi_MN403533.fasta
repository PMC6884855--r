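>MN403533 Megaselia sepsioides voucher UGC0005996 cytochrome c oxidase subunit I (COI), partial cds; mitochondrial
ACTTTATATTTTATTTTTGGAGCTTGAGCTGGAATAGTAGGTACTTCCTTAAGAATCATAATTCGTGCTG
AATTAGGACACCCAGGAGCACTTATTGGTGATGACCAAATTTATAATGTGATTGTTACTGCACATGCTTT
TATTATAATTTTTTTTATAGTAATACCTATTATAATAGGAGGTTTTGGTAATTGACTTGTACCTTTAATA
TTAGGAGCCCCAGATATGGCATTCCCTCGAATGAATAATATAAGTTTTTGAATATTACCTCCTTCTTTAA
CTCTTTTATTAGCCAGAAGTATAGTAGAAAATGGAGCTGGAACTGGTTGAACAGTTTATCCTCCTTTATC
TTCTAGAATCGCTCATAGTGGAGCTTCTGTTGATTTAGCAATTTTCTCTCTTCATTTAGCTGGAATTTCA
TCTATTTTAGGAGCTGTAAATTTTATTACAACAATTATTAATATACGATCATCAGGTATTACATTTGACC
GAATACCTCTATTTGTTTGATCTGTAGGTATTACAGCTTTATTGCTACTCTTATCACTTCCTGTTTTAGC
TGGTGCTATTACAATACTATTAACAGACCGAAATTTTAATACTTCATTTTTTGACCCAGCAGGAGGAGGA
GATCCAATTTTATACCAACATTTATTC
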