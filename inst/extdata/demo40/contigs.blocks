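contig_1: -23 -22 +19 +20
contig_2: -15 -14 +12 +13 -11
contig_3: +34 +35
contig_4: +36 +37 +38 +39 +40
contig_5: -3 -2 -1
contig_6: +5 +6 +7 +8
contig_7: +31 +32 +33 -30 -29
contig_8: -28 -27 +26 -25 -24 +4
contig_9: +21 -18 -17 -16 +9 +10
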