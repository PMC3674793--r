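+1 +2 +3 -23 -22 +19 +20 +21 -18 -17 -16 +9 +10 +11 -13 -12 +14 +15 -8 -7 -6 -5 -4 +24 +25 -26 +27 +28 -35 -34 +31 +32 +33 -30 -29 +36 +37 +38 +39 +40
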