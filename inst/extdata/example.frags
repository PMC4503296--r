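# n=8
2 r1 1 TGG 8 A
1 r2 1 ACTGTCT
1 r3 8 G
1 r4 4 ACAA
1 r5 1 ACTGTC
1 r6 7 TG
1 r7 1 TGGAC
1 r8 6 AAA
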