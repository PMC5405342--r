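p0_neg,p0_pos,p1_neg,p1_pos,significance,power_unselected,power_positive,pet,expected_n,design
0.03,0.03,0.10,0.10,0.048,0.800,0.800,0.623,110.2,(3 2)/(44 34) -> (7/104) | (9 4)/(135 53)
0.03,0.03,0.10,0.15,0.049,0.801,0.801,0.653,77.9,(2 2)/(32 21) -> (6/67) | (7 3)/(106 29)
0.03,0.03,0.10,0.25,0.050,0.800,0.800,0.571,60.0,(2 1)/(34 8) -> (4/29) | (6 2)/(87 9)
0.03,0.03,0.15,0.15,0.050,0.802,0.801,0.611,46.9,(2 1)/(20 12) -> (4/43) | (6 2)/(66 21)
0.03,0.03,0.15,0.25,0.046,0.803,0.802,0.561,32.5,(1 1)/(12 7) -> (4/28) | (4 2)/(43 11)
0.03,0.03,0.15,0.35,0.045,0.801,0.800,0.615,27.8,(1 1)/(11 5) -> (3/15) | (4 2)/(47 7)
0.03,0.03,0.25,0.25,0.045,0.802,0.801,0.695,18.5,(1 1)/(6 6) -> (3/24) | (3 2)/(23 13)
0.03,0.03,0.25,0.40,0.038,0.802,0.801,0.742,13.5,(1 1)/(6 4) -> (2/9) | (3 2)/(23 5)
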