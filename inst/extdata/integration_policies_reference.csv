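code,X1,X2,X3,X4,X5,X6,X7,X8,X9,pmc
P1,0.67,0.33,0.33,0.67,1,0.6,1,1,1,6.6
P2,1,0.33,0.33,0.67,1,1,1,1,1,7.33
P3,0.83,0.33,0.33,0.67,1,1,1,0.8,0.6,6.57
P4,0.67,0.33,0.33,1,1,1,1,1,1,7.33
P5,0.83,0.33,0.33,0.67,0.8,0.8,1,1,0.6,6.37
P6,0.67,0.33,0.33,1,0.8,0.8,0.75,1,0.6,6.28
P7,0.67,0.33,0.33,1,1,1,1,1,1,7.33
P8,0.5,0.33,0.33,1,1,0.6,0.75,0.6,1,6.12
P9,1,0.33,0.33,1,1,1,1,1,0.8,7.47
P10,0.67,0.33,0.33,1,0.8,1,1,0.8,1,6.93
P11,0.5,0.33,0.33,0.33,0.6,0.8,0.75,0.8,0.6,5.05
P12,0.5,0.33,0.33,0.67,0.8,1,0.75,0.6,0.8,5.78
P13,0.33,0.33,0.33,0.67,0.4,0.6,1,0.8,0.4,4.87
P14,0.5,0.33,0.33,0.33,0.6,0.6,1,0.6,0.4,4.7
P15,0.5,0.33,0.33,0.33,0.4,0.6,1,0.8,0.4,4.7
P16,0.5,0.33,0.33,0.67,1,1,1,0.8,0.6,6.23
P17,0.5,0.33,1,1,0.8,1,1,0.8,0.4,6.83
P18,0.67,0.33,0.33,0.67,1,0.6,1,0.8,0.6,6
P19,0.67,0.33,0.33,0.67,1,1,1,1,0.8,6.8
P20,0.83,0.33,0.67,1,0.8,1,1,1,0.8,7.43
P21,0.67,0.33,0.33,1,1,1,1,0.8,0.8,6.93
P22,1,0.33,0.33,1,1,1,1,1,1,7.67
P23,0.67,0.33,0.33,0.67,0.6,0.8,1,0.8,0.8,6
P24,0.5,0.33,1,0.67,1,1,1,0.8,0.8,7.1
P25,1,0.33,0.33,1,1,1,1,1,0.8,7.47
P26,0.33,0.33,0.33,0.33,0.6,0.67,1,0.4,0.4,4.4
P27,0.83,0.33,0.67,1,1,0.8,1,1,0.8,7.43
P28,0.83,0.33,0.33,1,1,1,1,0.8,1,7.3
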