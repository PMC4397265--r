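variable,Figural,Numerical,Verbal,Cond1,Cond2,Cond3,Cond4,Cond5
Figural,1.00,0.58,0.40,0.36,0.28,0.41,0.43,0.34
Numerical,0.58,1.00,0.42,0.27,0.28,0.40,0.40,0.32
Verbal,0.40,0.42,1.00,0.17,0.15,0.27,0.21,0.15
Cond1,0.36,0.27,0.17,1.00,0.38,0.52,0.39,0.42
Cond2,0.28,0.28,0.15,0.38,1.00,0.56,0.45,0.42
Cond3,0.41,0.40,0.27,0.52,0.56,1.00,0.55,0.49
Cond4,0.43,0.40,0.21,0.39,0.45,0.55,1.00,0.53
Cond5,0.34,0.32,0.15,0.42,0.42,0.49,0.53,1.00
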