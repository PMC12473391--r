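subject,n_pos,n_neg,fp,fn,precision,recall,accuracy,f1
S01,397,2891,1,0,99.75,100,99.97,99.87
S02,454,5627,3,0,99.34,100,99.95,99.67
S03,283,5252,5,0,99.26,100,99.91,99.12
S04,728,6747,34,1,95.53,99.86,99.53,97.65
S05,396,3542,4,1,99.00,99.75,99.87,99.37
S06,193,2756,1,2,99.48,98.96,99.90,99.22
S07,208,3901,1,0,99.52,100,99.98,99.76
S08,637,3158,1,0,99.84,100,99.97,99.92
S09,199,3739,0,2,100,98.99,99.95,99.49
S10,373,4554,2,2,99.46,99.46,99.92,99.46
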