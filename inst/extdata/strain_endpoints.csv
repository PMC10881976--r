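strain,titre,glucose,od600
QLW1,0.136,20,NA
QLW2,0.39,20,NA
QLW3,0.65,20,NA
QLW5,0.74,20,6.97
QLW6,0.70,20,NA
QLW8,0.83,20,7.65
QLW10,0.31,20,NA
QLW12,0.44,20,NA
QLW13,0.45,20,NA
QLW15,1.18,20,NA
QLW19,1.34,20,NA
QLW23,4.12,20,NA
QLW71,11.25,20,NA
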