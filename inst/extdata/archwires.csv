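codename,alias,material,shape,dim1_in,dim2_in
I,S1616,stainless steel archwire,rectangular,0.016,0.016
II,S1622,stainless steel archwire,rectangular,0.022,0.016
III,S1625,stainless steel archwire,rectangular,0.025,0.016
IV,S0014,stainless steel archwire,round,0.014,NA
V,S0016,stainless steel archwire,round,0.016,NA
VI,S0018,stainless steel archwire,round,0.018,NA
VII,S0020,stainless steel archwire,round,0.020,NA
VIII,A0014,australian archwire,round,0.014,NA
IX,A0016,australian archwire,round,0.016,NA
X,A0018,australian archwire,round,0.018,NA
XI,A0020,australian archwire,round,0.020,NA
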