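name,E_GPa,nu,sigma_e_GPa,sigma_b_GPa,density_mg_cm3
cortical bone,13.00,0.30,NA,NA,2400
cancellous bone,0.345,0.30,NA,NA,1100
periodontal ligament,0.00689,0.45,NA,NA,NA
tooth,20.20,0.30,NA,NA,NA
bracket,19.30,0.30,2.05,1.04,NA
stainless steel archwire,85.20,0.30,2.06,2.12,NA
australian archwire,74.90,0.30,2.08,2.30,NA
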