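name,label,center,half_width,unit
fn_mM,Finasteride concentration,3.25,1.75,mM
lipid_mM,Total lipid content,20,10,mM
chol_pct,Cholesterol in total lipid,40,10,% mol/mol
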