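analyte,rfd,csf,source
Ag,0.005,NA,US EPA IRIS oral RfD (silver)
Al,1,NA,US EPA PPRTV oral RfD (aluminum)
As,0.0003,1.5,US EPA IRIS oral RfD and oral slope factor (inorganic arsenic)
Ba,0.2,NA,US EPA IRIS oral RfD (barium)
Be,0.002,NA,US EPA IRIS oral RfD (beryllium)
Cd,0.0005,NA,US EPA IRIS oral RfD (cadmium; water)
Co,0.0003,NA,US EPA PPRTV oral RfD (cobalt)
Cr,0.003,0.5,US EPA IRIS oral RfD (Cr(VI)); oral slope factor convention for Cr(VI)
Cu,0.04,NA,US EPA HEAST oral RfD (copper)
Mn,0.14,NA,US EPA IRIS oral RfD (manganese; diet)
Mo,0.005,NA,US EPA IRIS oral RfD (molybdenum)
Ni,0.02,NA,US EPA IRIS oral RfD (nickel; soluble salts)
Pb,1.5,0.0085,study convention: no EPA oral RfD established for lead; slope factor per oral ingestion convention
Sb,0.0004,NA,US EPA IRIS oral RfD (antimony)
Se,0.005,NA,US EPA IRIS oral RfD (selenium)
Sn,0.6,NA,US EPA HEAST oral RfD (tin)
Sr,0.6,NA,US EPA IRIS oral RfD (strontium)
Tl,0.00001,NA,US EPA PPRTV screening oral RfD (thallium)
V,0.005,NA,US EPA PPRTV oral RfD (vanadium)
Zn,0.3,NA,US EPA IRIS oral RfD (zinc)
ethanol,62,NA,oral RfD used for ethanol in the sachet-spirit risk framework
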