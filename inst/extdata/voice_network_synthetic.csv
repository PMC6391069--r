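"name","x","y","z","cortical","radius"
"pSTS_L",-58,-40,6,TRUE,5
"pSTS_R",60,-38,8,TRUE,5
"aSTS_L",-56,-8,-8,TRUE,5
"aSTS_R",58,-6,-10,TRUE,5
"PP_R",48,-6,-6,TRUE,5
"HG_L",-42,-22,8,TRUE,5
"AI_L",-34,20,2,TRUE,5
"AI_R",36,22,0,TRUE,5
"rACC_R",8,38,18,TRUE,5
"vmPFC",2,46,-12,TRUE,5
"OFC_R",28,34,-14,TRUE,5
"NAc_L",-10,12,-8,FALSE,2
"NAc_R",10,12,-8,FALSE,2
"Amygdala_L",-24,-4,-18,FALSE,2
"Hippocampus_R",28,-24,-12,FALSE,2
"Fusiform_R",42,-50,-18,TRUE,5
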