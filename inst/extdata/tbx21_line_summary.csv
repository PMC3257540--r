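construct,line_id,mitral_tufted,olfactory_pathway
Tbx5.0gV,line_1,TRUE,TRUE
Tbx5.0gV,line_2,TRUE,TRUE
Tbx5.0gV,line_3,TRUE,TRUE
Tbx5.0gV,line_4,TRUE,TRUE
Tbx5.0gV,line_5,TRUE,TRUE
Tbx5.0gV,line_6,TRUE,TRUE
Tbx5.0gV,line_7,TRUE,TRUE
Tbx5.0gV,line_8,TRUE,TRUE
Tbx5.0gV,line_9,TRUE,TRUE
Tbx5.0gV,line_10,TRUE,TRUE
Tbx5.0gV,line_11,TRUE,TRUE
Tbx5.0gV,line_12,TRUE,TRUE
Tbx5.0gV,line_13,TRUE,TRUE
Tbx5.0gV,line_14,TRUE,TRUE
Tbx5.0gV,line_15,TRUE,TRUE
Tbx5.0gV,line_16,FALSE,FALSE
Tbx5.0gV,line_17,FALSE,FALSE
Tbx2.6gV,line_123,TRUE,TRUE
Tbx2.6gV,line_127,TRUE,TRUE
Tbx2.6gV,line_001,FALSE,TRUE
Tbx2.6gV,line_004,FALSE,TRUE
Tbx2.6gV,line_006,FALSE,TRUE
Tbx2.6gV,line_008,FALSE,TRUE
Tbx2.6gV,line_103,FALSE,TRUE
Tbx2.6gV,line_105,FALSE,TRUE
Tbx2.6gV,line_114,FALSE,TRUE
Tbx2.6gV,line_120,FALSE,TRUE
Tbx2.6gV,line_124,FALSE,TRUE
Tbx2.6gV,line_129,FALSE,TRUE
Tbx2.6gV,founder_1,FALSE,TRUE
Tbx2.6gV,founder_3,FALSE,TRUE
Tbx2.6gV,line_p01,FALSE,TRUE
Tbx2.6gV,line_p02,FALSE,TRUE
Tbx2.6gV,line_p03,FALSE,TRUE
Tbx2.6gV,line_p04,FALSE,TRUE
Tbx2.6gV,line_p05,FALSE,TRUE
Tbx2.6gV,line_p06,FALSE,TRUE
Tbx2.6gV,line_p07,FALSE,TRUE
Tbx2.6gV,line_p08,FALSE,TRUE
Tbx2.6gV,line_p09,FALSE,TRUE
Tbx2.6gV,line_p10,FALSE,TRUE
Tbx2.6gV,line_p11,FALSE,TRUE
Tbx2.6gV,line_p12,FALSE,TRUE
Tbx2.6gV,line_p13,FALSE,TRUE
Tbx2.6gV,founder_4,FALSE,FALSE
Tbx2.6gV,line_117,FALSE,FALSE
Tbx2.6gV,line_n01,FALSE,FALSE
Tbx2.6gV,line_n02,FALSE,FALSE
Tbx2.6gV,line_n03,FALSE,FALSE
Tbx2.6gV,line_n04,FALSE,FALSE
Tbx2.6gV,line_n05,FALSE,FALSE
Tbx2.6gV,line_n06,FALSE,FALSE
Tbx2.6gV,line_n07,FALSE,FALSE
Tbx2.6gV,line_n08,FALSE,FALSE
Tbx2.6gV,line_n09,FALSE,FALSE
Tbx2.6gV,line_n10,FALSE,FALSE
Tbx2.6gV,line_n11,FALSE,FALSE
Tbx2.6gV,line_n12,FALSE,FALSE
Tbx2.6gV,line_n13,FALSE,FALSE
Tbx2.6gV,line_n14,FALSE,FALSE
Tbx1.0gV,line_1,FALSE,FALSE
Tbx1.0gV,line_2,FALSE,FALSE
Tbx1.0gV,line_3,FALSE,FALSE
MCE-gV,founder_1,FALSE,FALSE
MCE-gV,founder_2,FALSE,FALSE
MCE-gV,founder_3,TRUE,TRUE
MCE-gV,line_1,TRUE,TRUE
MCE-gV,line_2,FALSE,FALSE
MCE-gV,line_3,FALSE,FALSE
MCE-gV,line_4,FALSE,FALSE
MCE-gV,line_5,TRUE,TRUE
MCE-gV,line_6,FALSE,FALSE
MCE-gV,line_8,TRUE,TRUE
Tbx-spH,line_1,TRUE,TRUE
Tbx-spH,line_2,FALSE,FALSE
Tbx-spH,line_3,FALSE,FALSE
Tbx-spH,line_4,FALSE,FALSE
Tbx-spH,line_5,FALSE,FALSE
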