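name,value,provenance
anchor_yc_pib_suvr,1.012,Level-1 young-control anchor mean PiB SUVR (whole-cerebellum reference)
anchor_ad_pib_suvr,2.077,Level-1 AD-100 anchor mean PiB SUVR (whole-cerebellum reference)
fbb_pib_offset,0.39,published FBB-to-PiB surrogate conversion offset
fbb_pib_scale,0.61,published FBB-to-PiB surrogate conversion scale
fs_wc_slope,157.15,published FS-pipeline SUVR-to-CL slope (whole cerebellum)
fs_wc_intercept,-151.87,published FS-pipeline SUVR-to-CL intercept (whole cerebellum)
fs_comp_slope,244.20,published FS-pipeline SUVR-to-CL slope (composite reference)
fs_comp_intercept,-170.80,published FS-pipeline SUVR-to-CL intercept (composite reference)
ct_wc_slope,153.05,CT-parcellation SUVR-to-CL slope (whole cerebellum)
ct_wc_intercept,-143.63,CT-parcellation SUVR-to-CL intercept (whole cerebellum)
ct_comp_slope,234.01,CT-parcellation SUVR-to-CL slope (composite reference)
ct_comp_intercept,-168.12,CT-parcellation SUVR-to-CL intercept (composite reference)
std_wc_slope_rounded,154.0,standard-pipeline FBB-SUVR-to-CL slope as printed (whole cerebellum)
std_wc_intercept_rounded,-155.1,standard-pipeline FBB-SUVR-to-CL intercept as printed (whole cerebellum)
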