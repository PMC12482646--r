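{
  ".comment": "Default role-to-label table in the FreeSurfer aparc(DKT)+aseg numbering. Edit or replace to match your parcellation tool; pons requires a brainstem-substructure labelling (174 in FreeSurfer's brainstem module).",
  "frontal": [1003, 1012, 1014, 1017, 1018, 1019, 1020, 1024, 1027, 1028, 1032,
              2003, 2012, 2014, 2017, 2018, 2019, 2020, 2024, 2027, 2028, 2032],
  "cingulate": [1002, 1010, 1023, 1026, 2002, 2010, 2023, 2026],
  "lateral_parietal": [1008, 1029, 1031, 2008, 2029, 2031],
  "lateral_temporal": [1009, 1015, 1030, 2009, 2015, 2030],
  "whole_cerebellum": [7, 8, 46, 47],
  "cerebellar_gray": [8, 47],
  "pons": [174],
  "brainstem": [16, 174],
  "subcortical_white_matter": [2, 41]
}
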