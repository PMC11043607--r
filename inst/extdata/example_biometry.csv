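eye_id,source,flat_power_D,steep_power_D,steep_axis_deg,index_basis,axial_length_mm,elp_mm
eye_0001,K,41.337,44.843,16.002,1.332,23.67,4.856
eye_0001,TCRP,42.135,45.163,21.087,1.3375,23.67,4.856
eye_0001,TK,41.29,44.756,18.402,1.332,23.67,4.856
eye_0002,K,42.782,44.979,174.827,1.332,24.553,4.324
eye_0002,TCRP,43.393,45.822,176.891,1.3375,24.553,4.324
eye_0002,TK,42.78,44.853,174.565,1.332,24.553,4.324
eye_0003,K,40.194,42.78,87.549,1.332,21.539,4.77
eye_0003,TCRP,40.967,42.722,83.517,1.3375,21.539,4.77
eye_0003,TK,40.188,42.398,86.889,1.332,21.539,4.77
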