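"animal_id","dam_id","group","sex","body_weight_g","protocol","dose_total_mg","dose_tracer_fraction"
"LF_M_01","LF01","LF","M",30.0273,"OGTT",30.0273,0.05
"LF_F_01","LF01","LF","F",19.3421,"OGTT",19.3421,0.05
"LF_M_02","LF02","LF","M",29.0962,"OGTT",29.0962,0.05
"LF_F_02","LF02","LF","F",24.0251,"OGTT",24.0251,0.05
"HF_M_01","HF01","HF","M",23.0364,"OGTT",23.0364,0.05
"HF_F_01","HF01","HF","F",19.4572,"OGTT",19.4572,0.05
"HF_M_02","HF02","HF","M",26.807,"OGTT",26.807,0.05
"HF_F_02","HF02","HF","F",22.0745,"OGTT",22.0745,0.05
"GDM_M_01","GDM01","GDM","M",22.8547,"OGTT",22.8547,0.05
"GDM_F_01","GDM01","GDM","F",20.4728,"OGTT",20.4728,0.05
"GDM_M_02","GDM02","GDM","M",27.6815,"OGTT",27.6815,0.05
"GDM_F_02","GDM02","GDM","F",22.7433,"OGTT",22.7433,0.05
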