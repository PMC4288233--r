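"item","mode","table","value_column","value_type","discriminator_column","discriminator_value"
"ICD9","direct","Diagnosis","ICD9_Code","text","",""
"Ascites","indirect","Laboratory","Result_String","text","Item_Name","Ascites"
"ICG","indirect","Laboratory","Result_Number","number","Item_Name","ICG"
"Prothrombin_Activity","indirect","Laboratory","Result_Number","number","Item_Name","Prothrombin activity"
"Serum_Albumin","indirect","Laboratory","Result_Number","number","Item_Name","Serum albumin"
"Serum_Bilirubin","indirect","Laboratory","Result_Number","number","Item_Name","Serum bilirubin"
"Treatment","direct","Treatment","Treatment_Name","text","",""
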