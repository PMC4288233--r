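[
  {
    "item": "ICD9",
    "mode": "direct",
    "table": "Diagnosis",
    "value_column": "ICD9_Code",
    "value_type": "text"
  },
  {
    "item": "Ascites",
    "mode": "indirect",
    "table": "Laboratory",
    "value_column": "Result_String",
    "value_type": "text",
    "discriminator_column": "Item_Name",
    "discriminator_value": "Ascites"
  },
  {
    "item": "ICG",
    "mode": "indirect",
    "table": "Laboratory",
    "value_column": "Result_Number",
    "value_type": "number",
    "discriminator_column": "Item_Name",
    "discriminator_value": "ICG"
  },
  {
    "item": "Prothrombin_Activity",
    "mode": "indirect",
    "table": "Laboratory",
    "value_column": "Result_Number",
    "value_type": "number",
    "discriminator_column": "Item_Name",
    "discriminator_value": "Prothrombin activity"
  },
  {
    "item": "Serum_Albumin",
    "mode": "indirect",
    "table": "Laboratory",
    "value_column": "Result_Number",
    "value_type": "number",
    "discriminator_column": "Item_Name",
    "discriminator_value": "Serum albumin"
  },
  {
    "item": "Serum_Bilirubin",
    "mode": "indirect",
    "table": "Laboratory",
    "value_column": "Result_Number",
    "value_type": "number",
    "discriminator_column": "Item_Name",
    "discriminator_value": "Serum bilirubin"
  },
  {
    "item": "Treatment",
    "mode": "direct",
    "table": "Treatment",
    "value_column": "Treatment_Name",
    "value_type": "text"
  }
]
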