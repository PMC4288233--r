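<?xml version="1.0" encoding="UTF-8"?>
<queryTask version="1.0" name="degree of liver damage">
  <node id="icd" name="Liver cancer diagnosis" class="patient_state" selected="true" mutuallyExclusive="false">
    <criterion>ICD9=155.0</criterion>
  </node>
  <node id="degree_decision" name="degree decision" class="decision" selected="true" mutuallyExclusive="false"/>
  <node id="degree_a" name="Degree A" class="action" selected="true" mutuallyExclusive="false">
    <criterion>at least 2 of (Ascites=="None", ICG is within 0 to 15, Prothrombin_Activity is within 80 to 100, Serum_Albumin is within 3.5 to 6, Serum_Bilirubin is within 0.1 to 2)</criterion>
  </node>
  <node id="degree_b" name="Degree B" class="action" selected="true" mutuallyExclusive="false">
    <criterion>at least 2 of (Ascites=="Controllable", ICG is within 15 to 40, Prothrombin_Activity is within 50 to 80, Serum_Albumin is within 3.0 to 3.5, Serum_Bilirubin is within 2.0 to 3.0)</criterion>
  </node>
  <node id="degree_c" name="Degree C" class="action" selected="true" mutuallyExclusive="false">
    <criterion>at least 2 of (Ascites=="Uncontrollable", ICG is within 40 to 100, Prothrombin_Activity is within 0 to 50, Serum_Albumin is within 1 to 3, Serum_Bilirubin is within 3 to 30)</criterion>
  </node>
  <edge from="icd" to="degree_decision"/>
  <edge from="degree_decision" to="degree_a"/>
  <edge from="degree_decision" to="degree_b"/>
  <edge from="degree_decision" to="degree_c"/>
</queryTask>
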