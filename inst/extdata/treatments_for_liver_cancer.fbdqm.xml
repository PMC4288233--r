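<?xml version="1.0" encoding="UTF-8"?>
<queryTask version="1.0" name="treatments for liver cancer">
  <node id="icd" name="Liver cancer diagnosis" class="patient_state" selected="true" mutuallyExclusive="false">
    <criterion>ICD9=155.0</criterion>
  </node>
  <node id="treatment_branch" name="treatment branch" class="branch" selected="true" mutuallyExclusive="false"/>
  <node id="lt" name="Liver transplantation" class="action" selected="true" mutuallyExclusive="false">
    <criterion>Treatment=="Liver transplantation"</criterion>
  </node>
  <node id="tace" name="Transarterial embolization and chemoembolization" class="action" selected="true" mutuallyExclusive="false">
    <criterion>Treatment=="Transarterial embolization and chemoembolization"</criterion>
  </node>
  <node id="rfa" name="Radiofrequency ablation" class="action" selected="true" mutuallyExclusive="false">
    <criterion>Treatment=="Radiofrequency ablation"</criterion>
  </node>
  <node id="ai" name="Alcohol injection" class="action" selected="true" mutuallyExclusive="false">
    <criterion>Treatment=="Alcohol injection"</criterion>
  </node>
  <node id="sr" name="Surgical resection" class="action" selected="true" mutuallyExclusive="false">
    <criterion>Treatment=="Surgical resection"</criterion>
  </node>
  <edge from="icd" to="treatment_branch"/>
  <edge from="treatment_branch" to="lt"/>
  <edge from="treatment_branch" to="tace"/>
  <edge from="treatment_branch" to="rfa"/>
  <edge from="treatment_branch" to="ai"/>
  <edge from="treatment_branch" to="sr"/>
</queryTask>
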