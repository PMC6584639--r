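"name","anchor_value","elution_volume_ml"
"apoferritin",17.6,3.802
"catalase",11.3,2.689
"glucose_oxidase",8,2.106
"BSA",4.6,1.505
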