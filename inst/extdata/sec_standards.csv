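"name","anchor_value","elution_volume_ml"
"thyroglobulin",8.5,2.899
"apoferritin",6.1,13.191
"catalase",5.2,18.143
"BSA",3.48,30.601
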