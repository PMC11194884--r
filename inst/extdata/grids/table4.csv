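"grid","row","attention_layers","fusion_layers"
"table4",1,"","conv2_2;conv3_3;conv4_3;fc7;conv6_2"
"table4",2,"","conv2_2;conv3_3;conv4_3;fc7"
"table4",3,"","conv2_2;conv3_3;conv4_3"
"table4",4,"","conv3_3;conv4_3;fc7;conv6_2"
"table4",5,"","conv4_3;fc7;conv6_2"
"table4",6,"","fc7;conv6_2"
"table4",7,"","conv2_2;conv3_3;fc7"
"table4",8,"","conv2_2;conv3_3"
"table4",9,"","conv4_3;fc7"
"table4",10,"","conv3_3;conv4_3"
"table4",11,"","conv2_2;conv3_3;conv6_2"
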