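"grid","row","attention_layers","fusion_layers"
"table3",1,"conv2_2;conv3_3;conv4_3;conv5_3",""
"table3",2,"conv2_2;conv3_3;conv4_3",""
"table3",3,"conv2_2;conv3_3;conv5_3",""
"table3",4,"conv2_2;conv4_3;conv5_3",""
"table3",5,"conv3_3;conv4_3;conv5_3",""
"table3",6,"conv2_2;conv3_3",""
"table3",7,"conv2_2;conv4_3",""
"table3",8,"conv2_2;conv5_3",""
"table3",9,"conv3_3;conv4_3",""
"table3",10,"conv3_3;conv5_3",""
"table3",11,"conv4_3;conv5_3",""
"table3",12,"conv2_2",""
"table3",13,"conv3_3",""
"table3",14,"conv4_3",""
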