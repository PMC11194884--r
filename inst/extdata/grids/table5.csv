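"grid","row","attention_layers","fusion_layers"
"table5",1,"conv2_2;conv3_3;conv4_3;conv5_3","conv2_2;conv3_3;conv4_3;fc7;conv6_2"
"table5",2,"conv2_2;conv3_3;conv4_3","conv2_2;conv3_3;conv4_3;fc7;conv6_2"
"table5",3,"conv2_2;conv3_3;conv5_3","conv2_2;conv3_3;conv4_3;fc7;conv6_2"
"table5",4,"conv2_2;conv4_3;conv5_3","conv2_2;conv3_3;conv4_3;fc7;conv6_2"
"table5",5,"conv3_3;conv4_3;conv5_3","conv2_2;conv3_3;conv4_3;fc7;conv6_2"
"table5",6,"conv2_2;conv3_3","conv2_2;conv3_3;conv4_3;fc7;conv6_2"
"table5",7,"conv2_2;conv4_3","conv2_2;conv3_3;conv4_3;fc7;conv6_2"
"table5",8,"conv2_2;conv5_3","conv2_2;conv3_3;conv4_3;fc7;conv6_2"
"table5",9,"conv3_3;conv4_3","conv2_2;conv3_3;conv4_3;fc7;conv6_2"
"table5",10,"conv3_3;conv5_3","conv2_2;conv3_3;conv4_3;fc7;conv6_2"
"table5",11,"conv4_3;conv5_3","conv2_2;conv3_3;conv4_3;fc7;conv6_2"
"table5",12,"conv2_2","conv2_2;conv3_3;conv4_3;fc7;conv6_2"
"table5",13,"conv3_3","conv2_2;conv3_3;conv4_3;fc7;conv6_2"
"table5",14,"conv4_3","conv2_2;conv3_3;conv4_3;fc7;conv6_2"
"table5",15,"conv5_3","conv2_2;conv3_3;conv4_3;fc7;conv6_2"
"table5",16,"","conv2_2;conv3_3;conv4_3;fc7;conv6_2"
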