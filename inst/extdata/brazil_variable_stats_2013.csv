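variable,vector,unit,mean,sd
hypertension_thousands,needs,thousands of people,1.2,1.6
diabetics_thousands,needs,thousands of people,337.84,506.9
asthmatics_thousands,needs,thousands of people,238.44,333.2
elderly_thousands,needs,thousands of people,978.0,71.4
negative_income_index,needs,index (tax income),0.5351,0.7119
bppp_value_millions,services,millions of reais,67.6,100.2
bcpa_value_millions,services,millions of reais,38,44.33
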