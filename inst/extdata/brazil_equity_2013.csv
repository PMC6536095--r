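dmu_id,name,region,row_type,ei_mean,se,ci_low,ci_high
TO,Tocantins,North,state,0.6788,0.0281,0.6237,0.7338
AC,Acre,North,state,0.7411,0.0407,0.6613,0.8210
AM,Amazonas,North,state,0.7512,0.0418,0.6692,0.8332
PA,Para,North,state,0.7530,0.0326,0.6892,0.8169
AP,Amapa,North,state,0.7587,0.0396,0.6811,0.8364
RO,Rondonia,North,state,0.8348,0.0227,0.7903,0.8792
RR,Roraima,North,state,0.9680,0.0183,0.9322,1.0038
PI,Piaui,Northeast,state,0.6197,0.0230,0.5747,0.6647
PE,Pernambuco,Northeast,state,0.6570,0.0255,0.6069,0.7071
SE,Sergipe,Northeast,state,0.6808,0.0302,0.6216,0.7399
AL,Alagoas,Northeast,state,0.6969,0.0299,0.6383,0.7555
MA,Maranhao,Northeast,state,0.6970,0.0376,0.6233,0.7706
CE,Ceara,Northeast,state,0.7020,0.0295,0.6443,0.7598
BA,Bahia,Northeast,state,0.8142,0.0322,0.7511,0.8774
RN,Rio Grande do Norte,Northeast,state,0.8295,0.0184,0.7935,0.8654
PB,Paraiba,Northeast,state,0.8629,0.0206,0.8225,0.9032
ES,Espirito Santo,Southeast,state,0.8319,0.0225,0.7879,0.8760
RJ,Rio de Janeiro,Southeast,state,0.9024,0.0114,0.8800,0.9248
MG,Minas Gerais,Southeast,state,0.9778,0.0072,0.9637,0.9918
SP,Sao Paulo,Southeast,state,1,0,1.00,1.00
SC,Santa Catarina,South,state,0.8733,0.0186,0.8368,0.9097
PR,Parana,South,state,0.9162,0.0149,0.8870,0.9454
RS,Rio Grande do Sul,South,state,0.9267,0.0151,0.8971,0.9563
MT,Mato Grosso,Midwest,state,0.7128,0.0263,0.6613,0.7643
MS,Mato Grosso do Sul,Midwest,state,0.7412,0.0237,0.6947,0.7876
DF,Distrito Federal,Midwest,state,0.8120,0.0241,0.7649,0.8592
GO,Goias,Midwest,state,0.8896,0.0175,0.8553,0.9239
N,North,North,region,0.7837,0.0352,0.7147,0.8527
NE,Northeast,Northeast,region,0.7289,0.0283,0.6735,0.7843
SO,Southeast,Southeast,region,0.928,0.0382,0.8531,1.003
S,South,South,region,0.9054,0.0426,0.7808,0.9479
MW,Midwest,Midwest,region,0.7889,0.0512,0.7046,0.9051
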