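dmu_id,name,region,row_type,effective_bppp,effective_bcpa,effective_total,projected_bppp,projected_bcpa,projected_total
TO,Tocantins,North,state,5.10,8.19,13.29,18.51,25.05,43.56
AC,Acre,North,state,0.29,4.04,4.33,9.87,78.20,88.07
AM,Amazonas,North,state,0.98,18.47,19.45,17.00,222.30,239.30
PA,Para,North,state,25.63,41.20,66.83,50.13,76.05,126.18
AP,Amapa,North,state,0.11,3.49,3.60,9.75,172.77,182.52
RO,Rondonia,North,state,11.05,8.30,19.35,24.62,17.64,42.26
RR,Roraima,North,state,1.60,2.42,4.02,11.63,13.45,25.08
PI,Piaui,Northeast,state,13.73,16.69,30.42,34.12,38.56,72.68
PE,Pernambuco,Northeast,state,49.24,47.32,96.56,94.52,88.73,183.25
SE,Sergipe,Northeast,state,6.68,11.02,17.70,21.60,30.88,52.48
AL,Alagoas,Northeast,state,10.82,17.64,28.46,28.24,41.37,69.61
MA,Maranhao,Northeast,state,12.64,34.21,46.85,37.77,89.54,127.31
CE,Ceara,Northeast,state,36.64,47.58,84.22,71.63,89.29,160.92
BA,Bahia,Northeast,state,51.30,77.59,128.89,89.21,129.96,219.17
RN,Rio Grande do Norte,Northeast,state,35.00,18.91,53.91,53.26,28.84,82.10
PB,Paraiba,Northeast,state,31.31,21.68,52.99,47.16,32.02,79.18
ES,Espirito Santo,Southeast,state,52.50,18.66,71.16,77.58,28.45,106.03
RJ,Rio de Janeiro,Southeast,state,219.59,84.35,303.94,248.63,96.15,344.78
MG,Minas Gerais,Southeast,state,291.85,104.77,396.62,300.93,108.83,409.76
SP,Sao Paulo,Southeast,state,397.22,216.66,613.88,397.22,216.66,613.88
SC,Santa Catarina,South,state,75.05,32.93,107.98,96.82,42.94,139.76
PR,Parana,South,state,130.81,56.62,187.43,150.55,65.65,216.20
RS,Rio Grande do Sul,South,state,221.10,57.26,278.36,249.29,66.33,315.62
MT,Mato Grosso,Midwest,state,15.80,17.09,32.89,34.37,34.78,69.15
MS,Mato Grosso do Sul,Midwest,state,16.43,13.25,29.68,33.82,26.16,59.98
DF,Distrito Federal,Midwest,state,24.03,13.49,37.52,42.35,23.71,66.06
GO,Goias,Midwest,state,87.84,32.17,120.01,109.72,40.95,150.67
N,North,North,region,44.76,86.11,130.87,141.51,605.46,746.97
NE,Northeast,Northeast,region,247.36,292.64,540.00,477.51,569.19,1046.70
SO,Southeast,Southeast,region,961.16,424.44,1385.60,1024.36,450.09,1474.45
S,South,South,region,426.96,146.81,573.77,496.66,174.92,671.58
MW,Midwest,Midwest,region,144.10,76.00,220.10,220.26,125.60,345.86
BR,Total,Total,total,1824.34,1026.00,2850.00,2360.30,1925.26,4285.56
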