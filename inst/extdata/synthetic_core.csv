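depth_mbsf,species,concentration_mM
0.050000000000000003,CH4, 0.136637971065656810
0.150000000000000022,CH4, 0.211463048400991366
0.250000000000000000,CH4, 0.310563643655425103
0.350000000000000033,CH4, 0.000000000000000000
0.450000000000000011,CH4, 0.151696110205239265
0.550000000000000044,CH4, 0.000000000000000000
0.650000000000000133,CH4, 0.000000000000000000
0.750000000000000111,CH4, 0.000000000000000000
0.850000000000000089,CH4, 0.000000000000000000
0.950000000000000067,CH4, 0.024645342128592446
1.050000000000000044,CH4, 0.091632798143372995
1.150000000000000133,CH4, 0.000000000000000000
1.250000000000000222,CH4, 0.358468863669696325
1.350000000000000089,CH4, 0.047892342055137371
1.450000000000000178,CH4, 0.115534578888542960
1.550000000000000044,CH4, 1.137182848629182175
1.650000000000000133,CH4, 1.604941017103299616
1.750000000000000222,CH4, 3.645010885015751434
1.850000000000000089,CH4, 5.108690175952138368
1.950000000000000178,CH4, 8.198422259803697543
2.049999999999999822,CH4,11.608447146367577574
2.149999999999999911,CH4,15.465207723277019980
2.250000000000000000,CH4,20.657299850635588712
2.350000000000000089,CH4,24.573294516358380690
2.450000000000000178,CH4,28.040001866814723286
2.549999999999999822,CH4,31.092648157709831480
2.649999999999999911,CH4,33.582552895482344013
2.750000000000000000,CH4,35.205104951472840469
2.850000000000000089,CH4,35.597077145837857870
2.950000000000000178,CH4,37.513347868930097206
0.050000000000000003,SO4,28.364117691338623928
0.150000000000000022,SO4,27.689046898384813034
0.250000000000000000,SO4,27.872873167366911673
0.350000000000000033,SO4,27.858824248517159106
0.450000000000000011,SO4,27.694019796090312724
0.550000000000000044,SO4,27.441340158927602033
0.650000000000000133,SO4,27.818739706036929249
0.750000000000000111,SO4,27.209501112971654635
0.850000000000000089,SO4,27.673592239398910664
0.950000000000000067,SO4,26.793803865898890848
1.050000000000000044,SO4,26.789701928817304832
1.150000000000000133,SO4,26.400209159412629134
1.250000000000000222,SO4,24.199250928691537155
1.350000000000000089,SO4,22.865429631367703678
1.450000000000000178,SO4,20.560933612000837911
1.550000000000000044,SO4,17.760519075814656276
1.650000000000000133,SO4,13.934614904336603658
1.750000000000000222,SO4, 9.477151054846530087
1.850000000000000089,SO4, 5.991603681172777307
1.950000000000000178,SO4, 4.114165828608647324
2.049999999999999822,SO4, 1.438150203187772425
2.149999999999999911,SO4, 0.000000000000000000
2.250000000000000000,SO4, 0.000000000000000000
2.350000000000000089,SO4, 0.370124729538125585
2.450000000000000178,SO4, 0.569350081154462173
2.549999999999999822,SO4, 0.000000000000000000
2.649999999999999911,SO4, 0.000000000000000000
2.750000000000000000,SO4, 0.000000000000000000
2.850000000000000089,SO4, 0.138043669654054929
2.950000000000000178,SO4, 0.000000000000000000
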