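# 4-10-2 multilayer perceptron parameters (tansig hidden layer, linear outputs)
# w1: hidden x input weight matrix, rows pair with b1 entries and w2 entries
# outputs: de (disinfection efficiency), nde (negative disinfection effect)
hidden_size: 10
[w1]
-2.2264843404709231 1.4445054452140973 0.37347240570903362 1.7912129167797899
0.28373790392803888 -2.4322869476045663 -0.49844554568205773 1.285538179348072
-1.577021437225925 -2.3216990424583965 -1.0439509360936723 -0.49127974227126764
-1.3929110122378521 -1.5862753950671646 -0.6943257810737461 0.92230670254520253
0.0062537023069687697 1.1089013107640835 0.70865214563352252 1.1472529657345023
-1.992372972284326 -0.82189187786987539 1.527011149326817 -0.18686885970967243
-1.1378541924874293 0.84648602435997011 -0.9780357313064737 -1.3630683902071483
1.5020518212917611 0.32509362788792218 -1.5693931358736695 -0.031089357432888279
-1.4882883913438978 -2.9651377089231907 2.199846446705342 -0.43752062219922738
1.3599011247022701 -0.81015345267550232 2.9754824151678636 -1.9571431435625306
[b1]
2.7373703731067001
-0.83325876887422079
2.171582970034827
0.56212948576185007
1.0424070358882143
-0.54324401496903252
-1.1022234392936949
2.0378619763856407
1.2672225714710146
2.9832316738791187
[w2_de]
-0.35262980357087659
-0.24318178776467936
-0.79248319436380665
0.82630798614474876
1.796820588074038
0.21420000089354962
0.60020942311500314
0.40809858306703195
0.57830471663552308
1.2020209830201682
[w2_nde]
-0.12048113211448197
0.34901295143434985
0.63326846110801793
0.042982012720122198
-0.68987705311744119
0.94749566689285258
-0.43511551317049457
-0.56189528509021669
-0.83086076761510286
-0.73536668215158751
[b2_de]
0.35872919821907595
[b2_nde]
-0.19926566214623609
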