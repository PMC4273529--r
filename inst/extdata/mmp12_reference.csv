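id,r_group,actual_pic50,predicted_pic50,residual,role,distance_score
10,,2.699,2.594,0.105,train,0.066
11,,1.8861,2.05,-0.1639,train,0.028
12,,1.8239,2.144,-0.3201,train,0.022
13,,3.1549,2.688,0.4669,train,0.049
14,,1.6383,1.646,-0.0077,train,0.332
15,,1.7447,1.754,-0.0093,test,0.065
16,,2.6576,2.672,-0.0144,train,0.208
19,,3.3979,3.706,-0.3081,train,0.037
20,,4,4.032,-0.032,train,0.043
21,,4,3.778,0.222,train,0.03
22,,3.699,3.647,0.052,train,0.033
23,,3.699,3.752,-0.053,train,0.031
24,,3,3.049,-0.049,train,0.005
25,,3.3979,3.17,0.2279,test,0.085
26,,3,2.945,0.055,train,0.009
27,,2.9208,2.949,-0.0282,train,0.008
33,Methyl,2.0655,2.341,-0.2755,train,0
34,Ethyl,2.5376,2.452,0.0856,train,0.01
35,i-Propyl,2.3468,2.423,-0.0762,train,0.087
36,t-Butyl,1.7696,1.839,-0.0694,train,0.554
37,i-Butyl,2.2676,2.203,0.0646,train,0.284
38,CH2OCH3,2.7212,2.571,0.1502,train,0.007
39,CF3,2.6576,2.543,0.1146,train,0
40,Cyclopropyl,2.7959,2.767,0.0289,train,0.08
41,Cyclobutyl,2.6383,2.689,-0.0507,train,0.377
42,Cyclohexyl,2.1427,2.126,0.0167,train,1
43,Phenyl,2.3979,2.561,-0.1631,train,0.116
44,,3.5229,3.491,0.0319,train,0.186
51,,2.5441,2.483,0.0611,test,0.059
52,,2.0969,2.502,-0.4051,test,0.088
53,,2.173,2.146,0.027,test,0.297
54,,2.5229,2.526,-0.0031,test,0.049
55,,2.1461,2.305,-0.1589,test,0.324
56,,2.8909,2.616,0.2749,test,
57,,2.8037,2.773,0.0307,test,0.668
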