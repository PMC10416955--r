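1,-1,498.33554,395.373303,26.741917,24.726257,0.715689,-1,-1,-1
1,-1,356.023803,397.720017,22.870604,25.265725,0.814721,-1,-1,-1
2,-1,186.400086,298.218126,23.418126,24.589385,0.187148,-1,-1,-1
2,-1,498.561606,393.869668,26.741917,24.726257,0.941853,-1,-1,-1
2,-1,359.093998,403.870627,22.870604,25.265725,0.864366,-1,-1,-1
3,-1,504.094753,397.48145,26.741917,24.726257,0.791339,-1,-1,-1
3,-1,362.533219,401.595536,22.870604,25.265725,0.820691,-1,-1,-1
4,-1,509.122886,402.863672,26.741917,24.726257,0.708279,-1,-1,-1
4,-1,364.752645,402.95622,22.870604,25.265725,0.954698,-1,-1,-1
5,-1,511.901719,403.790113,26.741917,24.726257,0.70931,-1,-1,-1
5,-1,364.740651,403.253003,22.870604,25.265725,0.895688,-1,-1,-1
6,-1,508.958467,404.177596,26.741917,24.726257,0.879052,-1,-1,-1
6,-1,365.417799,394.371089,22.870604,25.265725,0.793783,-1,-1,-1
7,-1,509.624078,404.365701,26.741917,24.726257,0.996073,-1,-1,-1
7,-1,371.315682,397.345277,22.870604,25.265725,0.948678,-1,-1,-1
8,-1,515.321328,406.662131,26.741917,24.726257,0.882315,-1,-1,-1
8,-1,361.486503,400.495724,22.870604,25.265725,0.741434,-1,-1,-1
9,-1,515.945211,406.474667,26.741917,24.726257,0.961278,-1,-1,-1
9,-1,368.384148,399.903969,22.870604,25.265725,0.873126,-1,-1,-1
10,-1,513.735806,410.384633,26.741917,24.726257,0.939752,-1,-1,-1
10,-1,365.440037,400.065354,22.870604,25.265725,0.708459,-1,-1,-1
11,-1,513.161275,410.048003,26.741917,24.726257,0.776907,-1,-1,-1
11,-1,367.926701,397.425987,22.870604,25.265725,0.92703,-1,-1,-1
12,-1,517.245843,408.865653,26.741917,24.726257,0.948984,-1,-1,-1
12,-1,365.924399,404.939942,22.870604,25.265725,0.857114,-1,-1,-1
13,-1,519.690939,414.141529,26.741917,24.726257,0.891381,-1,-1,-1
13,-1,366.108054,399.31228,22.870604,25.265725,0.846372,-1,-1,-1
14,-1,522.357444,412.368213,26.741917,24.726257,0.874552,-1,-1,-1
14,-1,363.984234,401.705296,22.870604,25.265725,0.730111,-1,-1,-1
15,-1,519.998945,421.384482,26.741917,24.726257,0.952484,-1,-1,-1
15,-1,363.976992,410.501906,22.870604,25.265725,0.820748,-1,-1,-1
16,-1,518.884267,410.709895,26.741917,24.726257,0.931781,-1,-1,-1
16,-1,358.683011,407.541458,22.870604,25.265725,0.985437,-1,-1,-1
17,-1,517.3409,413.927385,26.741917,24.726257,0.779641,-1,-1,-1
17,-1,362.528363,412.355132,22.870604,25.265725,0.948789,-1,-1,-1
18,-1,518.585061,416.054276,26.741917,24.726257,0.896098,-1,-1,-1
18,-1,355.595387,409.182071,22.870604,25.265725,0.939555,-1,-1,-1
19,-1,512.634089,409.223705,26.741917,24.726257,0.755845,-1,-1,-1
19,-1,359.391678,413.900621,22.870604,25.265725,0.926412,-1,-1,-1
20,-1,510.934754,414.036638,26.741917,24.726257,0.920776,-1,-1,-1
20,-1,355.295746,415.609585,22.870604,25.265725,0.925536,-1,-1,-1
21,-1,507.44605,408.133483,26.741917,24.726257,0.799784,-1,-1,-1
21,-1,358.96173,412.48564,22.870604,25.265725,0.717265,-1,-1,-1
22,-1,515.708534,414.039015,26.741917,24.726257,0.902325,-1,-1,-1
22,-1,348.849104,408.7444,22.870604,25.265725,0.712471,-1,-1,-1
23,-1,505.028246,412.261981,26.741917,24.726257,0.893069,-1,-1,-1
23,-1,352.456317,405.821881,22.870604,25.265725,0.789881,-1,-1,-1
24,-1,500.702009,415.039398,26.741917,24.726257,0.818029,-1,-1,-1
24,-1,351.572643,409.258553,22.870604,25.265725,0.977051,-1,-1,-1
25,-1,502.70504,417.698467,26.741917,24.726257,0.903765,-1,-1,-1
25,-1,352.16712,408.808372,22.870604,25.265725,0.915264,-1,-1,-1
26,-1,504.696695,414.811643,26.741917,24.726257,0.915141,-1,-1,-1
26,-1,358.358664,403.781795,22.870604,25.265725,0.768452,-1,-1,-1
27,-1,504.511569,416.400904,26.741917,24.726257,0.822632,-1,-1,-1
27,-1,360.8154,402.740921,22.870604,25.265725,0.871334,-1,-1,-1
28,-1,513.703512,410.368937,26.741917,24.726257,0.963835,-1,-1,-1
28,-1,353.625752,407.57845,22.870604,25.265725,0.878403,-1,-1,-1
29,-1,511.442671,407.863691,26.741917,24.726257,0.975444,-1,-1,-1
29,-1,352.176164,411.366479,22.870604,25.265725,0.805415,-1,-1,-1
30,-1,511.682012,412.267996,26.741917,24.726257,0.776197,-1,-1,-1
30,-1,352.066311,407.202,22.870604,25.265725,0.914233,-1,-1,-1
31,-1,504.825233,417.205153,26.741917,24.726257,0.765541,-1,-1,-1
31,-1,356.69999,402.661507,22.870604,25.265725,0.83301,-1,-1,-1
32,-1,504.494249,420.387656,26.741917,24.726257,0.908864,-1,-1,-1
32,-1,357.264002,410.9601,22.870604,25.265725,0.902051,-1,-1,-1
33,-1,507.463125,416.954377,26.741917,24.726257,0.754162,-1,-1,-1
33,-1,359.221162,408.168148,22.870604,25.265725,0.919524,-1,-1,-1
34,-1,501.404671,414.548679,26.741917,24.726257,0.797969,-1,-1,-1
34,-1,359.782394,408.821847,22.870604,25.265725,0.805727,-1,-1,-1
35,-1,499.338344,416.179829,26.741917,24.726257,0.936698,-1,-1,-1
35,-1,364.635913,408.122754,22.870604,25.265725,0.809361,-1,-1,-1
36,-1,501.432154,418.290601,26.741917,24.726257,0.784948,-1,-1,-1
36,-1,361.517292,400.460949,22.870604,25.265725,0.778186,-1,-1,-1
37,-1,499.441227,422.620526,26.741917,24.726257,0.708076,-1,-1,-1
37,-1,360.117532,400.967749,22.870604,25.265725,0.896888,-1,-1,-1
38,-1,502.772905,424.704305,26.741917,24.726257,0.924034,-1,-1,-1
38,-1,355.025152,407.563422,22.870604,25.265725,0.889344,-1,-1,-1
39,-1,500.694498,425.393834,26.741917,24.726257,0.716355,-1,-1,-1
39,-1,353.007975,401.538974,22.870604,25.265725,0.858185,-1,-1,-1
40,-1,499.122015,416.609998,26.741917,24.726257,0.726332,-1,-1,-1
40,-1,349.442003,393.913136,22.870604,25.265725,0.781086,-1,-1,-1
41,-1,499.628004,417.756343,26.741917,24.726257,0.700382,-1,-1,-1
41,-1,349.4571,394.178363,22.870604,25.265725,0.911954,-1,-1,-1
42,-1,352.634981,393.815225,22.870604,25.265725,0.740288,-1,-1,-1
43,-1,494.890728,404.556371,26.741917,24.726257,0.879739,-1,-1,-1
43,-1,347.190116,395.279685,22.870604,25.265725,0.807764,-1,-1,-1
44,-1,501.016527,403.778056,26.741917,24.726257,0.903419,-1,-1,-1
44,-1,348.170107,391.106292,22.870604,25.265725,0.809779,-1,-1,-1
45,-1,502.115652,403.68767,26.741917,24.726257,0.940266,-1,-1,-1
45,-1,352.08999,396.347572,22.870604,25.265725,0.996109,-1,-1,-1
46,-1,500.77926,408.956779,26.741917,24.726257,0.844978,-1,-1,-1
46,-1,353.348075,393.089336,22.870604,25.265725,0.72361,-1,-1,-1
47,-1,508.4597,404.767065,26.741917,24.726257,0.740337,-1,-1,-1
47,-1,347.502427,392.822436,22.870604,25.265725,0.968301,-1,-1,-1
48,-1,47.745816,301.015555,24.334348,24.785483,0.216531,-1,-1,-1
48,-1,500.808599,404.659604,26.741917,24.726257,0.914064,-1,-1,-1
48,-1,349.146733,396.176557,22.870604,25.265725,0.96225,-1,-1,-1
49,-1,499.147673,398.369149,26.741917,24.726257,0.971132,-1,-1,-1
49,-1,339.870366,391.230494,22.870604,25.265725,0.84319,-1,-1,-1
50,-1,499.17917,406.391159,26.741917,24.726257,0.720034,-1,-1,-1
50,-1,345.858804,387.736956,22.870604,25.265725,0.915964,-1,-1,-1
51,-1,502.283263,406.393715,26.741917,24.726257,0.781579,-1,-1,-1
51,-1,346.280583,390.581669,22.870604,25.265725,0.797974,-1,-1,-1
52,-1,491.966255,405.400202,26.741917,24.726257,0.815515,-1,-1,-1
52,-1,343.217083,396.464178,22.870604,25.265725,0.799213,-1,-1,-1
53,-1,497.354762,401.831157,26.741917,24.726257,0.729574,-1,-1,-1
53,-1,341.884424,398.494,22.870604,25.265725,0.874354,-1,-1,-1
54,-1,495.952668,405.165594,26.741917,24.726257,0.926858,-1,-1,-1
54,-1,338.688371,401.867615,22.870604,25.265725,0.855101,-1,-1,-1
55,-1,491.57557,399.501449,26.741917,24.726257,0.782358,-1,-1,-1
55,-1,346.441975,404.912916,22.870604,25.265725,0.833385,-1,-1,-1
56,-1,485.012877,397.965629,26.741917,24.726257,0.968682,-1,-1,-1
56,-1,346.78829,408.711123,22.870604,25.265725,0.976385,-1,-1,-1
57,-1,476.576823,395.520042,26.741917,24.726257,0.856401,-1,-1,-1
57,-1,348.969324,405.627517,22.870604,25.265725,0.929759,-1,-1,-1
58,-1,476.615225,399.21776,26.741917,24.726257,0.930016,-1,-1,-1
58,-1,343.955652,402.986142,22.870604,25.265725,0.951469,-1,-1,-1
59,-1,482.142226,401.586554,26.741917,24.726257,0.982225,-1,-1,-1
59,-1,339.989387,403.798776,22.870604,25.265725,0.826836,-1,-1,-1
60,-1,485.004357,398.124312,26.741917,24.726257,0.881421,-1,-1,-1
60,-1,342.002055,405.082116,22.870604,25.265725,0.766059,-1,-1,-1
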