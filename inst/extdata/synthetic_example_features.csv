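subject_id,cohort,diagnosis,sex,age,region01_thickness,region02_thickness,region03_thickness,region04_thickness,region01_area,region02_area,region03_area,region04_area,region01_volume,region02_volume,region03_volume,region04_volume
DS1_HC001,DS1,HC,M,27.9,3.0996379014737085,2.2885705832914653,2.618950542160681,2.679555266509973,2479.0417169487855,2643.1781726100935,3083.103946356756,2357.0637497385,9645.91580701223,9149.258222387693,8057.539471907096,9998.473179806533
DS1_HC002,DS1,HC,F,35.7,3.0022676506438106,2.049106934388107,2.898543456407318,2.4764865397163947,2804.628366866071,2744.261972210294,3220.207392643911,2776.0348908759397,7973.79278514571,6386.357707524803,8831.099515586104,9558.32002311196
DS1_HC003,DS1,HC,F,50.5,3.2762903871916897,2.3756330505827736,2.793088691240067,2.820864248363106,2832.8832349279337,2261.3973457402517,3298.473687954138,2432.509717494726,8920.33982027224,7035.250623717859,8171.610049378623,9230.153616451767
DS1_HC004,DS1,HC,M,20.2,3.033465521367766,2.2081246939127213,2.6400197779657915,2.30045249564034,2817.0533840386033,2916.0332983167573,2584.9157823839646,2707.8425276183752,6089.243141394956,5986.727734716437,6879.8584169166315,8617.2197299511
DS1_HC005,DS1,HC,F,36.4,3.3100446642441055,2.309289821394151,2.1953635011345884,2.98582489905521,1957.5114375976882,1797.8052724861295,4031.8236014281747,2101.661669976324,11658.372716126527,3534.3031174174844,8230.792103222326,10373.692821694578
DS1_HC006,DS1,HC,F,33.7,3.1225854994949693,2.2130392737242013,2.818941940854211,2.7029982060532647,2727.3815251472183,2407.13955191674,2845.066161485902,2387.7028284104185,9949.542123473833,8061.5224420159,8640.377683219633,11639.837676260982
DS1_EM001,DS1,EM,F,26.3,2.8925637777936926,2.2592305791678595,2.7437589873204278,2.841233388853082,2264.7325452022314,2302.9666992147622,3361.1961999606806,1987.2843028066027,8419.98153444492,6496.103898364792,8179.52797463839,7385.467542021003
DS1_EM002,DS1,EM,F,48,2.8938254549152167,2.2462703670970723,2.466163208365905,2.4749538744441817,2558.567161776857,2623.6674505659103,3463.4931738965183,1901.4574426612148,8902.013803068434,6223.320607732654,8839.11840253396,8273.686734888815
DS1_CM001,DS1,CM,F,40.1,2.6561894660909604,2.2554121133223832,2.7518581550596353,2.5766100609909675,1696.355506738057,2434.1233621165106,3008.8104131276114,1548.9015978588463,10823.595738792668,5506.3284803047345,10045.669830394272,9087.72074057326
DS1_CM002,DS1,CM,M,21.6,3.3459503013811016,2.539145744444048,2.7838503786288262,2.8079678172287657,1717.3435942250571,2637.504243538212,3339.808066598543,1997.6932522035454,10135.770028547118,4835.056931011379,8215.788269029412,8002.01328605179
DS2_HC001,DS2,HC,F,35,2.7634587772320263,2.4100165307322396,2.547156860752734,2.5984483039314377,2049.1244657995167,3459.1928955286867,3331.1532966418113,979.4904346688811,9589.352694488849,5476.799819872668,8572.789697873066,9557.350460892227
DS2_HC002,DS2,HC,F,44,2.847606519853138,2.1961534271288103,2.6802544719301693,2.7923400355051777,2627.787759708454,2533.374852950113,2943.9676810018855,2408.4012313910844,9151.144756911384,7168.620481420614,9150.247665121298,10728.826308642685
DS2_HC003,DS2,HC,F,52,3.2577155493604,2.6477849609888002,2.7773121621221675,2.786767784097397,2929.2661560241304,3137.271780499364,3393.0222693857463,1433.910654337061,10462.509353814052,5531.933504181361,8360.889784736304,10739.125003991934
DS2_HC004,DS2,HC,F,44.9,2.7735358070405387,2.585305400440219,2.695725925343972,2.3650153652566104,2464.5910896574055,3412.9854872758515,3079.2760497445365,1071.6018261340025,11378.650974005266,5953.768528535184,11149.712150505251,11233.425201298456
DS2_HC005,DS2,HC,F,41.2,3.135661562058244,2.1887190065552304,2.637470939147705,2.846802322910193,2495.385214969428,2316.0926540516116,2873.621529766136,2634.207722401642,10426.320559680675,8195.261315625346,9689.990657250844,10266.659952184185
DS2_EM001,DS2,EM,F,39,2.890412437788057,2.140460755427825,2.7048194174759987,2.689196451133061,2469.30309845686,2429.448797867397,3313.2755776361255,2052.3645641850458,10637.781834003346,5431.10016179324,9312.034285516575,9105.784386132338
DS2_EM002,DS2,EM,M,32.1,2.8703731223843056,2.053914724122568,2.50221432073462,2.5064046860403297,2435.525392694898,2513.336732182279,3046.5285255122276,2152.41487309532,10884.562345880153,5951.9499842809755,8013.421210701366,8749.394591601103
DS2_CM001,DS2,CM,M,34.8,3.076255723826502,2.1647099489259274,2.6228407535274645,2.9378492348998333,1738.31099291891,2437.7564890548338,2704.2844991031957,1687.3593202068412,10439.99275013898,6627.674005382361,9551.295254661456,8838.535621656467
DS2_CM002,DS2,CM,F,54.2,3.039190194369861,2.3573868387257173,2.650781827246804,2.6856701604772724,1651.1457475075827,2803.750497292435,3271.42723963083,2435.7322770530222,9444.740847047862,4726.926914736875,8191.736509049764,8129.909454278208
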