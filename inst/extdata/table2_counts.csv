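variable,level,n_case,pct_case,n_control,pct_control
educ_respondent,none,1808,15.7,9730,84.3
educ_respondent,primary,1369,23.2,4543,76.8
educ_respondent,secondary,2009,34.1,3881,65.9
educ_respondent,higher,650,51.0,624,49.0
educ_partner,none,1472,16.2,7624,83.8
educ_partner,primary,1210,23.0,4048,77.0
educ_partner,secondary,1874,28.0,4813,72.0
educ_partner,higher,1124,40.7,1640,59.3
residence,urban,2500,36.4,4365,63.6
residence,rural,3336,18.8,14413,81.2
religion,catholic,724,31.5,1577,68.5
religion,other_christian,2604,30.1,6045,69.9
religion,islam,2372,18.2,10662,81.8
religion,traditionalist,88,19.6,360,80.4
religion,other,14,38.9,22,61.1
wealth,poorest,718,12.0,5279,88.0
wealth,poorer,828,14.4,4920,85.6
wealth,middle,1195,24.2,3745,75.8
wealth,richer,1386,32.0,2943,68.0
wealth,richest,1709,47.5,1891,52.5
ethnicity,Ekoi,67,16.7,334,83.3
ethnicity,Fulani,202,10.2,1787,89.8
ethnicity,Hausa,1120,17.5,5275,82.5
ethnicity,Ibibio,153,36.8,263,63.2
ethnicity,Igala,99,31.5,215,68.5
ethnicity,Igbo,1091,39.0,1708,61.0
ethnicity,Ijaw/Izon,297,35.3,544,64.7
ethnicity,Kanuri/Beriberi,115,16.5,584,83.5
ethnicity,Tiv,102,14.0,626,86.0
ethnicity,Yoruba,879,31.3,1934,68.7
ethnicity,Others,1684,23.8,5400,76.2
state,Akwa Ibom,169,34.9,316,65.2
state,Anambra,222,47.2,248,52.8
state,Bauchi/Gombe,213,12.1,1544,87.9
state,Edo,230,39.2,357,60.8
state,Benue,92,11.9,683,88.1
state,Borno,193,21.8,693,78.2
state,Cross River,133,24.2,417,75.8
state,Adamawa,136,16.1,709,83.9
state,Imo,183,46.8,208,53.2
state,Kaduna,196,22.2,688,77.8
state,Kano,227,19.1,963,80.9
state,Katsina,113,10.8,929,89.2
state,Kwara,118,24.1,372,75.9
state,Lagos,357,50.2,354,49.8
state,Niger,199,20.7,762,79.3
state,Ogun,98,21.6,355,78.4
state,Ondo/Ekiti,254,26.9,690,73.1
state,Oye,135,26.7,370,73.3
state,Nassarawa/Plateau,276,20.3,1083,79.7
state,Rivers/Bayelsa,410,39.4,631,60.6
state,Sokoto/Zamfara,230,14.8,1323,85.2
state,Abia,158,38.6,251,61.4
state,Delta,123,26.9,335,73.1
state,Enungu/Ebonyi,253,25.5,741,74.5
state,Jigawa,123,13.9,760,86.1
state,Kebbi,207,26.9,563,73.1
state,Kogi,141,28.6,352,71.4
state,Osun,82,19.3,343,80.7
state,Taraba,238,26.1,674,73.9
state,Yobe,87,10.5,741,89.5
state,Abuja,240,42.6,323,57.4
excluded,underweight,3353,,,
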