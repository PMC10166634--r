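sex,site,age_group,duration,R,method
female,breast_like,0-29,5,0.82589281819539,model
female,breast_like,0-29,10,1,model
female,breast_like,0-29,15,1,model
female,breast_like,0-29,20,1,model
female,breast_like,0-29,25,1,model
female,breast_like,0-29,30,1,model
female,breast_like,0-29,35,1,model
female,breast_like,30-34,5,0.552695257725606,model
female,breast_like,30-34,10,0.894073966323514,model
female,breast_like,30-34,15,1,model
female,breast_like,30-34,20,1,model
female,breast_like,30-34,25,1,model
female,breast_like,30-34,30,1,model
female,breast_like,30-34,35,1,model
female,breast_like,35-39,5,0.459094668408598,model
female,breast_like,35-39,10,0.742668902444078,model
female,breast_like,35-39,15,0.937148462895939,model
female,breast_like,35-39,20,1,model
female,breast_like,35-39,25,1,model
female,breast_like,35-39,30,1,model
female,breast_like,35-39,35,1,model
female,breast_like,40-44,5,0.40941833257924,model
female,breast_like,40-44,10,0.662319716557366,model
female,breast_like,40-44,15,0.835768947213959,model
female,breast_like,40-44,20,0.959661356121124,model
female,breast_like,40-44,25,1,model
female,breast_like,40-44,30,1,model
female,breast_like,40-44,35,1,model
female,breast_like,45-49,5,0.379558676215298,model
female,breast_like,45-49,10,0.614029349085817,model
female,breast_like,45-49,15,0.774844959852003,model
female,breast_like,45-49,20,0.889716885594211,model
female,breast_like,45-49,25,0.972774267378723,model
female,breast_like,45-49,30,1,model
female,breast_like,45-49,35,1,model
female,breast_like,50-54,5,0.360517476514642,model
female,breast_like,50-54,10,0.583244015268799,model
female,breast_like,50-54,15,0.736013849349634,model
female,breast_like,50-54,20,0.845143327481241,model
female,breast_like,50-54,25,0.92405114450681,model
female,breast_like,50-54,30,0.981292130153329,model
female,breast_like,50-54,35,1,model
female,breast_like,55-59,5,0.347780309103162,model
female,breast_like,55-59,10,0.562661464724446,model
female,breast_like,55-59,15,0.710061754886633,model
female,breast_like,55-59,20,0.815361583470218,model
female,breast_like,55-59,25,0.891503471476847,model
female,breast_like,55-59,30,0.946739672756551,model
female,breast_like,55-59,35,0.98684212822446,model
female,breast_like,60-64,5,0.335685766495079,model
female,breast_like,60-64,10,0.54629171426297,model
female,breast_like,60-64,15,0.690775413984459,model
female,breast_like,60-64,20,0.793999976889443,model
female,breast_like,60-64,25,0.868645596233315,model
female,breast_like,60-64,30,0.922798637878977,model
female,breast_like,60-64,35,0.962115907934174,model
female,breast_like,65-69,5,0.325212713173806,model
female,breast_like,65-69,10,0.526569384737513,model
female,breast_like,65-69,15,0.671497864150757,model
female,breast_like,65-69,20,0.775051198625046,model
female,breast_like,65-69,25,0.849940339040899,model
female,breast_like,65-69,30,0.904273089458141,model
female,breast_like,65-69,35,0.943722439423179,model
female,breast_like,70-74,5,0.327309888022841,model
female,breast_like,70-74,10,0.517489753090501,model
female,breast_like,70-74,15,0.655803245259003,model
female,breast_like,70-74,20,0.760091408811466,model
female,breast_like,70-74,25,0.835520131326206,model
female,breast_like,70-74,30,0.890248652619446,model
female,breast_like,70-74,35,0.9299876273119,model
female,breast_like,75-79,5,0.325151910052379,model
female,breast_like,75-79,10,0.517298244541463,model
female,breast_like,75-79,15,0.647718405490231,model
female,breast_like,75-79,20,0.747616943510694,model
female,breast_like,75-79,25,0.823872351934129,model
female,breast_like,75-79,30,0.879206441293645,model
female,breast_like,75-79,35,0.919388160604688,model
female,breast_like,80+,5,0.331112950135751,model
female,breast_like,80+,10,0.514084312625961,model
female,breast_like,80+,15,0.640476507310626,model
female,breast_like,80+,20,0.733777303337106,model
female,breast_like,80+,25,0.804844915885724,model
female,breast_like,80+,30,0.858653819761108,model
female,breast_like,80+,35,0.898934409380472,model
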