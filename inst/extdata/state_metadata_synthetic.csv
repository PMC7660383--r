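"code","name","population","lat","lon","law_restrictiveness","included"
"S01","Unit S01",27202429,30.0726380343549,-120.964755215216,0.237070526570442,TRUE
"S02","Unit S02",3102020,30.9099462213926,-112.229561093729,0.325612325735269,TRUE
"S03","Unit S03",20273928,29.7086089500226,-105.96373809129,0.175633534657504,TRUE
"S04","Unit S04",2635574,29.8448683354072,-96.5132705955766,0.179136527050548,TRUE
"S05","Unit S05",2839392,30.1959859491326,-90.5455362871289,0.244708168025023,TRUE
"S06","Unit S06",2605890,30.4867078168318,-82.332474087365,0.231100233797727,TRUE
"S07","Unit S07",689435,30.9687224277295,-75.9372681300156,0.76353727445983,TRUE
"S08","Unit S08",2794390,33.4098300090991,-120.180657627992,0.200514309524721,TRUE
"S09","Unit S09",802168,32.5570341106504,-112.226646000985,0.263344347994874,TRUE
"S10","Unit S10",25734581,32.858969939407,-105.188690362033,0.207724154779863,TRUE
"S11","Unit S11",949842,32.6464772731997,-97.4124246961437,0.180785321257398,TRUE
"S12","Unit S12",563605,32.0348933422938,-90.0096060126089,0.228265759126062,TRUE
"S13","Unit S13",2547283,32.9731745538302,-82.9438592772931,0.750305472890785,TRUE
"S14","Unit S14",13163291,32.4306351300329,-74.4510047840886,0.329779828340654,TRUE
"S15","Unit S15",19662732,36.061056190636,-120.207920555491,0.718637724458079,TRUE
"S16","Unit S16",1289769,36.1968885306269,-111.634604002815,0.22171773245862,TRUE
"S17","Unit S17",7505111,35.3748585595749,-105.172167882789,0.729017904590023,TRUE
"S18","Unit S18",2509757,36.8081359979697,-97.7247245744802,0.219771297673402,TRUE
"S19","Unit S19",16817346,36.2789393705316,-90.1546888570301,0.161229452748629,TRUE
"S20","Unit S20",23995740,35.9578401725739,-83.2249290375039,0.183720223796838,TRUE
"S21","Unit S21",2371734,35.4912346699275,-75.0922187129036,0.179022299725766,TRUE
"S22","Unit S22",12337367,39.6781123219989,-119.580018814187,0.185553568529006,TRUE
"S23","Unit S23",24958320,38.652969783172,-112.748132308479,0.27109689386631,TRUE
"S24","Unit S24",3318818,38.3341198009439,-105.049302186817,0.219066571731809,TRUE
"S25","Unit S25",5301592,38.5147057306021,-97.434607532341,0.176553349514833,TRUE
"S26","Unit S26",5495699,39.2961118896492,-89.7397275567055,0.217246207091345,TRUE
"S27","Unit S27",6483839,38.8191462350078,-81.6624667979777,0.124441209161833,TRUE
"S28","Unit S28",1594443,39.7288940949365,-74.2050882326439,0.233539368427428,TRUE
"S29","Unit S29",534151,42.548103982117,-119.285768878646,0.729537854399266,TRUE
"S30","Unit S30",10856972,41.0331404642202,-112.850853920449,0.171591577308736,TRUE
"S31","Unit S31",34567602,42.6474792906083,-105.101819948759,0.112761721423692,TRUE
"S32","Unit S32",503022,42.517325533554,-98.3095580604859,0.170822572006412,TRUE
"S33","Unit S33",2325893,42.296448931098,-89.494619668927,0.134192630205641,TRUE
"S34","Unit S34",2727361,42.6231124531478,-81.7571315155365,0.251208492532729,TRUE
"S35","Unit S35",4520634,42.6283459807746,-75.5874041593634,0.758355115250434,TRUE
"S36","Unit S36",8466851,45.9952715961263,-119.305519811809,0.234374324864512,TRUE
"S37","Unit S37",6446539,44.2196291643195,-111.917022369336,0.186246720018432,TRUE
"S38","Unit S38",3865009,44.5067680724896,-104.988022253849,0.192328038225269,TRUE
"S39","Unit S39",3506997,44.2636692691594,-96.5391497984529,0.179645902235445,TRUE
"S40","Unit S40",1432521,45.5741122765467,-90.4214651663788,0.117469619111094,TRUE
"S41","Unit S41",11006395,45.4989811824635,-82.353702690918,0.189029552036707,TRUE
"S42","Unit S42",570304,45.9537610635161,-75.2261303318664,0.726309839800668,TRUE
"S43","Unit S43",45286534,47.1021407386288,-119.862029290292,0.181411297357202,TRUE
"S44","Unit S44",1049283,47.400061886292,-112.664043454919,0.217786154258109,TRUE
"S45","Unit S45",4359734,48.2450527441688,-104.203391406219,0.174340872192408,TRUE
"S46","Unit S46",2662166,47.6874852990732,-97.5369132962078,0.140448112640385,TRUE
"S47","Unit S47",2414478,48.1817509140819,-89.8225047015585,0.242034275182963,TRUE
"S48","Unit S48",5678788,47.3050593729131,-82.9285908327438,0.213074867015755,TRUE
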