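"moa","hrac","2","5","9","4","12+13+27","15","14","1","3","22"
"ALS inhibitors","2",1,0.526,0.366,0.303,0.126,0.128,0.14,0.359,0.115,0.154
"PSII inhibitors","5",0.526,1,0.266,0.171,0.164,0.129,0.164,0.256,0.129,0.238
"EPSP synthase inhibitors","9",0.366,0.266,1,0.246,0.205,0.182,0.205,0.212,0.156,0.25
"Synthetic auxins","4",0.303,0.171,0.246,1,0.167,0.108,0.135,0.045,0.051,0.043
"Carotenoid biosynthesis inhibitors","12+13+27",0.126,0.164,0.205,0.167,1,0.438,0.2,0.109,0.211,0.148
"Lipid synthesis inhibitors","15",0.128,0.129,0.182,0.108,0.438,1,0.211,0.19,0.375,0.111
"PPO inhibitors","14",0.14,0.164,0.205,0.135,0.2,0.211,1,0.063,0.211,0.107
"ACCase inhibitors","1",0.359,0.256,0.212,0.045,0.109,0.19,0.063,1,0.25,0.16
"Microtubule assembly inhibitors","3",0.115,0.129,0.156,0.051,0.211,0.375,0.211,0.25,1,0.111
"PSI inhibitors","22",0.154,0.238,0.25,0.043,0.148,0.111,0.107,0.16,0.111,1
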