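activity,WF,WL,WR,WU,WD,RF,JU,Si,St,Sl,EU,ED
WF,1,0.774,0.980,0.874,0.985,0.996,0.980,0.997,0.999,1,0.999,1
WL,0.774,1,0.989,0.968,0.958,0.998,0.996,0.951,0.999,1,0.999,1
WR,0.980,0.989,1,0.798,0.998,0.997,0.988,0.988,0.971,1,0.981,1
WU,0.874,0.968,0.798,1,0.708,0.985,0.979,0.962,0.998,1,0.971,1
WD,0.985,0.958,0.998,0.708,1,0.992,0.878,0.967,0.850,1,0.986,1
RF,0.996,0.998,0.997,0.985,0.992,1,0.978,0.991,0.996,0.957,0.994,1
JU,0.980,0.996,0.988,0.979,0.878,0.978,1,0.973,1,0.929,1,1
Si,0.997,0.951,0.988,0.962,0.967,0.991,0.973,1,0.987,1,0.126,0.992
St,0.999,0.999,0.971,0.999,0.850,0.995,1,0.987,1,1,0.326,0.887
Sl,1,1,1,1,1,0.957,0.930,1,1,1,1,0.992
EU,0.999,0.999,0.981,0.971,0.986,0.994,1,0.126,0.326,1,1,0.697
ED,1,1,1,1,1,1,1,0.992,0.887,0.992,0.697,1
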