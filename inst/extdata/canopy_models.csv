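band,crop,stage,intercept,slope,r_squared,p_flag
A,alfalfa,1,2.6155,0.8048,0.3741,***
A,alfalfa,2,6.2248,0.5754,0.215,***
A,bean,1,3.4655,0.6863,0.9657,***
A,bean,2,0.05918,0.9552,0.4966,***
A,corn,1,-3.3529,1.2681,0.8206,***
A,corn,2,2.8026,0.7680,0.8563,***
A,pasture,1,-0.2593,1.1113,0.6318,***
A,pasture,2,5.9341,0.5464,0.5804,***
A,potato,1,-3.0608,1.2029,0.7089,***
A,potato,2,3.8663,0.7018,0.4248,***
B,alfalfa,1,0.8681,1.0350,0.4932,***
B,alfalfa,2,7.38339,0.31449,0.3017,***
B,bean,1,7.03727,0.35023,0.674,***
B,bean,2,0.87834,0.88096,0.9315,***
B,corn,1,1.0665,0.9809,0.8702,***
B,corn,2,2.2445,0.7935,0.946,**
B,pasture,1,-2.1935,1.3620,0.5521,***
B,pasture,2,3.3894,0.6443,0.3717,***
B,potato,1,0.41817,0.96059,0.9559,***
B,potato,2,3.50316,0.71010,0.4934,***
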