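theta,measure,healthy,preop,f05,f10,f15
30,peak,2.17,2.61,2.99,5.41,4.31
45,peak,1.9,2.72,4.16,3.75,4.06
60,peak,1.79,2.45,2.52,2.57,2.7
75,peak,2,1.95,2.4,2.36,2.39
30,mean,0.85,1.03,1.05,1.2,1.36
45,mean,0.78,1.18,1.32,1.37,1.44
60,mean,0.74,0.94,1.32,1.24,1.41
75,mean,0.76,0.89,0.98,1,1.06
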