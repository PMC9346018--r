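theta,measure,region,healthy,preop,f05,f10,f15
30,peak,patella,0.844,0.94,1.719,1.985,1.359
45,peak,patella,0.724,1.302,1.433,1.395,1.623
60,peak,patella,0.893,0.919,1.238,1.16,1.336
75,peak,patella,1.002,0.975,1.025,0.989,0.979
30,peak,trochlea,1.027,0.939,1.141,1.636,1.608
45,peak,trochlea,0.945,1.381,1.948,1.795,1.923
60,peak,trochlea,0.834,1.06,1.293,1.338,1.57
75,peak,trochlea,0.905,1.067,1.208,1.36,1.204
30,mean,patella,0.46,0.5,0.49,0.62,0.62
45,mean,patella,0.43,0.55,0.64,0.63,0.66
60,mean,patella,0.42,0.47,0.55,0.56,0.61
75,mean,patella,0.43,0.46,0.52,0.51,0.51
30,mean,trochlea,0.43,0.47,0.5,0.74,0.7
45,mean,trochlea,0.41,0.59,0.69,0.74,0.72
60,mean,trochlea,0.41,0.52,0.62,0.65,0.67
75,mean,trochlea,0.46,0.52,0.61,0.63,0.57
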