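zone,n,mean_measured,sd_measured,mean_predicted,sd_predicted,mean_corrected_published,sd_corrected_published,p_uncorrected_published,p_corrected_published
gray,78,5.02,1.3,4.94,0.97,4.54,0.89,0.50,0.0005
pink,136,7.71,1.81,7.74,0.85,7.12,0.78,0.80,0.0005
red,55,8.79,1.04,9.56,0.69,8.79,0.63,0.0005,0.98
purple,113,11.17,1.36,12.07,0.91,11.1,0.84,0.0005,0.44
yellow,107,13.8,1.89,14.95,1.3,13.76,1.2,0.0005,0.73
white,105,17.69,2.17,19.58,1.88,18.01,1.73,0.0005,0.063
blue,86,22.7,3.11,24.72,2.12,22.74,1.95,0.0005,0.89
orange,39,26.8,3.44,29.33,2.26,26.98,2.08,0.0005,0.69
green,50,29.32,3.45,33.52,1.83,30.84,1.68,0.0005,0.003
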