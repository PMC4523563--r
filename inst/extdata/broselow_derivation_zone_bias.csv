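zone,n,mean_d,sd_d,mean_after_published,sd_after_published
gray,55,16.37,20.49,7.05,18.84
pink,93,4.30,12.98,-4.04,11.94
red,97,7.37,17.11,-1.2,15.75
purple,91,4.39,12.55,-3.95,11.55
yellow,121,8.81,12.29,0.11,11.31
white,104,9.86,17.85,1.07,16.42
blue,91,11.46,10.17,2.54,9.36
orange,79,10.78,10.86,1.91,9.99
green,38,3.49,11.21,-4.79,10.31
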