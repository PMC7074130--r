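id,lfc_1,se_1,lfc_2,se_2
AT2G42230,-0.277,0.006,0.152,0.006
AT3G56110,0.081,0.121,0.228,0.099
AT1G23330,0.351,0.018,-0.209,0.012
AT5G23060,-0.243,0.005,-0.909,0.005
AT5G06240,-0.680,0.022,0.103,0.012
AT3G20350,-0.952,0.007,-0.090,0.009
AT1G30440,-1.056,0.010,-0.398,0.009
AT1G30490,-0.983,0.008,-0.322,0.006
AT1G23400,-1.017,0.011,-0.275,0.006
AT1G17980,0.734,0.001,-0.001,0.006
AT2G30890,-1.040,0.150,-0.142,0.125
AT5G15160,-0.044,0.129,-1.059,0.225
AT5G45310,-0.221,0.162,-1.404,0.313
AT5G46871,0.373,0.065,0.886,0.094
AT2G22240,0.076,0.016,-0.975,0.043
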