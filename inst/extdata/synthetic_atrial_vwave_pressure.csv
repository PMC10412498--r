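t_s,p_mmhg
0.0000,10.00
0.0100,10.07
0.0200,10.27
0.0300,10.60
0.0400,11.06
0.0500,11.64
0.0600,12.33
0.0700,13.12
0.0800,14.00
0.0900,14.95
0.1000,15.97
0.1100,17.03
0.1200,18.12
0.1300,19.22
0.1400,20.32
0.1500,21.40
0.1600,22.44
0.1700,23.44
0.1800,24.36
0.1900,25.21
0.2000,25.96
0.2100,26.60
0.2200,27.14
0.2300,27.55
0.2400,27.83
0.2500,27.98
0.2600,27.62
0.2700,26.69
0.2800,25.75
0.2900,24.81
0.3000,23.88
0.3100,22.94
0.3200,22.00
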