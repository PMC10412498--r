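t_s,p_mmhg
0.0000,78.00
0.0100,78.72
0.0200,80.81
0.0300,84.15
0.0400,88.50
0.0500,93.56
0.0600,99.00
0.0700,104.44
0.0800,109.50
0.0900,113.85
0.1000,117.19
0.1100,119.28
0.1200,120.00
0.1300,119.28
0.1400,117.19
0.1500,113.85
0.1600,109.50
0.1700,104.44
0.1800,99.00
0.1900,93.56
0.2000,88.50
0.2100,84.15
0.2200,80.81
0.2300,78.72
0.2400,78.00
0.2500,118.12
0.2600,116.25
0.2700,114.38
0.2800,112.50
0.2900,110.62
0.3000,108.75
0.3100,106.88
0.3200,105.00
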