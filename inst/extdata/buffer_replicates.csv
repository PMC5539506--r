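phone,sample,ideal_ph,rep1,rep2,rep3,rep4,avg_abs_err,std_dev
A,buffer,1.68,1.5,1.5,1.5,1.5,0.18,0.00
A,buffer,4.01,4.1,4.1,4.2,4.2,0.14,0.05
A,buffer,7.00,7.2,7.2,7.2,7.2,0.20,0.00
A,buffer,10.01,9.9,9.9,9.9,9.9,0.11,0.00
A,buffer,12.46,12.5,12.5,12.4,12.4,0.05,0.05
B,buffer,1.68,1.5,1.5,1.5,1.5,0.18,0.00
B,buffer,4.01,4.1,4.1,4.2,4.4,0.19,0.12
B,buffer,7.00,6.9,7.0,6.9,7.0,0.05,0.05
B,buffer,10.01,9.8,9.8,9.9,9.9,0.16,0.05
B,buffer,12.46,12.6,12.5,12.5,12.0,0.17,0.23
C,buffer,1.68,1.6,1.6,1.6,1.5,0.11,0.04
C,buffer,4.01,4.3,4.3,4.1,4.2,0.22,0.08
C,buffer,7.00,7.2,7.2,7.3,7.3,0.25,0.05
C,buffer,10.01,10.0,9.8,9.7,9.8,0.19,0.11
C,buffer,12.46,12.3,12.3,12.3,12.2,0.19,0.04
A,BS,6.0,6.1,6.1,6.1,6.1,0.10,0.00
A,BS,6.5,6.6,6.6,6.6,6.6,0.10,0.00
A,PBS,7.4,8.4,8.4,8.4,8.4,1.00,0.00
B,BS,6.0,6.0,6.1,6.1,6.1,0.07,0.04
B,BS,6.5,6.5,6.5,6.4,6.3,0.08,0.08
B,PBS,7.4,8.2,8.3,8.2,8.3,0.85,0.05
C,BS,6.0,6.2,6.1,6.1,6.1,0.13,0.04
C,BS,6.5,6.7,6.6,6.7,6.7,0.18,0.04
C,PBS,7.4,8.5,8.4,8.5,8.5,1.08,0.04
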