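absorption_efficiency: 0.8
delay_time: 0.25
l_5_4: 20.0
l_6_5: 8.044880000000001
l_7_5: 0.92
l_8_5: 1.03512
l_5_6: 0.003632
l_5_7: 0.368
l_0_6: 0.00039044
dietary_intake: 2.27
dose: 1.81
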