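type: msa
sensor_open_A: 9000.0
sensor_open_Vhalf: -45.0
sensor_open_r: 22.0
sensor_close_A: 9000.0
sensor_close_Vhalf: -75.0
sensor_close_r: 22.0
open_rate: 6000.0
close_rate: 600.0
fast_on: 4.7
fast_off: 452.0
fast_allo: 3.43
slow_on: 0.0065
slow_off: 17.0
slow_allo: 2.77
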