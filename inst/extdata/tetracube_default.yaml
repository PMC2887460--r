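type: tetracube
act_open_A: 8346.658477026452601
fast_open_A: 485.937205165518833
slow_open_A: 16.967538034020063
act_close_A: 6154.660370894195694
fast_close_A: 1053.843635362369469
slow_close_A: 0.550007978268412
act_open_Vhalf: -41.720438555375367
fast_open_Vhalf: -73.053119951654949
slow_open_Vhalf: -67.080765161509262
act_close_Vhalf: -53.709681539474097
fast_close_Vhalf: -52.211545173122815
slow_close_Vhalf: -60.231175777989222
act_open_r: 11.533736487212645
fast_open_r: 18.067821452884463
slow_open_r: 12.753950134541666
act_close_r: 18.87554975837201
fast_close_r: 4.253654458796283
slow_close_r: 5.89741989078988
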