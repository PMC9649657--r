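{"seed":7,"placements":[{"quaternion":[1,0,0,0],"translation":[25.82238196,-9.64486894,9.13751492]},{"quaternion":[0.96592583,0,0,0.25881905],"translation":[21.80314408,5.35513106,31.13751492]},{"quaternion":[0.8660254,0,0,0.5],"translation":[10.82238196,16.33589317,53.13751492]},{"quaternion":[0.70710678,0,0,0.70710678],"translation":[-4.17761804,20.35513106,75.13751492]}],"n_restraints":180}
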