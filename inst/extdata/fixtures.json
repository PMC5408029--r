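[{"variable":"gamma_dot","stimulus":0.797,"seed":2026,"bank":{"range":[0.1,2.2],"n_peaks":15,"sd":0.1,"amplitude":50},"counts":[0,0,0,1,32,42,5,0,0,0,0,0,0,0,0],"mle_estimate":0.796},{"variable":"gamma_dot","stimulus":1.15,"seed":2027,"bank":{"range":[0.1,2.2],"n_peaks":15,"sd":0.1,"amplitude":50},"counts":[0,0,0,0,0,0,19,63,19,0,0,0,0,0,0],"mle_estimate":1.15},{"variable":"gamma","stimulus":0.1622,"seed":2028,"bank":{"range":[0,1],"n_peaks":11,"sd":0.1,"amplitude":50},"counts":[13,43,29,17,3,0,0,0,0,0,0],"mle_estimate":0.151},{"variable":"gamma","stimulus":0.5,"seed":2029,"bank":{"range":[0,1],"n_peaks":11,"sd":0.1,"amplitude":50},"counts":[0,0,0,7,29,49,32,10,0,0,0],"mle_estimate":0.507}]
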