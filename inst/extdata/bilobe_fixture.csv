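# Synthetic discretised bilobe response kernel (impulse representation).
# Qualitative shape of the measured wild-type E. coli impulse response:
# positive lobe peaking near 0.5 s, zero crossing near 1 s, shallow
# negative lobe extending to 3.5 s, total area close to (but not exactly)
# zero. Amplitudes are package units, not measured values.
lag_s,weight
0.25,0.0008287
0.5,0.001004
0.75,0.0001723
1,-1.056e-05
1.25,-3.921e-05
1.5,-8.567e-05
1.75,-0.0001573
2,-0.0002428
2.25,-0.000315
2.5,-0.0003436
2.75,-0.000315
3,-0.0002428
3.25,-0.0001573
3.5,-8.567e-05
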