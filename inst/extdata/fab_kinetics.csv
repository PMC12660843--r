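fab,ligand,KD_printed,ka,kd
hSC44,3-pTza,1.62e-09,5.06e+04,8.16e-05
hSC44.20,3-pTza,4.21e-10,2.45e+05,1.03e-04
hSC44.20.N32F,3-pTza,8.92e-10,1.99e+05,1.77e-04
hSC44.20.N32Y,3-pTza,8.30e-10,2.24e+05,1.86e-04
rSC44,3-pTza,6.68e-10,2.03e+05,1.35e-04
hSC44,3-pHis,4.05e-08,5.79e+04,2.35e-03
hSC44.20,3-pHis,1.75e-08,2.40e+05,4.20e-03
hSC44.20.N32F,3-pHis,6.63e-09,1.05e+05,6.97e-04
hSC44.20.N32Y,3-pHis,5.11e-09,1.29e+05,6.60e-04
rSC44,3-pHis,4.85e-08,1.22e+05,5.91e-03
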