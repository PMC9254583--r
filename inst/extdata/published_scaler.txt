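# min-max scaler ranges frozen from the 28-treatment experiment table
# columns: variable n_min n_max m_min m_max
naocl 0 1.26 -1 1
h2o2 0 12.25 -1 1
hgcl2 0 0.2 -1 1
time 5 30 -1 1
de 0 100 -1 1
nde 0 100 -1 1
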