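# Synthetic two-factor CFA oracle fixture.
# Covariance of simulated indicator data; oracle values estimated with
# the lava package (v1.8.1), ML, unit factor variances.
n 1000
p1 4
p2 4
oracle_phi 0.3705246839
oracle_chisq 11.74399894
oracle_df 19
oracle_cfi 1.00000000
oracle_tli 1.00541233
oracle_rmsea 0.00000000
oracle_srmr 0.01099065
0.97382014066207356 0.41805808255569021 0.45503450734311807 0.24059375795112484 0.17330092633284966 0.14150704246766854 0.16514923170495907 0.15211906913417167
0.41805808255569021 0.97930917385857019 0.5598617397154616 0.28810669282539897 0.19460428267655946 0.13880421656840602 0.20036310409012573 0.15792149557854274
0.45503450734311807 0.5598617397154616 0.99242803286572379 0.32856277147836233 0.21149167047982578 0.164954995028323 0.21461919586248851 0.22815605265139327
0.24059375795112484 0.28810669282539897 0.32856277147836233 0.92397150427050512 0.1203873608040876 0.080549011990852806 0.10830189196428924 0.11426117655356317
0.17330092633284966 0.19460428267655946 0.21149167047982578 0.1203873608040876 1.0263967235025373 0.45940025911273252 0.56640940578458454 0.46375767052806172
0.14150704246766854 0.13880421656840602 0.164954995028323 0.080549011990852806 0.45940025911273252 1.0246598176456239 0.4590269575605635 0.41540396430973608
0.16514923170495907 0.20036310409012573 0.21461919586248851 0.10830189196428924 0.56640940578458454 0.4590269575605635 1.0542157427234824 0.52121029532309915
0.15211906913417167 0.15792149557854274 0.22815605265139327 0.11426117655356317 0.46375767052806172 0.41540396430973608 0.52121029532309915 0.94931371283974464
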