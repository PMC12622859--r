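# Synthetic two-factor CFA oracle fixture.
# Covariance of simulated indicator data; oracle values estimated with
# the lava package (v1.8.1), ML, unit factor variances.
n 1000
p1 3
p2 5
oracle_phi -0.2853269406
oracle_chisq 33.69287240
oracle_df 19
oracle_cfi 0.98544242
oracle_tli 0.97854672
oracle_rmsea 0.02780844
oracle_srmr 0.02820190
0.95138730868878763 0.31750335682723951 0.18894031716400977 -0.10604357531796893 -0.15614581963987154 -0.1767627172105477 -0.0984075839174159 -0.11565845172648741
0.31750335682723951 1.0130428320359324 0.25338463281308998 -0.045205096614575065 -0.091731236762311597 -0.16054414953219379 -0.078306792944208975 -0.11963100154338036
0.18894031716400977 0.25338463281308998 0.99104129895030713 -0.2028453979200579 -0.09863634968675361 -0.20302079158021355 -0.10669022666132918 -0.1769089033915954
-0.10604357531796893 -0.045205096614575065 -0.2028453979200579 2.0776776776776775 0.54390390390390386 0.73853853853853857 0.50474474474474473 0.89417417417417422
-0.15614581963987154 -0.091731236762311597 -0.09863634968675361 0.54390390390390386 2.0432592592592593 0.62050050050050054 0.59283683683683686 0.74451251251251249
-0.1767627172105477 -0.16054414953219379 -0.20302079158021355 0.73853853853853857 0.62050050050050054 2.0064064064064064 0.5444644644644645 0.87311311311311313
-0.0984075839174159 -0.078306792944208975 -0.10669022666132918 0.50474474474474473 0.59283683683683686 0.5444644644644645 2.0503213213213214 0.62944144144144143
-0.11565845172648741 -0.11963100154338036 -0.1769089033915954 0.89417417417417422 0.74451251251251249 0.87311311311311313 0.62944144144144143 2.1181821821821822
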