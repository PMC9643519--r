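# Regional tissue material cards: reduced-polynomial hyperelasticity and
# linear elasticity, MPa. Columns C30e3..C60e3 are printed at 1000x their
# value (the loader divides by 1000). Empty cells are absent terms.
# "stiffness": average | stiff | compliant (5th/95th percentile shorthand).
region,stiffness,C10,C20,C30e3,C40e3,C50e3,C60e3,D1,E,nu
anterior_sclera,average,0.926,511,-42.6,2260,-59300,594000,0.044,,
equatorial_sclera,average,0.390,252,-11.2,219,,,0.104,,
posterior_sclera,average,0.633,144,-6.08,153,-1930,9550,0.064,,
posterior_sclera,stiff,1.056,179,-7.31,179,-2190,10300,0.038,,
posterior_sclera,compliant,0.069,46,-7.4,4.16,,,0.587,,
peripapillary_sclera,average,0.170,44,-1.43,27.59,-250,845,0.238,,
peripapillary_sclera,stiff,0.060,48,-0.412,1.95,-4300,3510,0.674,,
peripapillary_sclera,compliant,0.080,-0.539,0.00881,-0.0198,15100,,0.400,,
on_sheath,average,0.492,91,-1.78,16.3,,,0.083,,
on_sheath,stiff,0.221,2870,-11.5,280,-3310,14700,0.184,,
on_sheath,compliant,0.127,25,-0.446,2.92,,,0.318,,
lamina_cribrosa,average,0.281,16,-0.0445,0.05,,,0.072,,
on_connective,average,0.626,98,-3.48,70.2,-679,2490,0.065,,
on_connective,stiff,1.226,126,-1.78,8.92,,,0,,
on_connective,compliant,0.160,21.6,-0.311,1.81,,,0,,
on_neural,average,,,,,,,,0.001195,0.48
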