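# synthetic example per-domain hits (hmmsearch orientation)
# target            acc tlen query acc qlen   E      score bias # of  cE    iE    score bias hf ht af at ef et acc desc
p1 - 400 GH13 - 100 1e-06 50.0 0.0 1 1 1e-06 1e-06 50.0 0.0 1 50 10 59 10 59 0.95 -
p2 - 350 GH13 - 100 1e-05 40.0 0.0 1 1 1e-05 1e-05 40.0 0.0 1 40 5 44 5 44 0.95 -
p3 - 250 CBM50 - 200 1e-07 60.0 0.0 1 1 1e-07 1e-07 60.0 0.0 1 70 20 89 20 89 0.95 -
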