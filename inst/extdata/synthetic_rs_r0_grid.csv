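sensor,temp_c,rh_pct,rs_over_r0
2,0,20,1.356625
2,10,20,1.303431
2,20,20,1.252323
2,30,20,1.203218
2,40,20,1.15604
2,0,40,1.227525
2,10,40,1.179393
2,20,40,1.133148
2,30,40,1.088717
2,40,40,1.046028
2,0,65,1.083287
2,10,65,1.040811
2,20,65,1
2,30,65,0.960789
2,40,65,0.923116
2,0,85,0.980199
2,10,85,0.941765
2,20,85,0.904837
2,30,85,0.869358
2,40,85,0.83527
2,0,95,0.932394
2,10,95,0.895834
2,20,95,0.860708
2,30,95,0.826959
2,40,95,0.794534
3,0,20,1.616074
3,10,20,1.521962
3,20,20,1.433329
3,30,20,1.349859
3,40,20,1.271249
3,0,40,1.377128
3,10,40,1.29693
3,20,40,1.221403
3,30,40,1.150274
3,40,40,1.083287
3,0,65,1.127497
3,10,65,1.061837
3,20,65,1
3,30,65,0.941765
3,40,65,0.88692
3,0,85,0.960789
3,10,85,0.904837
3,20,85,0.852144
3,30,85,0.802519
3,40,85,0.755784
3,0,95,0.88692
3,10,95,0.83527
3,20,95,0.786628
3,30,95,0.740818
3,40,95,0.697676
4,0,20,1.514371
4,10,20,1.440514
4,20,20,1.370259
4,30,20,1.303431
4,40,20,1.239862
4,0,40,1.316531
4,10,40,1.252323
4,20,40,1.191246
4,30,40,1.133148
4,40,40,1.077884
4,0,65,1.105171
4,10,65,1.051271
4,20,65,1
4,30,65,0.951229
4,40,65,0.904837
4,0,85,0.960789
4,10,85,0.913931
4,20,85,0.869358
4,30,85,0.826959
4,40,85,0.786628
4,0,95,0.895834
4,10,95,0.852144
4,20,95,0.810584
4,30,95,0.771052
4,40,95,0.733447
5,0,20,1.433329
5,10,20,1.370259
5,20,20,1.309964
5,30,20,1.252323
5,40,20,1.197217
5,0,40,1.271249
5,10,40,1.215311
5,20,40,1.161834
5,30,40,1.110711
5,40,40,1.061837
5,0,65,1.094174
5,10,65,1.046028
5,20,65,1
5,30,65,0.955997
5,40,65,0.913931
5,0,85,0.970446
5,10,85,0.927743
5,20,85,0.88692
5,30,85,0.847894
5,40,85,0.810584
5,0,95,0.913931
5,10,95,0.873716
5,20,95,0.83527
5,30,95,0.798516
5,40,95,0.763379
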