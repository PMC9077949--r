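layer_index,energy_MeV,x_mm,y_mm,mu
1,165,-10,-5,0.318
1,165,-5,-5,1.068
1,165,0,-5,0.881
1,165,5,-5,0.294
1,165,10,-5,1.419
1,165,-10,0,1.418
1,165,-5,0,0.237
1,165,0,0,1.259
1,165,5,0,0.729
1,165,10,0,0.847
1,165,-10,5,0.851
1,165,-5,5,0.396
1,165,0,5,1.153
1,165,5,5,0.312
1,165,10,5,0.638
2,160,-10,-5,1.288
2,160,-5,-5,1.466
2,160,0,-5,0.377
2,160,5,-5,0.695
2,160,10,-5,0.159
2,160,-10,0,1.01
2,160,-5,0,0.612
2,160,0,0,1.263
2,160,5,0,0.268
2,160,10,0,0.554
2,160,-10,5,0.759
2,160,-5,5,0.266
2,160,0,5,0.568
2,160,5,5,1.446
2,160,10,5,0.242
3,155.5,-10,-5,0.065
3,155.5,-5,-5,0.289
3,155.5,0,-5,1.225
3,155.5,5,-5,1.31
3,155.5,10,-5,0.796
3,155.5,-10,0,0.959
3,155.5,-5,0,1.274
3,155.5,0,0,0.463
3,155.5,5,0,1.017
3,155.5,10,0,0.268
3,155.5,-10,5,1.474
3,155.5,-5,5,0.481
3,155.5,0,5,0.217
3,155.5,5,5,0.287
3,155.5,10,5,1.419
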