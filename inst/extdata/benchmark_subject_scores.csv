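# Per-subject segmentation scores of five models (IAANet, TriSegNet, U-Net,
# nnU-Net, MfNS_De) on a 20-subject Parkinson disease T2-weighted 3T cohort,
# as printed in the published benchmark table (3 decimals). Mean/Std rows are
# not stored; they are recomputed (Std = population convention, divisor N).
subject_id,model,DSC,SEN,PPV
1,IAANet,0.492,0.577,0.429
1,TriSegNet,0.643,0.689,0.603
1,U-Net,0.694,0.666,0.724
1,nnU-Net,0.722,0.802,0.656
1,MfNS_De,0.714,0.631,0.821
2,IAANet,0.51,0.661,0.415
2,TriSegNet,0.596,0.492,0.755
2,U-Net,0.72,0.673,0.774
2,nnU-Net,0.687,0.609,0.788
2,MfNS_De,0.737,0.755,0.717
3,IAANet,0.458,0.435,0.483
3,TriSegNet,0.533,0.843,0.39
3,U-Net,0.676,0.804,0.583
3,nnU-Net,0.678,0.838,0.57
3,MfNS_De,0.703,0.633,0.793
4,IAANet,0.431,0.519,0.369
4,TriSegNet,0.574,0.71,0.482
4,U-Net,0.64,0.617,0.664
4,nnU-Net,0.677,0.816,0.579
4,MfNS_De,0.685,0.63,0.717
5,IAANet,0.498,0.432,0.587
5,TriSegNet,0.662,0.669,0.654
5,U-Net,0.646,0.535,0.816
5,nnU-Net,0.652,0.522,0.869
5,MfNS_De,0.675,0.649,0.697
6,IAANet,0.412,0.445,0.383
6,TriSegNet,0.555,0.78,0.431
6,U-Net,0.642,0.627,0.658
6,nnU-Net,0.668,0.614,0.732
6,MfNS_De,0.718,0.786,0.665
7,IAANet,0.491,0.442,0.551
7,TriSegNet,0.611,0.58,0.645
7,U-Net,0.636,0.598,0.68
7,nnU-Net,0.63,0.548,0.741
7,MfNS_De,0.683,0.679,0.682
8,IAANet,0.409,0.431,0.389
8,TriSegNet,0.313,0.535,0.221
8,U-Net,0.629,0.645,0.613
8,nnU-Net,0.651,0.559,0.779
8,MfNS_De,0.671,0.651,0.701
9,IAANet,0.561,0.493,0.651
9,TriSegNet,0.647,0.544,0.797
9,U-Net,0.732,0.689,0.781
9,nnU-Net,0.753,0.693,0.824
9,MfNS_De,0.711,0.63,0.803
10,IAANet,0.617,0.729,0.535
10,TriSegNet,0.582,0.605,0.561
10,U-Net,0.649,0.662,0.637
10,nnU-Net,0.676,0.737,0.624
10,MfNS_De,0.703,0.75,0.74
11,IAANet,0.6,0.636,0.567
11,TriSegNet,0.5,0.376,0.745
11,U-Net,0.58,0.472,0.752
11,nnU-Net,0.63,0.527,0.785
11,MfNS_De,0.699,0.645,0.775
12,IAANet,0.581,0.613,0.552
12,TriSegNet,0.538,0.452,0.665
12,U-Net,0.581,0.488,0.719
12,nnU-Net,0.591,0.486,0.752
12,MfNS_De,0.675,0.634,0.735
13,IAANet,0.445,0.541,0.378
13,TriSegNet,0.598,0.622,0.575
13,U-Net,0.659,0.643,0.677
13,nnU-Net,0.69,0.667,0.714
13,MfNS_De,0.663,0.6,0.726
14,IAANet,0.374,0.46,0.315
14,TriSegNet,0.568,0.744,0.459
14,U-Net,0.649,0.709,0.597
14,nnU-Net,0.715,0.763,0.674
14,MfNS_De,0.687,0.659,0.726
15,IAANet,0.411,0.562,0.323
15,TriSegNet,0.576,0.563,0.589
15,U-Net,0.646,0.717,0.589
15,nnU-Net,0.667,0.717,0.624
15,MfNS_De,0.691,0.678,0.702
16,IAANet,0.474,0.621,0.383
16,TriSegNet,0.673,0.792,0.585
16,U-Net,0.7,0.744,0.661
16,nnU-Net,0.776,0.822,0.735
16,MfNS_De,0.745,0.706,0.77
17,IAANet,0.431,0.525,0.365
17,TriSegNet,0.681,0.655,0.709
17,U-Net,0.706,0.715,0.696
17,nnU-Net,0.733,0.716,0.75
17,MfNS_De,0.75,0.706,0.799
18,IAANet,0.425,0.542,0.35
18,TriSegNet,0.654,0.697,0.616
18,U-Net,0.665,0.723,0.616
18,nnU-Net,0.695,0.796,0.617
18,MfNS_De,0.702,0.675,0.733
19,IAANet,0.484,0.535,0.441
19,TriSegNet,0.674,0.696,0.654
19,U-Net,0.715,0.732,0.699
19,nnU-Net,0.71,0.643,0.792
19,MfNS_De,0.744,0.738,0.751
20,IAANet,0.439,0.551,0.365
20,TriSegNet,0.608,0.656,0.567
20,U-Net,0.649,0.742,0.576
20,nnU-Net,0.666,0.668,0.664
20,MfNS_De,0.686,0.618,0.769
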