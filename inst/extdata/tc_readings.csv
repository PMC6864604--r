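set_id,quantity_fg,reading_index,tc_ratio
set1,100000,1,0.764
set1,100000,2,0.782
set1,100000,3,0.772
set1,100000,4,0.758
set1,100000,5,0.762
set1,10000,1,0.672
set1,10000,2,0.618
set1,10000,3,0.502
set1,10000,4,0.536
set1,10000,5,0.596
set1,1000,1,0.434
set1,1000,2,0.404
set1,1000,3,0.394
set1,1000,4,0.452
set1,1000,5,0.38
set1,100,1,0.21
set1,100,2,0.234
set1,100,3,0.2
set1,100,4,0.18
set1,100,5,0.194
set1,10,1,0
set1,10,2,0
set1,10,3,0
set1,10,4,0
set1,10,5,0
set2,100000,1,0.806
set2,100000,2,0.807
set2,100000,3,0.82
set2,100000,4,0.85
set2,100000,5,0.836
set2,10000,1,0.634
set2,10000,2,0.622
set2,10000,3,0.674
set2,10000,4,0.67
set2,10000,5,0.668
set2,1000,1,0.456
set2,1000,2,0.456
set2,1000,3,0.438
set2,1000,4,0.472
set2,1000,5,0.426
set2,100,1,0.246
set2,100,2,0.242
set2,100,3,0.212
set2,100,4,0.226
set2,100,5,0.176
set2,10,1,0
set2,10,2,0
set2,10,3,0
set2,10,4,0
set2,10,5,0
set3,100000,1,0.796
set3,100000,2,0.828
set3,100000,3,0.882
set3,100000,4,0.64
set3,100000,5,0.798
set3,10000,1,0.634
set3,10000,2,0.61
set3,10000,3,0.608
set3,10000,4,0.722
set3,10000,5,0.64
set3,1000,1,0.426
set3,1000,2,0.5
set3,1000,3,0.496
set3,1000,4,0.416
set3,1000,5,0.476
set3,100,1,0.238
set3,100,2,0.204
set3,100,3,0.208
set3,100,4,0.194
set3,100,5,0.22
set3,10,1,0
set3,10,2,0
set3,10,3,0
set3,10,4,0
set3,10,5,0
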