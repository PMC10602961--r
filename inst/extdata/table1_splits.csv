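vessel_model,outlet,method,fraction,printed_deviation
1,O1,bc1,0.513,41
1,O1,bc2,0.401,25
1,O1,bc3,0.465,35
1,O1,bc4,0.345,13
1,O1,bc5,0.301,NA
1,O2,bc1,0.209,-9
1,O2,bc2,0.207,-10
1,O2,bc3,0.173,-31
1,O2,bc4,0.239,5
1,O2,bc5,0.227,NA
1,O3,bc1,0.002,-900
1,O3,bc2,0.016,-25
1,O3,bc3,0.004,-400
1,O3,bc4,0.019,-5
1,O3,bc5,0.020,NA
1,O4,bc1,0.011,-555
1,O4,bc2,0.054,-33
1,O4,bc3,0.023,-213
1,O4,bc4,0.069,-4
1,O4,bc5,0.072,NA
1,O5,bc1,0.265,-44
1,O5,bc2,0.322,-18
1,O5,bc3,0.335,-14
1,O5,bc4,0.033,-1055
1,O5,bc5,0.381,NA
2,O1,bc1,0.397,36
2,O1,bc2,0.295,14
2,O1,bc3,0.351,28
2,O1,bc4,0.255,0
2,O1,bc5,0.254,NA
2,O2,bc1,0.187,-1
2,O2,bc2,0.143,-31
2,O2,bc3,0.119,-58
2,O2,bc4,0.218,14
2,O2,bc5,0.188,NA
2,O3,bc1,0.011,-1009
2,O3,bc2,0.030,-307
2,O3,bc3,0.011,-1009
2,O3,bc4,0.139,12
2,O3,bc5,0.122,NA
2,O4,bc1,0.086,59
2,O4,bc2,0.095,63
2,O4,bc3,0.064,45
2,O4,bc4,0.026,-35
2,O4,bc5,0.035,NA
2,O5,bc1,0.138,-56
2,O5,bc2,0.181,-19
2,O5,bc3,0.170,-26
2,O5,bc4,0.194,-11
2,O5,bc5,0.215,NA
2,O6,bc1,0.180,-3
2,O6,bc2,0.256,27
2,O6,bc3,0.284,35
2,O6,bc4,0.167,-11
2,O6,bc5,0.186,NA
3,O1,bc1,0.164,-62
3,O1,bc2,0.236,-13
3,O1,bc3,0.181,-47
3,O1,bc4,0.274,3
3,O1,bc5,0.266,NA
3,O2,bc1,0.098,-82
3,O2,bc2,0.182,2
3,O2,bc3,0.123,-45
3,O2,bc4,0.190,6
3,O2,bc5,0.178,NA
3,O3,bc1,0.738,25
3,O3,bc2,0.581,4
3,O3,bc3,0.697,20
3,O3,bc4,0.536,-4
3,O3,bc5,0.555,NA
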