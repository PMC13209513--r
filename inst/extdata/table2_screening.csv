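id,dg_mean,dg_sd,10,1
8012-2471,-25.87,1.74,100,18.2
6484-0008,-30.16,2.38,97.3,50.7
C200-4020,-37.36,1.79,87.9,44.9
5223-1356,-31.71,2.55,84.5,34.9
8020-2441,-25.55,2.61,80.9,32.2
D245-0568,-36.67,2.18,72.4,19.3
6484-0032,-30.64,2.40,70.2,54.0
3389-0956,-20.12,2.67,59.4,22.9
F279-0419,-33.51,1.98,57.5,13.3
L397-0566,-38.55,2.67,55.5,30.4
P300-1479,-37.54,2.86,54.0,2.9
G652-4613,-30.05,2.79,48.5,40.9
D116-0357,-41.28,2.74,44.8,22.0
8020-7630,-23.68,2.56,38.3,4.3
M652-0610,-28.56,2.46,35.7,16.9
C200-7927,-43.20,2.64,35.5,21.0
J108-0587,-31.52,2.45,33.1,18.2
D245-0478,-35.58,3.35,22.6,n.d.
C276-1683,-13.80,1.68,22.1,n.d.
G761-2889,-36.15,2.53,18.4,0
8018-0728,-29.58,2.17,12.8,0
G373-3180,-21.59,2.19,11.1,n.d.
M652-0525,-30.51,2.48,10.5,9.8
J006-1371,-36.31,2.68,3.2,0
8020-0186,-28.15,2.03,2.6,2.2
D679-0170,-32.93,2.46,0.4,0
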