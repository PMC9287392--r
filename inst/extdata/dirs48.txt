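0.8446523198 -0.3051030483 -0.4398574639
-0.2066573232 0.3343888664 -0.919498144
0.6596069763 0.4904433532 0.5695471483
0.2936790318 -0.6310756319 0.7179806217
-0.0114701356 0.8556288518 0.5174627561
0.0175483434 0.3020172583 0.9531409294
0.6791622645 -0.0766328939 -0.7299767243
-0.0771848061 -0.0535844114 0.9955758216
0.8805370878 0.3860180887 -0.2750354016
-0.3674048361 0.7580268312 0.5388961029
0.4521723573 -0.8681570933 -0.2045566439
0.9656673482 -0.1464691675 0.2145538524
-0.9752323882 -0.2176554788 -0.039343126
-0.6974389198 0.6305093679 0.3406418796
-0.3102739182 0.9408490953 -0.1361362391
0.2598860977 0.9380616168 0.2291279541
-0.3724914802 -0.7407987093 -0.5589878079
-0.8162894233 0.4895209206 -0.3066607992
-0.653559175 -0.1447938942 -0.7428964484
0.6228683182 0.6663165811 -0.4099478892
-0.1228095084 0.8841245335 -0.4508232846
-0.448980046 -0.1849217733 0.8741972638
-0.0989721769 -0.625195773 -0.7741671354
0.8121662893 -0.1721337328 0.5574548381
0.6987085755 0.3381141228 -0.6304642468
-0.3933271444 -0.4058568829 -0.8249690589
-0.2839701374 -0.8506146608 0.4425106326
-0.612964715 0.4917646557 -0.6184187753
0.4551355912 0.8844876813 -0.1026310633
-0.5017432807 0.7662691196 -0.4013543529
0.1051610281 -0.9764403595 -0.1884287201
0.3654999376 -0.191670772 -0.9108633876
0.1481050363 0.402876471 -0.9031918109
-0.9843877799 0.0912973548 0.1504841909
0.5311427883 -0.2036112257 0.8224535289
-0.8848170961 -0.1714618484 -0.4332430506
-0.7540274862 -0.6535243912 0.0659425522
-0.5871507158 0.4477489468 0.6743700154
-0.8859271618 -0.0734765636 0.4579675301
-0.3015213559 -0.0555981784 -0.951837021
0.0890105919 0.9861343641 -0.1400575972
-0.2522938899 0.5381813916 0.8041819339
0.4215647678 0.5704124438 -0.7049204143
-0.8403884491 -0.4841187123 -0.2436725818
-0.8924449458 0.4466391035 0.0636830435
0.0617451211 0.6998790311 -0.7115875784
-0.5880541679 -0.765735785 -0.2604630553
0.6726461156 -0.7373005974 0.0627298347
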