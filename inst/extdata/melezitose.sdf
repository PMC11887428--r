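melezitose
     RDKit          3D
generated in silico from connectivity; force-field refined 3D coordinates
 66 68  0  0  0  0  0  0  0  0999 V2000
   -7.3547    0.6506    0.9201 O   0  0  0  0  0  0  0  0  0  0  0  0
   -6.0145    0.8837    1.3463 C   0  0  0  0  0  0  0  0  0  0  0  0
   -5.0145    0.0152    0.5666 C   0  0  1  0  0  0  0  0  0  0  0  0
   -3.7105    0.2933    1.0916 O   0  0  0  0  0  0  0  0  0  0  0  0
   -2.6729   -0.4220    0.4178 C   0  0  2  0  0  0  0  0  0  0  0  0
   -2.6610   -0.0956   -0.9645 O   0  0  0  0  0  0  0  0  0  0  0  0
   -1.4092    0.2228   -1.5716 C   0  0  2  0  0  0  0  0  0  0  0  0
   -1.7214    0.5102   -3.0661 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.2515   -0.6496   -3.7243 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.5424   -0.9315   -1.5570 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.7641   -0.5189   -1.0757 C   0  0  2  0  0  0  0  0  0  0  0  0
    1.3426   -1.6964   -0.2839 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.5896   -1.9405    0.9024 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.5558    0.7616   -0.2612 C   0  0  1  0  0  0  0  0  0  0  0  0
    1.6183    1.7161   -0.2836 O   0  0  0  0  0  0  0  0  0  0  0  0
    2.8159    1.3153    0.3841 C   0  0  1  0  0  0  0  0  0  0  0  0
    3.5898    0.5012   -0.5018 O   0  0  0  0  0  0  0  0  0  0  0  0
    4.9980    0.4560   -0.2235 C   0  0  2  0  0  0  0  0  0  0  0  0
    5.4987   -0.9346   -0.6419 C   0  0  0  0  0  0  0  0  0  0  0  0
    6.8917   -1.0850   -0.3847 O   0  0  0  0  0  0  0  0  0  0  0  0
    5.3269    0.7785    1.2447 C   0  0  1  0  0  0  0  0  0  0  0  0
    6.7189    0.6999    1.5689 O   0  0  0  0  0  0  0  0  0  0  0  0
    4.8629    2.2065    1.5718 C   0  0  2  0  0  0  0  0  0  0  0  0
    4.6860    2.3173    2.9910 O   0  0  0  0  0  0  0  0  0  0  0  0
    3.5667    2.5857    0.8473 C   0  0  1  0  0  0  0  0  0  0  0  0
    3.8955    3.4114   -0.2881 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6208    1.4115   -0.9859 C   0  0  2  0  0  0  0  0  0  0  0  0
   -1.3631    2.2738   -0.1302 O   0  0  0  0  0  0  0  0  0  0  0  0
   -2.8870   -1.9347    0.6137 C   0  0  2  0  0  0  0  0  0  0  0  0
   -1.8654   -2.7201   -0.0331 O   0  0  0  0  0  0  0  0  0  0  0  0
   -4.2591   -2.3598    0.0837 C   0  0  1  0  0  0  0  0  0  0  0  0
   -4.4693   -3.7381    0.4471 O   0  0  0  0  0  0  0  0  0  0  0  0
   -5.3778   -1.4818    0.6638 C   0  0  2  0  0  0  0  0  0  0  0  0
   -6.5987   -1.7522   -0.0398 O   0  0  0  0  0  0  0  0  0  0  0  0
   -7.9098    1.3073    1.3794 H   0  0  0  0  0  0  0  0  0  0  0  0
   -5.9481    0.6772    2.4204 H   0  0  0  0  0  0  0  0  0  0  0  0
   -5.7771    1.9440    1.2036 H   0  0  0  0  0  0  0  0  0  0  0  0
   -5.0685    0.3283   -0.4848 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7360   -0.1433    0.8997 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8133    0.7848   -3.6132 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.4587    1.3128   -3.1666 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7217   -1.4041   -3.4099 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.3911   -0.3293   -1.9549 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.3225   -2.6124   -0.8846 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.3737   -1.5207    0.0209 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.2224   -2.4220    0.6269 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.2925    0.5682    0.7838 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.5543    0.7197    1.2683 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.5018    1.1904   -0.8654 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.9578   -1.7172   -0.0985 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.3146   -1.0924   -1.7105 H   0  0  0  0  0  0  0  0  0  0  0  0
    7.1620   -1.9285   -0.7944 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.8156    0.0653    1.9035 H   0  0  0  0  0  0  0  0  0  0  0  0
    7.1053   -0.0076    1.0055 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.6547    2.9216    1.3144 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.5382    2.0345    3.3804 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.9047    3.1825    1.4858 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.1450    4.2853    0.0609 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.2313    2.0453   -1.7936 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.7357    2.9432    0.2009 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.8320   -2.1754    1.6824 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7785   -2.3428   -0.9354 H   0  0  0  0  0  0  0  0  0  0  0  0
   -4.2821   -2.3335   -1.0126 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.6747   -4.2175    0.1476 H   0  0  0  0  0  0  0  0  0  0  0  0
   -5.5398   -1.7649    1.7114 H   0  0  0  0  0  0  0  0  0  0  0  0
   -7.2312   -1.0488    0.2207 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  1  0
  3  4  1  0
  4  5  1  0
  5  6  1  0
  7  6  1  1
  7  8  1  0
  8  9  1  0
  7 10  1  0
 10 11  1  0
 11 12  1  0
 12 13  1  0
 11 14  1  0
 14 15  1  0
 15 16  1  0
 16 17  1  0
 17 18  1  0
 18 19  1  0
 19 20  1  0
 18 21  1  0
 21 22  1  0
 21 23  1  0
 23 24  1  0
 23 25  1  0
 25 26  1  0
 14 27  1  0
 27 28  1  0
  5 29  1  0
 29 30  1  0
 29 31  1  0
 31 32  1  0
 31 33  1  0
 33 34  1  0
 33  3  1  0
 27  7  1  0
 25 16  1  0
  1 35  1  0
  2 36  1  0
  2 37  1  0
  3 38  1  6
  5 39  1  1
  8 40  1  0
  8 41  1  0
  9 42  1  0
 11 43  1  6
 12 44  1  0
 12 45  1  0
 13 46  1  0
 14 47  1  1
 16 48  1  1
 18 49  1  6
 19 50  1  0
 19 51  1  0
 20 52  1  0
 21 53  1  1
 22 54  1  0
 23 55  1  6
 24 56  1  0
 25 57  1  1
 26 58  1  0
 27 59  1  6
 28 60  1  0
 29 61  1  1
 30 62  1  0
 31 63  1  6
 32 64  1  0
 33 65  1  1
 34 66  1  0
M  END
$$$$
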