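beta_d_glucose
     RDKit          3D
generated in silico from connectivity; force-field refined 3D coordinates
 24 24  0  0  0  0  0  0  0  0999 V2000
    3.1746    1.0582   -0.5644 O   0  0  0  0  0  0  0  0  0  0  0  0
    2.3624   -0.1139   -0.4625 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.1319    0.1981    0.3978 C   0  0  1  0  0  0  0  0  0  0  0  0
    0.4115    1.2436   -0.2896 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.9599    1.2915    0.0628 C   0  0  1  0  0  0  0  0  0  0  0  0
   -1.5241    2.4365   -0.5639 O   0  0  0  0  0  0  0  0  0  0  0  0
   -1.7140    0.0250   -0.4174 C   0  0  2  0  0  0  0  0  0  0  0  0
   -2.8725   -0.1967    0.4118 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8185   -1.2312   -0.3788 C   0  0  1  0  0  0  0  0  0  0  0  0
   -0.2298   -1.5121   -1.6496 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.2826   -1.0629    0.6729 C   0  0  2  0  0  0  0  0  0  0  0  0
   -0.3635   -0.9332    1.9557 O   0  0  0  0  0  0  0  0  0  0  0  0
    2.5731    1.7566   -0.8904 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.0894   -0.4058   -1.4803 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.9709   -0.9052   -0.0152 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.4681    0.6365    1.3460 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0696    1.4369    1.1444 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1378    3.1975   -0.1020 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.0921    0.1825   -1.4340 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.5385   -0.4103    1.3055 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.4304   -2.1023   -0.1130 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.9582   -1.5981   -2.2923 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.9166   -1.9556    0.7195 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.3277   -1.0359    2.6370 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  1  0
  3  4  1  0
  4  5  1  0
  5  6  1  0
  5  7  1  0
  7  8  1  0
  7  9  1  0
  9 10  1  0
  9 11  1  0
 11 12  1  0
 11  3  1  0
  1 13  1  0
  2 14  1  0
  2 15  1  0
  3 16  1  1
  5 17  1  1
  6 18  1  0
  7 19  1  6
  8 20  1  0
  9 21  1  1
 10 22  1  0
 11 23  1  1
 12 24  1  0
M  END
$$$$
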