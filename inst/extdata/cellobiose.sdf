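cellobiose
     RDKit          3D
generated in silico from connectivity; force-field refined 3D coordinates
 45 46  0  0  0  0  0  0  0  0999 V2000
    4.3213    2.6825   -0.7717 O   0  0  0  0  0  0  0  0  0  0  0  0
    3.2357    1.9390   -1.3104 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.5439    1.0838   -0.2407 C   0  0  1  0  0  0  0  0  0  0  0  0
    1.3487    0.5307   -0.8316 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.8384   -0.5463   -0.0510 C   0  0  1  0  0  0  0  0  0  0  0  0
   -0.4498   -0.9007   -0.5530 O   0  0  0  0  0  0  0  0  0  0  0  0
   -1.5269   -0.1573    0.0347 C   0  0  1  0  0  0  0  0  0  0  0  0
   -2.1028    0.8052   -1.0018 C   0  0  2  0  0  0  0  0  0  0  0  0
   -1.1127    1.7305   -1.4828 O   0  0  0  0  0  0  0  0  0  0  0  0
   -3.2500    1.6131   -0.3886 C   0  0  1  0  0  0  0  0  0  0  0  0
   -4.0764    2.1033   -1.4599 O   0  0  0  0  0  0  0  0  0  0  0  0
   -4.0729    0.7739    0.6125 C   0  0  2  0  0  0  0  0  0  0  0  0
   -3.6654    1.0552    1.9458 O   0  0  0  0  0  0  0  0  0  0  0  0
   -3.9651   -0.6256    0.3874 O   0  0  0  0  0  0  0  0  0  0  0  0
   -2.6315   -1.1551    0.4457 C   0  0  2  0  0  0  0  0  0  0  0  0
   -2.3570   -1.7762    1.8267 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1106   -2.4736    1.8604 O   0  0  0  0  0  0  0  0  0  0  0  0
    1.7430   -1.7878   -0.2094 C   0  0  2  0  0  0  0  0  0  0  0  0
    1.5432   -2.6802    0.9006 O   0  0  0  0  0  0  0  0  0  0  0  0
    3.2251   -1.3767   -0.3171 C   0  0  1  0  0  0  0  0  0  0  0  0
    3.6527   -1.3465   -1.6853 O   0  0  0  0  0  0  0  0  0  0  0  0
    3.4822   -0.0071    0.3403 C   0  0  2  0  0  0  0  0  0  0  0  0
    3.2213   -0.1017    1.7523 O   0  0  0  0  0  0  0  0  0  0  0  0
    3.9506    3.3492   -0.1669 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.5239    2.6393   -1.7623 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.6163    1.3164   -2.1260 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.2254    1.7512    0.5710 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.7597   -0.2663    1.0076 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1815    0.4171    0.9040 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.4404    0.2518   -1.8871 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.2866    1.2132   -1.5938 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.8640    2.5074    0.1161 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.4627    2.5554   -2.0715 H   0  0  0  0  0  0  0  0  0  0  0  0
   -5.1321    1.0410    0.5231 H   0  0  0  0  0  0  0  0  0  0  0  0
   -4.4669    0.9426    2.4859 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.6158   -1.9866   -0.2717 H   0  0  0  0  0  0  0  0  0  0  0  0
   -3.1566   -2.4813    2.0802 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.3402   -1.0115    2.6090 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0580   -2.8873    2.7430 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.4548   -2.3499   -1.1062 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.5694   -2.7472    1.0265 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.8420   -2.1320    0.1838 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.9407   -0.9526   -2.2217 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.5313    0.2877    0.2322 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.7568   -0.8398    2.0990 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  1  0
  3  4  1  0
  4  5  1  0
  5  6  1  0
  6  7  1  0
  7  8  1  0
  8  9  1  0
  8 10  1  0
 10 11  1  0
 10 12  1  0
 12 13  1  0
 12 14  1  0
 14 15  1  0
 15 16  1  0
 16 17  1  0
  5 18  1  0
 18 19  1  0
 18 20  1  0
 20 21  1  0
 20 22  1  0
 22 23  1  0
 22  3  1  0
 15  7  1  0
  1 24  1  0
  2 25  1  0
  2 26  1  0
  3 27  1  1
  5 28  1  1
  7 29  1  1
  8 30  1  6
  9 31  1  0
 10 32  1  1
 11 33  1  0
 12 34  1  1
 13 35  1  0
 15 36  1  6
 16 37  1  0
 16 38  1  0
 17 39  1  0
 18 40  1  6
 19 41  1  0
 20 42  1  1
 21 43  1  0
 22 44  1  1
 23 45  1  0
M  END
$$$$
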