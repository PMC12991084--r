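ATOM      1  P     A A   1       9.200   0.000   0.000  1.00  0.00           P  
ATOM      2  OP1   A A   1       9.600   0.800   0.600  1.00  0.00           O  
ATOM      3  OP2   A A   1       9.500  -0.900  -0.600  1.00  0.00           O  
ATOM      4  C1'   A A   1       7.400   0.600   0.300  1.00  0.00           C  
ATOM      5  N9    A A   1       5.600   0.600   0.300  1.00  0.00           N  
ATOM      6  C8    A A   1       4.900   1.500   0.400  1.00  0.00           C  
ATOM      7  N7    A A   1       4.100   1.400   0.500  1.00  0.00           N  
ATOM      8  C5    A A   1       3.500   0.700   0.400  1.00  0.00           C  
ATOM      9  N1    A A   1       2.500   0.900   0.300  1.00  0.00           N  
ATOM     10  P     A A   2       7.802   4.875   2.600  1.00  0.00           P  
ATOM     11  OP1   A A   2       7.717   5.766   3.200  1.00  0.00           O  
ATOM     12  OP2   A A   2       8.533   4.271   2.000  1.00  0.00           O  
ATOM     13  C1'   A A   2       5.958   4.430   2.900  1.00  0.00           C  
ATOM     14  N9    A A   2       4.431   3.476   2.900  1.00  0.00           N  
ATOM     15  C8    A A   2       3.361   3.869   3.000  1.00  0.00           C  
ATOM     16  N7    A A   2       2.735   3.360   3.100  1.00  0.00           N  
ATOM     17  C5    A A   2       2.597   2.448   3.000  1.00  0.00           C  
ATOM     18  N1    A A   2       1.643   2.088   2.900  1.00  0.00           N  
ATOM     19  P     A A   3       4.033   8.269   5.200  1.00  0.00           P  
ATOM     20  OP1   A A   3       3.489   8.979   5.800  1.00  0.00           O  
ATOM     21  OP2   A A   3       4.973   8.144   4.600  1.00  0.00           O  
ATOM     22  C1'   A A   3       2.705   6.914   5.500  1.00  0.00           C  
ATOM     23  N9    A A   3       1.916   5.296   5.500  1.00  0.00           N  
ATOM     24  C8    A A   3       0.800   5.062   5.600  1.00  0.00           C  
ATOM     25  N7    A A   3       0.539   4.299   5.700  1.00  0.00           N  
ATOM     26  C5    A A   3       0.905   3.453   5.600  1.00  0.00           C  
ATOM     27  N1    A A   3       0.287   2.642   5.500  1.00  0.00           N  
ATOM     28  P     A A   4      -0.962   9.150   7.800  1.00  0.00           P  
ATOM     29  OP1   A A   4      -1.799   9.464   8.400  1.00  0.00           O  
ATOM     30  OP2   A A   4      -0.098   9.542   7.200  1.00  0.00           O  
ATOM     31  C1'   A A   4      -1.370   7.297   8.100  1.00  0.00           C  
ATOM     32  N9    A A   4      -1.182   5.507   8.100  1.00  0.00           N  
ATOM     33  C8    A A   4      -2.004   4.716   8.200  1.00  0.00           C  
ATOM     34  N7    A A   4      -1.821   3.931   8.300  1.00  0.00           N  
ATOM     35  C5    A A   4      -1.062   3.408   8.200  1.00  0.00           C  
ATOM     36  N1    A A   4      -1.156   2.392   8.100  1.00  0.00           N  
ATOM     37  P     C A   5      -5.664   7.250  10.400  1.00  0.00           P  
ATOM     38  OP1   C A   5      -6.541   7.072  11.000  1.00  0.00           O  
ATOM     39  OP2   C A   5      -5.140   8.040   9.800  1.00  0.00           O  
ATOM     40  C1'   C A   5      -5.029   5.462  10.700  1.00  0.00           C  
ATOM     41  N1    C A   5      -3.921   4.043  10.700  1.00  0.00           N  
ATOM     42  C2    C A   5      -3.918   2.903  10.800  1.00  0.00           C  
ATOM     43  O2    C A   5      -2.647   3.388  10.800  1.00  0.00           O  
ATOM     44  N3    C A   5      -3.022   2.081  10.700  1.00  0.00           N  
ATOM     45  P     U A   6      -8.645   3.147  13.000  1.00  0.00           P  
ATOM     46  OP1   U A   6      -9.295   2.532  13.600  1.00  0.00           O  
ATOM     47  OP2   U A   6      -8.619   4.095  12.400  1.00  0.00           O  
ATOM     48  C1'   U A   6      -7.159   1.967  13.300  1.00  0.00           C  
ATOM     49  N1    U A   6      -5.467   1.351  13.300  1.00  0.00           N  
ATOM     50  C2    U A   6      -4.861   0.386  13.400  1.00  0.00           C  
ATOM     51  O2    U A   6      -3.913   1.530  13.400  1.00  0.00           O  
ATOM     52  N3    U A   6      -3.665   0.163  13.500  1.00  0.00           N  
ATOM     53  P     C A   7      -8.999  -1.913  15.600  1.00  0.00           P  
ATOM     54  OP1   C A   7      -9.224  -2.778  16.200  1.00  0.00           O  
ATOM     55  OP2   C A   7      -9.480  -1.095  15.000  1.00  0.00           O  
ATOM     56  C1'   C A   7      -7.114  -2.125  15.900  1.00  0.00           C  
ATOM     57  N1    C A   7      -5.353  -1.751  15.900  1.00  0.00           N  
ATOM     58  C2    C A   7      -4.327  -2.249  16.000  1.00  0.00           C  
ATOM     59  O2    C A   7      -4.206  -0.894  16.000  1.00  0.00           O  
ATOM     60  N3    C A   7      -3.195  -1.804  15.900  1.00  0.00           N  
ATOM     61  P     C A   8      -6.618  -6.391  18.200  1.00  0.00           P  
ATOM     62  OP1   C A   8      -6.350  -7.244  18.800  1.00  0.00           O  
ATOM     63  OP2   C A   8      -7.459  -5.952  17.600  1.00  0.00           O  
ATOM     64  C1'   C A   8      -4.906  -5.572  18.500  1.00  0.00           C  
ATOM     65  N1    C A   8      -3.612  -4.322  18.500  1.00  0.00           N  
ATOM     66  C2    C A   8      -2.478  -4.200  18.600  1.00  0.00           C  
ATOM     67  O2    C A   8      -3.093  -2.987  18.600  1.00  0.00           O  
ATOM     68  N3    C A   8      -1.754  -3.223  18.500  1.00  0.00           N  
ATOM     69  N   ALA B   1      -6.636  12.526   4.000  1.00  0.00           N  
ATOM     70  CA  ALA B   1      -5.432  13.444   4.000  1.00  0.00           C  
ATOM     71  C   ALA B   1      -3.835  13.550   4.000  1.00  0.00           C  
ATOM     72  O   ALA B   1      -3.071  12.672   4.000  1.00  0.00           O  
ATOM     73  CB  ALA B   1      -5.055  11.978   4.000  1.00  0.00           C  
ATOM     74  N   LEU B   2      -6.636  12.526   7.400  1.00  0.00           N  
ATOM     75  CA  LEU B   2      -5.432  13.444   7.400  1.00  0.00           C  
ATOM     76  C   LEU B   2      -3.835  13.550   7.400  1.00  0.00           C  
ATOM     77  O   LEU B   2      -3.071  12.672   7.400  1.00  0.00           O  
ATOM     78  CB  LEU B   2      -5.055  11.978   7.400  1.00  0.00           C  
ATOM     79  CG  LEU B   2      -4.716  10.605   7.400  1.00  0.00           C  
ATOM     80  CD1 LEU B   2      -4.415   9.325   7.400  1.00  0.00           C  
ATOM     81  N   ALA B   3      -6.636  12.526  10.800  1.00  0.00           N  
ATOM     82  CA  ALA B   3      -5.432  13.444  10.800  1.00  0.00           C  
ATOM     83  C   ALA B   3      -3.835  13.550  10.800  1.00  0.00           C  
ATOM     84  O   ALA B   3      -3.071  12.672  10.800  1.00  0.00           O  
ATOM     85  CB  ALA B   3      -5.055  11.978  10.800  1.00  0.00           C  
ATOM     86  N   LYS B   4      -6.636  12.526  14.200  1.00  0.00           N  
ATOM     87  CA  LYS B   4      -5.432  13.444  14.200  1.00  0.00           C  
ATOM     88  C   LYS B   4      -3.835  13.550  14.200  1.00  0.00           C  
ATOM     89  O   LYS B   4      -3.071  12.672  14.200  1.00  0.00           O  
ATOM     90  CB  LYS B   4      -5.055  11.978  14.200  1.00  0.00           C  
ATOM     91  CG  LYS B   4      -4.716  10.605  14.200  1.00  0.00           C  
ATOM     92  NZ  LYS B   4      -4.302   9.047  14.200  1.00  0.00           N  
END   
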