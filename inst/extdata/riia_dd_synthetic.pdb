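REMARK SYNTHETIC stand-in for an RII-type D/D reference dimer.
CRYST1   45.000   45.000   60.000  90.00  90.00  90.00 P 1
ATOM      1  CA  GLY A   1       2.300   0.000   0.000  1.00 20.00           C
ATOM      2  CA  GLN A   2      -0.399   2.265   1.500  1.00 20.00           C
ATOM      3  CA  LEU A   3      -2.162  -0.785   3.000  1.00 20.00           C
ATOM      4  CA  LEU A   4       1.148  -1.993   4.500  1.00 20.00           C
ATOM      5  CA  ARG A   5       1.764   1.476   6.000  1.00 20.00           C
ATOM      6  CA  GLU A   6      -1.759   1.481   7.500  1.00 20.00           C
ATOM      7  CA  LEU A   7      -1.154  -1.990   9.000  1.00 20.00           C
ATOM      8  CA  VAL A   8       2.159  -0.792  10.500  1.00 20.00           C
ATOM      9  CA  ASN A   9       0.405   2.264  12.000  1.00 20.00           C
ATOM     10  CA  GLU A  10      -2.300   0.007  13.500  1.00 20.00           C
ATOM     11  CA  ILE A  11       0.392  -2.266  15.000  1.00 20.00           C
ATOM     12  CA  ALA A  12       2.164   0.779  16.500  1.00 20.00           C
ATOM     13  CA  PRO A  13       2.300   0.000  17.700  1.00 20.00           C
ATOM     14  CA  ALA A  14       3.800   1.683  17.148  1.00 20.00           C
ATOM     15  CA  SER A  15       5.300   1.819  16.001  1.00 20.00           C
ATOM     16  CA  LEU A  16       6.800   0.282  15.312  1.00 20.00           C
ATOM     17  CA  GLU A  17       8.300  -1.514  15.716  1.00 20.00           C
ATOM     18  CA  ALA A  18       8.043   2.091  16.500  1.00 20.00           C
ATOM     19  CA  VAL A  19       7.106  -1.305  15.000  1.00 20.00           C
ATOM     20  CA  GLU A  20      10.614  -1.639  13.500  1.00 20.00           C
ATOM     21  CA  TYR A  21      10.334   1.873  12.000  1.00 20.00           C
ATOM     22  CA  PHE A  22       6.924   0.990  10.500  1.00 20.00           C
ATOM     23  CA  LYS A  23       8.385  -2.216   9.000  1.00 20.00           C
ATOM     24  CA  ARG A  24      11.289  -0.221   7.500  1.00 20.00           C
ATOM     25  CA  LEU A  25       8.821   2.293   6.000  1.00 20.00           C
ATOM     26  CA  LEU A  26       6.773  -0.574   4.500  1.00 20.00           C
ATOM     27  CA  HIS A  27       9.951  -2.094   3.000  1.00 20.00           C
ATOM     28  CA  GLU A  28      10.898   1.300   1.500  1.00 20.00           C
ATOM     29  CA  ALA A  29       7.391   1.644   0.000  1.00 20.00           C
ATOM     30  CA  ALA A  30       7.660  -1.869  -1.500  1.00 20.00           C
ATOM     31  CA  THR A  31      11.000   0.000  -2.000  1.00 20.00           C
ATOM     32  CA  ALA A  32      14.040   1.933  -2.240  1.00 20.00           C
ATOM     33  CA  TYR A  33      17.080   2.956  -2.480  1.00 20.00           C
ATOM     34  CA  SER A  34      20.120   2.590  -2.720  1.00 20.00           C
ATOM     35  CA  THR A  35      23.160   1.005  -2.960  1.00 20.00           C
ATOM     36  CA  ASP A  36      26.200  -1.052  -3.200  1.00 20.00           C
ATOM     37  CA  GLU A  37      29.240  -2.615  -3.440  1.00 20.00           C
ATOM     38  CA  ARG A  38      32.280  -2.947  -3.680  1.00 20.00           C
ATOM     39  CA  LEU A  39      35.320  -1.894  -3.920  1.00 20.00           C
ATOM     40  CA  GLU A  40      38.360   0.050  -4.160  1.00 20.00           C
ATOM     41  CA  TRP A  41      41.400   1.971  -4.400  1.00 20.00           C
ATOM     42  CA  ALA A  42      44.440   2.965  -4.640  1.00 20.00           C
ATOM     43  CA  MET A  43      47.480   2.564  -4.880  1.00 20.00           C
ATOM     44  CA  SER A  44      50.520   0.957  -5.120  1.00 20.00           C
TER
ATOM    101  CA  GLY B   1       6.800   0.500  16.000  1.00 20.00           C
ATOM    102  CA  GLN B   2       4.101  -1.765  14.500  1.00 20.00           C
ATOM    103  CA  LEU B   3       2.338   1.285  13.000  1.00 20.00           C
ATOM    104  CA  LEU B   4       5.648   2.493  11.500  1.00 20.00           C
ATOM    105  CA  ARG B   5       6.264  -0.976  10.000  1.00 20.00           C
ATOM    106  CA  GLU B   6       2.741  -0.981   8.500  1.00 20.00           C
ATOM    107  CA  LEU B   7       3.346   2.490   7.000  1.00 20.00           C
ATOM    108  CA  VAL B   8       6.659   1.292   5.500  1.00 20.00           C
ATOM    109  CA  ASN B   9       4.905  -1.764   4.000  1.00 20.00           C
ATOM    110  CA  GLU B  10       2.200   0.493   2.500  1.00 20.00           C
ATOM    111  CA  ILE B  11       4.892   2.766   1.000  1.00 20.00           C
ATOM    112  CA  ALA B  12       6.664  -0.279  -0.500  1.00 20.00           C
ATOM    113  CA  PRO B  13       6.800   0.500  -1.700  1.00 20.00           C
ATOM    114  CA  ALA B  14       8.300  -1.183  -1.148  1.00 20.00           C
ATOM    115  CA  SER B  15       9.800  -1.319  -0.001  1.00 20.00           C
ATOM    116  CA  LEU B  16      11.300   0.218   0.688  1.00 20.00           C
ATOM    117  CA  GLU B  17      12.800   2.014   0.284  1.00 20.00           C
ATOM    118  CA  ALA B  18      12.543  -1.591  -0.500  1.00 20.00           C
ATOM    119  CA  VAL B  19      11.606   1.805   1.000  1.00 20.00           C
ATOM    120  CA  GLU B  20      15.114   2.139   2.500  1.00 20.00           C
ATOM    121  CA  TYR B  21      14.834  -1.373   4.000  1.00 20.00           C
ATOM    122  CA  PHE B  22      11.424  -0.490   5.500  1.00 20.00           C
ATOM    123  CA  LYS B  23      12.885   2.716   7.000  1.00 20.00           C
ATOM    124  CA  ARG B  24      15.789   0.721   8.500  1.00 20.00           C
ATOM    125  CA  LEU B  25      13.321  -1.793  10.000  1.00 20.00           C
ATOM    126  CA  LEU B  26      11.273   1.074  11.500  1.00 20.00           C
ATOM    127  CA  HIS B  27      14.451   2.594  13.000  1.00 20.00           C
ATOM    128  CA  GLU B  28      15.398  -0.800  14.500  1.00 20.00           C
ATOM    129  CA  ALA B  29      11.891  -1.144  16.000  1.00 20.00           C
ATOM    130  CA  ALA B  30      12.160   2.369  17.500  1.00 20.00           C
ATOM    131  CA  THR B  31      15.500   0.500  18.000  1.00 20.00           C
ATOM    132  CA  ALA B  32      18.540  -1.433  18.240  1.00 20.00           C
ATOM    133  CA  TYR B  33      21.580  -2.456  18.480  1.00 20.00           C
ATOM    134  CA  SER B  34      24.620  -2.090  18.720  1.00 20.00           C
ATOM    135  CA  THR B  35      27.660  -0.505  18.960  1.00 20.00           C
ATOM    136  CA  ASP B  36      30.700   1.552  19.200  1.00 20.00           C
ATOM    137  CA  GLU B  37      33.740   3.115  19.440  1.00 20.00           C
ATOM    138  CA  ARG B  38      36.780   3.447  19.680  1.00 20.00           C
ATOM    139  CA  LEU B  39      39.820   2.394  19.920  1.00 20.00           C
ATOM    140  CA  GLU B  40      42.860   0.450  20.160  1.00 20.00           C
ATOM    141  CA  TRP B  41      45.900  -1.471  20.400  1.00 20.00           C
ATOM    142  CA  ALA B  42      48.940  -2.465  20.640  1.00 20.00           C
ATOM    143  CA  MET B  43      51.980  -2.064  20.880  1.00 20.00           C
ATOM    144  CA  SER B  44      55.020  -0.457  21.120  1.00 20.00           C
TER
END
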