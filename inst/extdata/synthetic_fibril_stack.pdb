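ATOM      1  CA  ALA A   1       0.000   0.877   0.000  1.00  0.00              
ATOM      2  CA  ALA A   2       3.371  -0.877   0.000  1.00  0.00              
ATOM      3  CA  ALA A   3       6.741   0.877   0.000  1.00  0.00              
ATOM      4  CA  ALA A   4      10.112  -0.877   0.000  1.00  0.00              
ATOM      5  CA  ALA A   5      13.483   0.877   0.000  1.00  0.00              
ATOM      6  CA  ALA A   6      16.853  -0.877   0.000  1.00  0.00              
ATOM      7  CA  ALA A   7      20.224   0.877   0.000  1.00  0.00              
ATOM      8  CA  ALA A   8      23.594  -0.877   0.000  1.00  0.00              
ATOM      9  CA  ALA A   9      26.965   0.877   0.000  1.00  0.00              
ATOM     10  CA  ALA A  10      30.336  -0.877   0.000  1.00  0.00              
ATOM     11  CA  ALA A  11      33.706   0.877   0.000  1.00  0.00              
ATOM     12  CA  ALA A  12      37.077  -0.877   0.000  1.00  0.00              
ATOM     13  CA  ALA A  13      40.448   0.877   0.000  1.00  0.00              
ATOM     14  CA  ALA A  14      43.818  -0.877   0.000  1.00  0.00              
ATOM     15  CA  ALA A  15      47.189   0.877   0.000  1.00  0.00              
ATOM     16  CA  ALA A  16      50.560  -0.877   0.000  1.00  0.00              
ATOM     17  CA  ALA A  17      53.930   0.877   0.000  1.00  0.00              
ATOM     18  CA  ALA A  18      57.301  -0.877   0.000  1.00  0.00              
ATOM     19  CA  ALA A  19      60.672   0.877   0.000  1.00  0.00              
ATOM     20  CA  ALA A  20      64.042  -0.877   0.000  1.00  0.00              
ATOM     21  CA  ALA A  21      67.413   0.877   0.000  1.00  0.00              
ATOM     22  CA  ALA A  22      70.783  -0.877   0.000  1.00  0.00              
ATOM     23  CA  ALA A  23      74.154   0.877   0.000  1.00  0.00              
ATOM     24  CA  ALA A  24      77.525  -0.877   0.000  1.00  0.00              
ATOM     25  CA  ALA A  25      80.895   0.877   0.000  1.00  0.00              
ATOM     26  CA  ALA A  26      84.266  -0.877   0.000  1.00  0.00              
ATOM     27  CA  ALA A  27      87.637   0.877   0.000  1.00  0.00              
ATOM     28  CA  ALA A  28      91.007  -0.877   0.000  1.00  0.00              
ATOM     29  CA  ALA A  29      94.378   0.877   0.000  1.00  0.00              
ATOM     30  CA  ALA A  30      97.749  -0.877   0.000  1.00  0.00              
ATOM     31  CA  ALA B   1       0.000   0.877   4.800  1.00  0.00              
ATOM     32  CA  ALA B   2       3.371  -0.877   4.800  1.00  0.00              
ATOM     33  CA  ALA B   3       6.741   0.877   4.800  1.00  0.00              
ATOM     34  CA  ALA B   4      10.112  -0.877   4.800  1.00  0.00              
ATOM     35  CA  ALA B   5      13.483   0.877   4.800  1.00  0.00              
ATOM     36  CA  ALA B   6      16.853  -0.877   4.800  1.00  0.00              
ATOM     37  CA  ALA B   7      20.224   0.877   4.800  1.00  0.00              
ATOM     38  CA  ALA B   8      23.594  -0.877   4.800  1.00  0.00              
ATOM     39  CA  ALA B   9      26.965   0.877   4.800  1.00  0.00              
ATOM     40  CA  ALA B  10      30.336  -0.877   4.800  1.00  0.00              
ATOM     41  CA  ALA B  11      33.706   0.877   4.800  1.00  0.00              
ATOM     42  CA  ALA B  12      37.077  -0.877   4.800  1.00  0.00              
ATOM     43  CA  ALA B  13      40.448   0.877   4.800  1.00  0.00              
ATOM     44  CA  ALA B  14      43.818  -0.877   4.800  1.00  0.00              
ATOM     45  CA  ALA B  15      47.189   0.877   4.800  1.00  0.00              
ATOM     46  CA  ALA B  16      50.560  -0.877   4.800  1.00  0.00              
ATOM     47  CA  ALA B  17      53.930   0.877   4.800  1.00  0.00              
ATOM     48  CA  ALA B  18      57.301  -0.877   4.800  1.00  0.00              
ATOM     49  CA  ALA B  19      60.672   0.877   4.800  1.00  0.00              
ATOM     50  CA  ALA B  20      64.042  -0.877   4.800  1.00  0.00              
ATOM     51  CA  ALA B  21      67.413   0.877   4.800  1.00  0.00              
ATOM     52  CA  ALA B  22      70.783  -0.877   4.800  1.00  0.00              
ATOM     53  CA  ALA B  23      74.154   0.877   4.800  1.00  0.00              
ATOM     54  CA  ALA B  24      77.525  -0.877   4.800  1.00  0.00              
ATOM     55  CA  ALA B  25      80.895   0.877   4.800  1.00  0.00              
ATOM     56  CA  ALA B  26      84.266  -0.877   4.800  1.00  0.00              
ATOM     57  CA  ALA B  27      87.637   0.877   4.800  1.00  0.00              
ATOM     58  CA  ALA B  28      91.007  -0.877   4.800  1.00  0.00              
ATOM     59  CA  ALA B  29      94.378   0.877   4.800  1.00  0.00              
ATOM     60  CA  ALA B  30      97.749  -0.877   4.800  1.00  0.00              
ATOM     61  CA  ALA C   1       0.000   0.877   9.600  1.00  0.00              
ATOM     62  CA  ALA C   2       3.371  -0.877   9.600  1.00  0.00              
ATOM     63  CA  ALA C   3       6.741   0.877   9.600  1.00  0.00              
ATOM     64  CA  ALA C   4      10.112  -0.877   9.600  1.00  0.00              
ATOM     65  CA  ALA C   5      13.483   0.877   9.600  1.00  0.00              
ATOM     66  CA  ALA C   6      16.853  -0.877   9.600  1.00  0.00              
ATOM     67  CA  ALA C   7      20.224   0.877   9.600  1.00  0.00              
ATOM     68  CA  ALA C   8      23.594  -0.877   9.600  1.00  0.00              
ATOM     69  CA  ALA C   9      26.965   0.877   9.600  1.00  0.00              
ATOM     70  CA  ALA C  10      30.336  -0.877   9.600  1.00  0.00              
ATOM     71  CA  ALA C  11      33.706   0.877   9.600  1.00  0.00              
ATOM     72  CA  ALA C  12      37.077  -0.877   9.600  1.00  0.00              
ATOM     73  CA  ALA C  13      40.448   0.877   9.600  1.00  0.00              
ATOM     74  CA  ALA C  14      43.818  -0.877   9.600  1.00  0.00              
ATOM     75  CA  ALA C  15      47.189   0.877   9.600  1.00  0.00              
ATOM     76  CA  ALA C  16      50.560  -0.877   9.600  1.00  0.00              
ATOM     77  CA  ALA C  17      53.930   0.877   9.600  1.00  0.00              
ATOM     78  CA  ALA C  18      57.301  -0.877   9.600  1.00  0.00              
ATOM     79  CA  ALA C  19      60.672   0.877   9.600  1.00  0.00              
ATOM     80  CA  ALA C  20      64.042  -0.877   9.600  1.00  0.00              
ATOM     81  CA  ALA C  21      67.413   0.877   9.600  1.00  0.00              
ATOM     82  CA  ALA C  22      70.783  -0.877   9.600  1.00  0.00              
ATOM     83  CA  ALA C  23      74.154   0.877   9.600  1.00  0.00              
ATOM     84  CA  ALA C  24      77.525  -0.877   9.600  1.00  0.00              
ATOM     85  CA  ALA C  25      80.895   0.877   9.600  1.00  0.00              
ATOM     86  CA  ALA C  26      84.266  -0.877   9.600  1.00  0.00              
ATOM     87  CA  ALA C  27      87.637   0.877   9.600  1.00  0.00              
ATOM     88  CA  ALA C  28      91.007  -0.877   9.600  1.00  0.00              
ATOM     89  CA  ALA C  29      94.378   0.877   9.600  1.00  0.00              
ATOM     90  CA  ALA C  30      97.749  -0.877   9.600  1.00  0.00              
END
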