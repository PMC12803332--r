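ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N
ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C
ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C
ATOM      4  N   ALA A   2       1.468   2.268  -0.869  1.00  0.00           N
ATOM      5  CA  ALA A   2       1.908   3.655  -0.968  1.00  0.00           C
ATOM      6  C   ALA A   2       1.777   4.370   0.371  1.00  0.00           C
ATOM      7  N   ALA A   3       0.629   4.212   1.020  1.00  0.00           N
ATOM      8  CA  ALA A   3       0.380   4.844   2.310  1.00  0.00           C
ATOM      9  C   ALA A   3       1.436   4.445   3.332  1.00  0.00           C
ATOM     10  N   ALA A   4       1.727   3.151   3.412  1.00  0.00           N
ATOM     11  CA  ALA A   4       2.721   2.641   4.350  1.00  0.00           C
ATOM     12  C   ALA A   4       4.073   3.308   4.137  1.00  0.00           C
ATOM     13  N   ALA A   5       4.505   3.388   2.883  1.00  0.00           N
ATOM     14  CA  ALA A   5       5.784   4.003   2.546  1.00  0.00           C
ATOM     15  C   ALA A   5       5.854   5.439   3.050  1.00  0.00           C
ATOM     16  N   ALA A   6       4.800   6.210   2.798  1.00  0.00           N
ATOM     17  CA  ALA A   6       4.744   7.602   3.227  1.00  0.00           C
ATOM     18  C   ALA A   6       4.934   7.722   4.734  1.00  0.00           C
ATOM     19  N   ALA A   7       4.221   6.894   5.491  1.00  0.00           N
ATOM     20  CA  ALA A   7       4.313   6.910   6.946  1.00  0.00           C
ATOM     21  C   ALA A   7       5.746   6.688   7.410  1.00  0.00           C
ATOM     22  N   ALA A   8       6.409   5.688   6.837  1.00  0.00           N
ATOM     23  CA  ALA A   8       7.787   5.373   7.194  1.00  0.00           C
ATOM     24  C   ALA A   8       8.697   6.578   6.994  1.00  0.00           C
ATOM     25  N   ALA A   9       8.573   7.232   5.844  1.00  0.00           N
ATOM     26  CA  ALA A   9       9.386   8.401   5.531  1.00  0.00           C
ATOM     27  C   ALA A   9       9.222   9.485   6.588  1.00  0.00           C
ATOM     28  N   ALA A  10       7.978   9.775   6.955  1.00  0.00           N
ATOM     29  CA  ALA A  10       7.688  10.793   7.958  1.00  0.00           C
ATOM     30  C   ALA A  10       8.396  10.489   9.272  1.00  0.00           C
ATOM     31  N   ALA A  11       8.302   9.243   9.724  1.00  0.00           N
ATOM     32  CA  ALA A  11       8.935   8.826  10.970  1.00  0.00           C
ATOM     33  C   ALA A  11      10.033   7.803  10.714  1.00  0.00           C
ATOM     34  N   ALA A  12      10.485   7.714   9.467  1.00  0.00           N
ATOM     35  CA  ALA A  12      11.535   6.774   9.093  1.00  0.00           C
ATOM     36  C   ALA A  12      12.351   7.298   7.919  1.00  0.00           C
ATOM     37  N   ALA A  13      13.616   7.618   8.169  1.00  0.00           N
ATOM     38  CA  ALA A  13      14.501   8.131   7.130  1.00  0.00           C
ATOM     39  C   ALA A  13      14.811   7.060   6.093  1.00  0.00           C
ATOM     40  N   ALA A  14      14.100   5.939   6.165  1.00  0.00           N
ATOM     41  CA  ALA A  14      14.300   4.838   5.229  1.00  0.00           C
ATOM     42  C   ALA A  14      13.426   5.000   3.993  1.00  0.00           C
TER
END

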