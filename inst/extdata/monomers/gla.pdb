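TITLE     idealized GLA monosaccharide template v1 (synthetic)
REMARK    local frame: chain axis +z, anomeric C1 at origin
ATOM      1  C1  GLA     1      0.000   0.000   0.000  1.00  0.00           C
ATOM      2  C2  GLA     1      1.316   0.000   0.760  1.00  0.00           C
ATOM      3  C3  GLA     1      1.316   0.000   2.280  1.00  0.00           C
ATOM      4  C4  GLA     1      0.000   0.000   3.040  1.00  0.00           C
ATOM      5  C5  GLA     1     -1.316   0.000   2.280  1.00  0.00           C
ATOM      6  O5  GLA     1     -1.316   0.000   0.760  1.00  0.00           O
ATOM      7  O1  GLA     1      0.000   0.000  -1.430  1.00  0.00           O
ATOM      8  HO1 GLA     1      0.000   0.780  -1.990  1.00  0.00           H
ATOM      9  O2  GLA     1      1.316   1.430   0.760  1.00  0.00           O
ATOM     10  HO2 GLA     1      1.316   2.200   1.330  1.00  0.00           H
ATOM     11  O3  GLA     1      1.316  -1.430   2.280  1.00  0.00           O
ATOM     12  HO3 GLA     1      1.316  -2.200   2.850  1.00  0.00           H
ATOM     13  O4  GLA     1      0.000   0.000   4.470  1.00  0.00           O
ATOM     14  HO4 GLA     1      0.000   0.780   5.030  1.00  0.00           H
ATOM     15  H1  GLA     1      0.000   1.070  -0.200  1.00  0.00           H
ATOM     16  H2  GLA     1      1.316  -1.090   0.760  1.00  0.00           H
ATOM     17  H3  GLA     1      1.316   1.090   2.280  1.00  0.00           H
ATOM     18  H4  GLA     1      0.000   1.090   3.040  1.00  0.00           H
ATOM     19  H5  GLA     1     -1.316  -1.090   2.280  1.00  0.00           H
ATOM     20  C6  GLA     1     -2.576   0.000   3.130  1.00  0.00           C
ATOM     21  O6A GLA     1     -3.176   1.020   3.530  1.00  0.00           O
ATOM     22  O6B GLA     1     -3.176  -1.020   3.530  1.00  0.00           O
END
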