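TITLE     idealized GAL monosaccharide template v1 (synthetic)
REMARK    local frame: chain axis +z, anomeric C1 at origin
ATOM      1  C1  GAL     1      0.000   0.000   0.000  1.00  0.00           C
ATOM      2  C2  GAL     1      1.316   0.000   0.760  1.00  0.00           C
ATOM      3  C3  GAL     1      1.316   0.000   2.280  1.00  0.00           C
ATOM      4  C4  GAL     1      0.000   0.000   3.040  1.00  0.00           C
ATOM      5  C5  GAL     1     -1.316   0.000   2.280  1.00  0.00           C
ATOM      6  O5  GAL     1     -1.316   0.000   0.760  1.00  0.00           O
ATOM      7  O1  GAL     1      0.000   0.000  -1.430  1.00  0.00           O
ATOM      8  HO1 GAL     1      0.000   0.780  -1.990  1.00  0.00           H
ATOM      9  O2  GAL     1      1.316   1.430   0.760  1.00  0.00           O
ATOM     10  HO2 GAL     1      1.316   2.200   1.330  1.00  0.00           H
ATOM     11  O3  GAL     1      1.316  -1.430   2.280  1.00  0.00           O
ATOM     12  HO3 GAL     1      1.316  -2.200   2.850  1.00  0.00           H
ATOM     13  O4  GAL     1      0.000   0.000   4.470  1.00  0.00           O
ATOM     14  HO4 GAL     1      0.000   0.780   5.030  1.00  0.00           H
ATOM     15  H1  GAL     1      0.000   1.070  -0.200  1.00  0.00           H
ATOM     16  H2  GAL     1      1.316  -1.090   0.760  1.00  0.00           H
ATOM     17  H3  GAL     1      1.316   1.090   2.280  1.00  0.00           H
ATOM     18  H4  GAL     1      0.000   1.090   3.040  1.00  0.00           H
ATOM     19  H5  GAL     1     -1.316  -1.090   2.280  1.00  0.00           H
ATOM     20  C6  GAL     1     -2.576   0.000   3.130  1.00  0.00           C
ATOM     21  H61 GAL     1     -2.576   1.000   3.570  1.00  0.00           H
ATOM     22  H62 GAL     1     -2.576  -1.000   3.570  1.00  0.00           H
ATOM     23  O6  GAL     1     -3.436   0.000   4.270  1.00  0.00           O
ATOM     24  HO6 GAL     1     -4.216   0.000   4.830  1.00  0.00           H
END
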