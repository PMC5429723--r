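TITLE     idealized ARA monosaccharide template v1 (synthetic)
REMARK    local frame: chain axis +z, anomeric C1 at origin
ATOM      1  C1  ARA     1      0.000   0.000   0.000  1.00  0.00           C
ATOM      2  C2  ARA     1      1.230   0.000   0.893  1.00  0.00           C
ATOM      3  C3  ARA     1      0.760   0.000   2.339  1.00  0.00           C
ATOM      4  C4  ARA     1     -0.760   0.000   2.339  1.00  0.00           C
ATOM      5  O4  ARA     1     -1.230   0.000   0.893  1.00  0.00           O
ATOM      6  O1  ARA     1      0.000   0.000  -1.430  1.00  0.00           O
ATOM      7  HO1 ARA     1      0.000   0.780  -1.990  1.00  0.00           H
ATOM      8  O2  ARA     1      1.230   1.430   0.893  1.00  0.00           O
ATOM      9  HO2 ARA     1      1.230   2.200   1.463  1.00  0.00           H
ATOM     10  O3  ARA     1      0.760  -1.430   2.339  1.00  0.00           O
ATOM     11  HO3 ARA     1      0.760  -2.200   2.909  1.00  0.00           H
ATOM     12  C5  ARA     1     -0.760   0.000   3.859  1.00  0.00           C
ATOM     13  O5  ARA     1     -0.760   0.000   5.289  1.00  0.00           O
ATOM     14  HO5 ARA     1     -0.760   0.780   5.849  1.00  0.00           H
ATOM     15  H1  ARA     1      0.000   1.070  -0.200  1.00  0.00           H
ATOM     16  H2  ARA     1      1.230  -1.090   0.893  1.00  0.00           H
ATOM     17  H3  ARA     1      0.760   1.090   2.339  1.00  0.00           H
ATOM     18  H4  ARA     1     -0.760   1.090   2.339  1.00  0.00           H
ATOM     19  H51 ARA     1      0.190   0.000   4.399  1.00  0.00           H
ATOM     20  H52 ARA     1     -1.710   0.000   4.399  1.00  0.00           H
END
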