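ATOM      1  CA  ALA A   1      11.000  12.000  13.000  1.00 10.00           C
ATOM      2  CA AARG A   2      12.000  13.000  14.000  1.00 10.00           C
ATOM      3  CA BARG A   2      12.500  13.500  14.500  1.00 10.00           C
ATOM      4  CA  ASN A   3      13.000  14.000  15.000  1.00 10.00           C
ATOM      5  CA  ASP A   4      14.000  15.000  16.000  1.00 10.00           C
ATOM      6  CA  CYS A   5      15.000  16.000  17.000  1.00 10.00           C
END
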