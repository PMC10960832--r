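HEADER    SYNTHETIC INTERFACE FIXTURE
TITLE     SYNTHETIC ARG67-ASP1550 SALT BRIDGE MODEL
REMARK    SYNTHETIC COORDINATES - NOT DEPOSITED DATA
ATOM      1  N   ASP A1550      10.000  10.000  10.000  1.00 20.00           N
ATOM      2  CA  ASP A1550      11.458  10.000  10.000  1.00 20.00           C
ATOM      3  C   ASP A1550      12.100  11.300  10.400  1.00 20.00           C
ATOM      4  O   ASP A1550      11.600  12.300  10.900  1.00 20.00           O
ATOM      5  CB  ASP A1550      12.000   8.700   9.500  1.00 20.00           C
ATOM      6  CG  ASP A1550      13.400   8.500   9.900  1.00 20.00           C
ATOM      7  OD1 ASP A1550      14.100   9.400  10.300  1.00 20.00           O
ATOM      8  OD2 ASP A1550      13.900   7.350   9.800  1.00 20.00           O
ATOM      9  N   SER A1554       8.000  14.000  10.000  1.00 20.00           N
ATOM     10  CA  SER A1554       9.200  14.600  10.300  1.00 20.00           C
ATOM     11  CB  SER A1554       9.300  16.100  10.200  1.00 20.00           C
ATOM     12  OG  SER A1554      10.500  16.600  10.600  1.00 20.00           O
ATOM     13  C   SER A1554       9.500  14.100  11.700  1.00 20.00           C
ATOM     14  O   SER A1554       9.000  14.500  12.800  1.00 20.00           O
ATOM     15  N   ARG B  67      23.000   6.000  11.500  1.00 20.00           N
ATOM     16  CA  ARG B  67      23.100   7.000  10.500  1.00 20.00           C
ATOM     17  C   ARG B  67      24.550   7.300  10.300  1.00 20.00           C
ATOM     18  O   ARG B  67      25.300   6.400   9.900  1.00 20.00           O
ATOM     19  CB  ARG B  67      22.400   8.300  10.900  1.00 20.00           C
ATOM     20  CG  ARG B  67      21.000   8.200  10.500  1.00 20.00           C
ATOM     21  CD  ARG B  67      20.300   9.500  10.900  1.00 20.00           C
ATOM     22  NE  ARG B  67      18.900   9.300  10.800  1.00 20.00           N
ATOM     23  CZ  ARG B  67      17.900  10.100  10.700  1.00 20.00           C
ATOM     24  NH1 ARG B  67      16.900   9.400  10.300  1.00 20.00           N
ATOM     25  NH2 ARG B  67      18.000  11.400  10.900  1.00 20.00           N
HETATM   26  O   HOH A2001      13.200  16.600  10.600  1.00 20.00           O
END
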