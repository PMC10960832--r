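HEADER    SYNTHETIC INTERFACE FIXTURE
TITLE     SYNTHETIC GLU14-TYR1502/TYR1500 H-BOND MODEL
REMARK    SYNTHETIC COORDINATES - NOT DEPOSITED DATA
ATOM      1  N   TYR A1500       9.550   8.950   5.400  1.00 20.00           N
ATOM      2  CA  TYR A1500      10.750   9.750   5.600  1.00 20.00           C
ATOM      3  C   TYR A1500      12.000   8.950   5.300  1.00 20.00           C
ATOM      4  O   TYR A1500      13.100   9.450   5.400  1.00 20.00           O
ATOM      5  CB  TYR A1500      10.800  11.000   4.750  1.00 20.00           C
ATOM      6  N   TYR A1502      -0.400   8.500   5.600  1.00 20.00           N
ATOM      7  CA  TYR A1502       0.400   9.200   6.600  1.00 20.00           C
ATOM      8  C   TYR A1502      -0.300  10.500   6.900  1.00 20.00           C
ATOM      9  O   TYR A1502      -1.300  10.500   7.600  1.00 20.00           O
ATOM     10  CB  TYR A1502       1.800   9.500   6.100  1.00 20.00           C
ATOM     11  CG  TYR A1502       2.700   8.350   5.800  1.00 20.00           C
ATOM     12  CD1 TYR A1502       4.000   8.450   5.400  1.00 20.00           C
ATOM     13  CD2 TYR A1502       2.150   7.100   5.900  1.00 20.00           C
ATOM     14  CE1 TYR A1502       4.800   7.350   5.200  1.00 20.00           C
ATOM     15  CE2 TYR A1502       2.950   6.000   5.600  1.00 20.00           C
ATOM     16  CZ  TYR A1502       4.300   6.100   5.300  1.00 20.00           C
ATOM     17  OH  TYR A1502       5.000   5.000   5.000  1.00 20.00           O
ATOM     18  N   GLU B  14       6.300   9.700   6.200  1.00 20.00           N
ATOM     19  CA  GLU B  14       7.400   9.800   5.300  1.00 20.00           C
ATOM     20  C   GLU B  14       8.200  11.100   5.400  1.00 20.00           C
ATOM     21  O   GLU B  14       7.700  12.200   5.200  1.00 20.00           O
ATOM     22  CB  GLU B  14       8.300   8.600   5.500  1.00 20.00           C
ATOM     23  CG  GLU B  14       7.600   7.300   5.200  1.00 20.00           C
ATOM     24  CD  GLU B  14       8.300   6.050   5.300  1.00 20.00           C
ATOM     25  OE1 GLU B  14       9.550   6.050   5.400  1.00 20.00           O
ATOM     26  OE2 GLU B  14       7.600   5.000   5.000  1.00 20.00           O
END
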