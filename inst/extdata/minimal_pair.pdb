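HEADER    SYNTHETIC INTERFACE FIXTURE
TITLE     MINIMAL TWO-ATOM FIXTURE
REMARK    SYNTHETIC COORDINATES - NOT DEPOSITED DATA
ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00 20.00           C
ATOM      2  CA  GLY A   2       3.000   4.000   0.000  1.00 20.00           C
END
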