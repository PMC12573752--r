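6
Lattice="7.5000000000 0.0000000000 0.0000000000 0.0000000000 7.5000000000 0.0000000000 0.0000000000 0.0000000000 7.5000000000" Properties=species:S:1:pos:R:3:fragment:I:1:role:S:1
O        2.3000000000       3.7500000000       3.7500000000      1 QM
H        3.2572000000       3.7500000000       3.7500000000      1 QM
H        2.0600127916       3.7500000000       4.6766272065      1 QM
O        5.2000000000       3.7500000000       3.7500000000      2 MM
H        4.9159908603       3.7500000000       2.8359044642      2 MM
H        6.1561056763       3.7500000000       3.7042422066      2 MM
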