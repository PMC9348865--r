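# synthetic example reflectivity curve (generated, not measured)
# columns: Q (1/A)  R  dR  dQ (FWHM, 1/A)
0.0112 0.98213 0.01120 0.000224
0.0158 0.34159 0.00415 0.000316
0.0223 0.08217 0.00131 0.000446
0.0316 0.019438 0.000419 0.000632
0.0446 0.0043912 0.000130 0.000892
0.0631 0.00094729 0.0000401 0.001262
0.0891 0.00018101 0.0000117 0.001782
0.1258 0.000031870 0.00000322 0.002516
0.1778 0.0000062229 0.00000101 0.003556
0.2512 0.0000013771 0.00000034 0.005024
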