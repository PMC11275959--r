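# Synthetic DEG list: the 18 published common candidate-interval DEG IDs plus synthetic filler IDs (SYN_ prefix).
LOC_Os08g38460
LOC_Os08g38710
LOC_Os08g38720
LOC_Os08g39420
LOC_Os08g39430
LOC_Os08g39600
LOC_Os08g39694
LOC_Os08g39850
LOC_Os08g40580
LOC_Os08g40610
LOC_Os08g40850
LOC_Os08g40900
LOC_Os08g40910
LOC_Os08g41730
LOC_Os08g41820
LOC_Os08g41890
LOC_Os08g41990
LOC_Os08g42020
SYN_Os08gB0001
SYN_Os08gB0002
SYN_Os08gB0003
SYN_Os08gB0004
SYN_Os08gB0005
SYN_Os08gB0006
SYN_Os08gB0007
SYN_Os08gB0008
SYN_Os08gB0009
SYN_Os08gB0010
SYN_Os08gB0011
SYN_Os08gB0012
SYN_Os08gB0013
SYN_Os08gB0014
SYN_Os08gB0015
SYN_Os08gB0016
SYN_Os08gB0017
SYN_Os08gB0018
SYN_Os08gB0019
SYN_Os08gB0020
SYN_Os08gB0021
SYN_Os08gB0022
SYN_Os08gB0023
SYN_Os08gB0024
SYN_Os08gB0025
SYN_Os08gB0026
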