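>SYN0001.1 AP1
A [  4   2  90   2   2   2  90   5   4  80  30 ]
C [  3   2   3  60   4  90   2  20  70   8   5 ]
G [  3  90   4  30   4   2   4   5   6   6  60 ]
T [ 90   6   3   8  90   6   4  70  20   6   5 ]
>SYN0002.1 SPI1
A [ 80  80   5  80   5   5  85  85   5   5 ]
C [  8   8   5   8   5   5   5   5   5   5 ]
G [  6   6  85   6  85  85   5   5  85   8 ]
T [  6   6   5   6   5   5   5   5   5  82 ]
>SYN0003.1 SP1
A [  5   5   5   5   3   5   5   5   5   8 ]
C [  8   8   8   8  88   8   8   8   8  80 ]
G [ 82  82  82  82   6  82  82  82  82   7 ]
T [  5   5   5   5   3   5   5   5   5   5 ]
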