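>EX0001.1 gc_box_like
A [  2  1  0  0  1  3 ]
C [ 10  2 18  1 16  9 ]
G [  5 16  1 18  2  6 ]
T [  3  1  1  1  1  2 ]
>EX0002.1 tata_like
A [ 16  1 18 17  2 16 ]
C [  1  1  0  1  2  1 ]
G [  1  0  1  1  1  2 ]
T [  2 18  1  1 15  1 ]
>EX0003.1 palindrome
A [ 12  0  0  0  0  0 ]
C [  0 12  0  0 12  0 ]
G [  0  0 12 12  0  0 ]
T [  0  0  0  0  0 12 ]
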