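ID smad_like_synthetic
BF synthetic SMAD-like GTCT/AGAC binding-element count matrix (not a database matrix)
XX
P0      A      C      G      T
01      5      5     85      5      G
02      5      5      5     85      T
03      5     80     10      5      C
04      5      5     10     80      T
05     80     10      5      5      A
06      5      5     85      5      G
07     85      5      5      5      A
08      5     85      5      5      C
09     60     15     15     10      A
10     10     60     20     10      C
XX
//
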