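BLASTP 2.17.0+


Reference: Stephen F. Altschul, Thomas L. Madden, Alejandro A.
Schaffer, Jinghui Zhang, Zheng Zhang, Webb Miller, and David J.
Lipman (1997), "Gapped BLAST and PSI-BLAST: a new generation of
protein database search programs", Nucleic Acids Res. 25:3389-3402.


Reference for composition-based statistics: Alejandro A. Schaffer,
L. Aravind, Thomas L. Madden, Sergei Shavirin, John L. Spouge, Yuri
I. Wolf, Eugene V. Koonin, and Stephen F. Altschul (2001),
"Improving the accuracy of PSI-BLAST protein database searches with
composition-based statistics and other refinements", Nucleic Acids
Res. 29:2994-3005.



Database: db.fa
           3 sequences; 171 total letters



Query= q1 toy query

Length=78
                                                                      Score     E
Sequences producing significant alignments:                          (Bits)  Value

s1 first subject                                                      155     2e-56
s2 second subject                                                     81.3    2e-27


>s1 first subject
Length=78

 Score = 155 bits (392),  Expect = 2e-56, Method: Compositional matrix adjust.
 Identities = 76/78 (97%), Positives = 77/78 (99%), Gaps = 0/78 (0%)

Query  1   MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRVGDGTQDNLSGAEKAVQVKVK  60
           MKTAYIAKQRQISFVKSHFSRQ+E RLGLIEVQAPILSRVGDGTQDNLSGAEKAVQVKVK
Sbjct  1   MKTAYIAKQRQISFVKSHFSRQIEGRLGLIEVQAPILSRVGDGTQDNLSGAEKAVQVKVK  60

Query  61  ALPDAQFEVVHSLAKWKR  78
           ALPDAQFEVVHSLAKWKR
Sbjct  61  ALPDAQFEVVHSLAKWKR  78


>s2 second subject
Length=57

 Score = 81.3 bits (199),  Expect = 2e-27, Method: Compositional matrix adjust.
 Identities = 38/38 (100%), Positives = 38/38 (100%), Gaps = 0/38 (0%)

Query  41  GDGTQDNLSGAEKAVQVKVKALPDAQFEVVHSLAKWKR  78
           GDGTQDNLSGAEKAVQVKVKALPDAQFEVVHSLAKWKR
Sbjct  1   GDGTQDNLSGAEKAVQVKVKALPDAQFEVVHSLAKWKR  38


 Score = 42.4 bits (98),  Expect = 6e-12, Method: Compositional matrix adjust.
 Identities = 19/19 (100%), Positives = 19/19 (100%), Gaps = 0/19 (0%)

Query  1   MKTAYIAKQRQISFVKSHF  19
           MKTAYIAKQRQISFVKSHF
Sbjct  39  MKTAYIAKQRQISFVKSHF  57



Lambda      K        H        a         alpha
   0.317    0.130    0.357    0.792     4.96 

Gapped
Lambda      K        H        a         alpha    sigma
   0.267   0.0410    0.140     1.90     42.6     43.6 

Effective search space used: 9246


  Database: db.fa
    Posted date:  Sep 30, 2026  6:30 PM
  Number of letters in database: 171
  Number of sequences in database:  3



Matrix: BLOSUM62
Gap Penalties: Existence: 11, Extension: 1
Neighboring words threshold: 11
Window for multiple hits: 40
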