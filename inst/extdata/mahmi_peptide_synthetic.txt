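BLASTP 2.6.0+


Database: mahmi_peptides


Query= MAHMI_query

Length=22

Sequences producing significant alignments:

  MAHMI_pep_00471 immunomodulatory peptide, in silico digest         45  2.1e-06
  MAHMI_pep_01198 antiproliferative candidate peptide                31  0.0018


> MAHMI_pep_00471 immunomodulatory peptide, in silico digest
Length=22

 Score = 44.7 bits (104),  Expect = 2.1e-06
 Identities = 21/22 (95%), Positives = 22/22 (100%), Gaps = 0/22 (0%)

Query   1  LASDPIVLSKPDYGWANNHTFV  22
           LASDPIVLSKP+YGWANNHTFV
Sbjct   1  LASDPIVLSKPEYGWANNHTFV  22


> MAHMI_pep_01198 antiproliferative candidate peptide
Length=20

 Score = 31.2 bits (70),  Expect = 0.0018
 Identities = 12/14 (86%), Positives = 13/14 (93%), Gaps = 0/14 (0%)

Query   5  PIVLSKPDYGWANN  18
           PIVLS+PDYGW NN
Sbjct   1  PIVLSRPDYGWSNN  14


Lambda      K        H
   0.267   0.0410    0.140

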