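BLASTP 2.6.0+


Database: synthetic_db


Query= query_0001 hypothetical protein

Length=214

Sequences producing significant alignments:

  sbj_0001_01 DNA-directed RNA polymerase subunit                   109  1.5e-27
  sbj_0001_02                                                        49  1.4e-09


> sbj_0001_01 DNA-directed RNA polymerase subunit
Length=96

 Score = 109.0 bits (239),  Expect = 1.5e-27
 Identities = 56/70 (80%), Positives = 57/70 (81%), Gaps = 5/70 (7%)

Query  104  TELNTG-CIDKIPECGMNSVRMFHFRGWTMENAQTCRLKCCNMTFKPATFAYPVHYQYWY  162
            TEL TG C  KI ECG NS+RMFHFRGWTM N  TCRL CCNMTFKPATF YPVHYQYWY
Sbjct    2  TELLTGFCNRKI-ECGPNSMRMFHFRGWTMPN--TCRL-CCNMTFKPATFYYPVHYQYWY  57

Query  163  PCMCMRKTDG  172
            PCM M KTDG
Sbjct   58  PCMPMEKTDG  67


 Score = 58.2 bits (127),  Expect = 3.0e-12
 Identities = 18/18 (100%), Positives = 18/18 (100%), Gaps = 0/18 (0%)

Query  110  GGPNCRTFNNTNECPQMK  127
            GGPNCRTFNNTNECPQMK
Sbjct   28  GGPNCRTFNNTNECPQMK  45


> sbj_0001_02
Length=99

 Score = 49.3 bits (108),  Expect = 1.4e-09
 Identities = 18/25 (72%), Positives = 19/25 (76%), Gaps = 1/25 (4%)

Query  163  WTT-SIMMCNDERMHDAGTSIHGSD  186
            WTT SI MCNDERMHDAGT  +  D
Sbjct   63  WTTGSIFMCNDERMHDAGTQHRNGD  87


Query= query_0002

Length=203

Sequences producing significant alignments:

  sbj_0002_01 hypothetical protein                                  153  8.2e-41
  sbj_0002_02 elongation factor Tu                                  135  2.8e-35


> sbj_0002_01 hypothetical protein
Length=231

 Score = 153.1 bits (335),  Expect = 8.2e-41
 Identities = 72/79 (91%), Positives = 73/79 (92%), Gaps = 0/79 (0%)

Query   41  SVRIETSEFEDGTDVLKSHSDMACVWYMDIKKMAVYAVLSASYKIATTAGKRMSWICEKM  100
            SVRIETSEF DGTDVLKSHSDMACVWYMDIKKMAVYAVLS SYKIATTAGKRMS+I EK
Sbjct  121  SVRIETSEFVDGTDVLKSHSDMACVWYMDIKKMAVYAVLSTSYKIATTAGKRMSYIIEKD  180

Query  101  WAFYYAIYECAHNRRCAWM  119
            WAFYYA  ECAHNRRCAWM
Sbjct  181  WAFYYAHQECAHNRRCAWM  199


 Score = 77.6 bits (170),  Expect = 4.4e-18
 Identities = 33/38 (87%), Positives = 33/38 (87%), Gaps = 3/38 (8%)

Query  18  MKIVHWGTPQEAGSDYLRRLDLTVDG--CACHWKEIMA  53
           M IVHWGTPQEAGSDYLRR DLTVDG  CACH KEIMA
Sbjct  60  MMIVHWGTPQEAGSDYLRRNDLTVDGDFCACH-KEIMA  96


> sbj_0002_02 elongation factor Tu
Length=132

 Score = 134.7 bits (295),  Expect = 2.8e-35
 Identities = 66/75 (88%), Positives = 66/75 (88%), Gaps = 4/75 (5%)

Query   46  NWNYFTYWMSILLQLEEIPGNMMKKWMIRMAAEYIYLANGWGKVSPLDRDGLHSAHGDEC  105
            NWNYFTYWMSILLQLEE PGNMM KWMI MAAEYIYLANGWGK SPLD DGLHSAHGD C
Sbjct   18  NWNYFTYWMSILLQLEEKPGNMM-KWMIIMAAEYIYLANGWGKKSPLDADGLHSAHGD-C  75

Query  106  NRHPLLFELQSDQAC  120
            NRHPL  EL SDQAC
Sbjct   76  NRHPL--ELWSDQAC  88


 Score = 132.1 bits (289),  Expect = 1.7e-34
 Identities = 64/73 (88%), Positives = 64/73 (88%), Gaps = 3/73 (4%)

Query  130  AIEGTPHPVTPHGYSCGHWWMAAVFEARRNIHEINEEKKIWKCHCVHMMEIYSKICEDQE  189
            AIEGTPHPVTPHGYS  HWW AA F ARRNIHE NEEKKIWKCHCVHMMEIYSKICEDQE
Sbjct   56  AIEGTPHPVTPHGYSI-HWWEAAAFHARRNIHERNEEKKIWKCHCVHMMEIYSKICEDQE  114

Query  190  AIQVYRSWNKRHA  202
            AIQVYR W  RHA
Sbjct  115  AIQVYRIW--RHA  125


Lambda      K        H
   0.267   0.0410    0.140
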