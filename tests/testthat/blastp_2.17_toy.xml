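<?xml version="1.0" encoding="US-ASCII"?>
<!DOCTYPE BlastOutput PUBLIC "-//NCBI//NCBI BlastOutput/EN" "http://www.ncbi.nlm.nih.gov/dtd/NCBI_BlastOutput.dtd">
<BlastOutput>
  <BlastOutput_program>blastp</BlastOutput_program>
  <BlastOutput_version>BLASTP 2.17.0+</BlastOutput_version>
  <BlastOutput_reference>Stephen F. Altschul, Thomas L. Madden, Alejandro A. Sch&amp;auml;ffer, Jinghui Zhang, Zheng Zhang, Webb Miller, and David J. Lipman (1997), &quot;Gapped BLAST and PSI-BLAST: a new generation of protein database search programs&quot;, Nucleic Acids Res. 25:3389-3402.</BlastOutput_reference>
  <BlastOutput_db>toydb</BlastOutput_db>
  <BlastOutput_query-ID>Query_1</BlastOutput_query-ID>
  <BlastOutput_query-def>q1 toy query</BlastOutput_query-def>
  <BlastOutput_query-len>78</BlastOutput_query-len>
  <BlastOutput_param>
    <Parameters>
      <Parameters_matrix>BLOSUM62</Parameters_matrix>
      <Parameters_expect>10</Parameters_expect>
      <Parameters_gap-open>11</Parameters_gap-open>
      <Parameters_gap-extend>1</Parameters_gap-extend>
      <Parameters_filter>F</Parameters_filter>
    </Parameters>
  </BlastOutput_param>
<BlastOutput_iterations>
<Iteration>
  <Iteration_iter-num>1</Iteration_iter-num>
  <Iteration_query-ID>Query_1</Iteration_query-ID>
  <Iteration_query-def>q1 toy query</Iteration_query-def>
  <Iteration_query-len>78</Iteration_query-len>
<Iteration_hits>
<Hit>
  <Hit_num>1</Hit_num>
  <Hit_id>gnl|BL_ORD_ID|0</Hit_id>
  <Hit_def>s1 first subject</Hit_def>
  <Hit_accession>0</Hit_accession>
  <Hit_len>78</Hit_len>
  <Hit_hsps>
    <Hsp>
      <Hsp_num>1</Hsp_num>
      <Hsp_bit-score>155.606</Hsp_bit-score>
      <Hsp_score>392</Hsp_score>
      <Hsp_evalue>1.71676e-56</Hsp_evalue>
      <Hsp_query-from>1</Hsp_query-from>
      <Hsp_query-to>78</Hsp_query-to>
      <Hsp_hit-from>1</Hsp_hit-from>
      <Hsp_hit-to>78</Hsp_hit-to>
      <Hsp_query-frame>0</Hsp_query-frame>
      <Hsp_hit-frame>0</Hsp_hit-frame>
      <Hsp_identity>76</Hsp_identity>
      <Hsp_positive>77</Hsp_positive>
      <Hsp_gaps>0</Hsp_gaps>
      <Hsp_align-len>78</Hsp_align-len>
      <Hsp_qseq>MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRVGDGTQDNLSGAEKAVQVKVKALPDAQFEVVHSLAKWKR</Hsp_qseq>
      <Hsp_hseq>MKTAYIAKQRQISFVKSHFSRQIEGRLGLIEVQAPILSRVGDGTQDNLSGAEKAVQVKVKALPDAQFEVVHSLAKWKR</Hsp_hseq>
      <Hsp_midline>MKTAYIAKQRQISFVKSHFSRQ+E RLGLIEVQAPILSRVGDGTQDNLSGAEKAVQVKVKALPDAQFEVVHSLAKWKR</Hsp_midline>
    </Hsp>
  </Hit_hsps>
</Hit>
<Hit>
  <Hit_num>2</Hit_num>
  <Hit_id>gnl|BL_ORD_ID|1</Hit_id>
  <Hit_def>s2 second subject</Hit_def>
  <Hit_accession>1</Hit_accession>
  <Hit_len>57</Hit_len>
  <Hit_hsps>
    <Hsp>
      <Hsp_num>1</Hsp_num>
      <Hsp_bit-score>81.2629</Hsp_bit-score>
      <Hsp_score>199</Hsp_score>
      <Hsp_evalue>2.48362e-27</Hsp_evalue>
      <Hsp_query-from>41</Hsp_query-from>
      <Hsp_query-to>78</Hsp_query-to>
      <Hsp_hit-from>1</Hsp_hit-from>
      <Hsp_hit-to>38</Hsp_hit-to>
      <Hsp_query-frame>0</Hsp_query-frame>
      <Hsp_hit-frame>0</Hsp_hit-frame>
      <Hsp_identity>38</Hsp_identity>
      <Hsp_positive>38</Hsp_positive>
      <Hsp_gaps>0</Hsp_gaps>
      <Hsp_align-len>38</Hsp_align-len>
      <Hsp_qseq>GDGTQDNLSGAEKAVQVKVKALPDAQFEVVHSLAKWKR</Hsp_qseq>
      <Hsp_hseq>GDGTQDNLSGAEKAVQVKVKALPDAQFEVVHSLAKWKR</Hsp_hseq>
      <Hsp_midline>GDGTQDNLSGAEKAVQVKVKALPDAQFEVVHSLAKWKR</Hsp_midline>
    </Hsp>
    <Hsp>
      <Hsp_num>2</Hsp_num>
      <Hsp_bit-score>42.3578</Hsp_bit-score>
      <Hsp_score>98</Hsp_score>
      <Hsp_evalue>5.737e-12</Hsp_evalue>
      <Hsp_query-from>1</Hsp_query-from>
      <Hsp_query-to>19</Hsp_query-to>
      <Hsp_hit-from>39</Hsp_hit-from>
      <Hsp_hit-to>57</Hsp_hit-to>
      <Hsp_query-frame>0</Hsp_query-frame>
      <Hsp_hit-frame>0</Hsp_hit-frame>
      <Hsp_identity>19</Hsp_identity>
      <Hsp_positive>19</Hsp_positive>
      <Hsp_gaps>0</Hsp_gaps>
      <Hsp_align-len>19</Hsp_align-len>
      <Hsp_qseq>MKTAYIAKQRQISFVKSHF</Hsp_qseq>
      <Hsp_hseq>MKTAYIAKQRQISFVKSHF</Hsp_hseq>
      <Hsp_midline>MKTAYIAKQRQISFVKSHF</Hsp_midline>
    </Hsp>
  </Hit_hsps>
</Hit>
</Iteration_hits>
  <Iteration_stat>
    <Statistics>
      <Statistics_db-num>3</Statistics_db-num>
      <Statistics_db-len>171</Statistics_db-len>
      <Statistics_hsp-len>11</Statistics_hsp-len>
      <Statistics_eff-space>9246</Statistics_eff-space>
      <Statistics_kappa>0.041</Statistics_kappa>
      <Statistics_lambda>0.267</Statistics_lambda>
      <Statistics_entropy>0.14</Statistics_entropy>
    </Statistics>
  </Iteration_stat>
</Iteration>
</BlastOutput_iterations>
</BlastOutput>

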