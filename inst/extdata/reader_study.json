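{
 "note": "Transcription of the reader-study gold standard, the two observers' interpretations (procedure choice and number of fibroids to be removed, read from sagittal and from surface-rendered images), and the per-observer required-time and difficulty-score summary statistics (mean, SD, n=10 cases; time in seconds, difficulty on a 1-4 scale). The published table layout was normalized to one record per case.",
 "n_cases": 10,
 "cases": [
  {
   "case": 1,
   "gold_procedure": "LAM",
   "gold_intramural": 3,
   "gold_subserosal": 1,
   "gold_submucosal": 0,
   "gold_count": 4,
   "procedure_o1_sagittal": "TLM",
   "procedure_o1_sr": "TLM",
   "procedure_o2_sagittal": "AM",
   "procedure_o2_sr": "AM",
   "count_o1_sagittal": 4,
   "count_o1_sr": 4,
   "count_o2_sagittal": 3,
   "count_o2_sr": 4
  },
  {
   "case": 2,
   "gold_procedure": "TLM",
   "gold_intramural": 1,
   "gold_subserosal": 0,
   "gold_submucosal": 0,
   "gold_count": 1,
   "procedure_o1_sagittal": "TLM",
   "procedure_o1_sr": "TLM",
   "procedure_o2_sagittal": "TCR",
   "procedure_o2_sr": "TLM",
   "count_o1_sagittal": 1,
   "count_o1_sr": 1,
   "count_o2_sagittal": 1,
   "count_o2_sr": 1
  },
  {
   "case": 3,
   "gold_procedure": "LAM",
   "gold_intramural": 1,
   "gold_subserosal": 0,
   "gold_submucosal": 0,
   "gold_count": 1,
   "procedure_o1_sagittal": "TLM",
   "procedure_o1_sr": "TLM",
   "procedure_o2_sagittal": "AM",
   "procedure_o2_sr": "TLM",
   "count_o1_sagittal": 1,
   "count_o1_sr": 1,
   "count_o2_sagittal": 1,
   "count_o2_sr": 1
  },
  {
   "case": 4,
   "gold_procedure": "TLM",
   "gold_intramural": 2,
   "gold_subserosal": 0,
   "gold_submucosal": 0,
   "gold_count": 2,
   "procedure_o1_sagittal": "TLM",
   "procedure_o1_sr": "TLM",
   "procedure_o2_sagittal": "TLM",
   "procedure_o2_sr": "TLM",
   "count_o1_sagittal": 2,
   "count_o1_sr": 2,
   "count_o2_sagittal": 2,
   "count_o2_sr": 2
  },
  {
   "case": 5,
   "gold_procedure": "TLM",
   "gold_intramural": 1,
   "gold_subserosal": 0,
   "gold_submucosal": 0,
   "gold_count": 1,
   "procedure_o1_sagittal": "TLM",
   "procedure_o1_sr": "TLM",
   "procedure_o2_sagittal": "TLM",
   "procedure_o2_sr": "TCR",
   "count_o1_sagittal": 1,
   "count_o1_sr": 1,
   "count_o2_sagittal": 1,
   "count_o2_sr": 1
  },
  {
   "case": 6,
   "gold_procedure": "TLM",
   "gold_intramural": 1,
   "gold_subserosal": 0,
   "gold_submucosal": 0,
   "gold_count": 1,
   "procedure_o1_sagittal": "TLM",
   "procedure_o1_sr": "TLM",
   "procedure_o2_sagittal": "TLM",
   "procedure_o2_sr": "TLM",
   "count_o1_sagittal": 1,
   "count_o1_sr": 1,
   "count_o2_sagittal": 1,
   "count_o2_sr": 1
  },
  {
   "case": 7,
   "gold_procedure": "TLM",
   "gold_intramural": 5,
   "gold_subserosal": 1,
   "gold_submucosal": 0,
   "gold_count": 6,
   "procedure_o1_sagittal": "LAM",
   "procedure_o1_sr": "TLM",
   "procedure_o2_sagittal": "TLM",
   "procedure_o2_sr": "TLM",
   "count_o1_sagittal": 8,
   "count_o1_sr": 6,
   "count_o2_sagittal": 6,
   "count_o2_sr": 7
  },
  {
   "case": 8,
   "gold_procedure": "TLM",
   "gold_intramural": 5,
   "gold_subserosal": 0,
   "gold_submucosal": 0,
   "gold_count": 5,
   "procedure_o1_sagittal": "LAM",
   "procedure_o1_sr": "LAM",
   "procedure_o2_sagittal": "TLM",
   "procedure_o2_sr": "TLM",
   "count_o1_sagittal": 9,
   "count_o1_sr": 6,
   "count_o2_sagittal": 7,
   "count_o2_sr": 6
  },
  {
   "case": 9,
   "gold_procedure": "TLM",
   "gold_intramural": 3,
   "gold_subserosal": 0,
   "gold_submucosal": 0,
   "gold_count": 3,
   "procedure_o1_sagittal": "LAM",
   "procedure_o1_sr": "TLM",
   "procedure_o2_sagittal": "TLM",
   "procedure_o2_sr": "TLM",
   "count_o1_sagittal": 6,
   "count_o1_sr": 4,
   "count_o2_sagittal": 3,
   "count_o2_sr": 3
  },
  {
   "case": 10,
   "gold_procedure": "TCR",
   "gold_intramural": 0,
   "gold_subserosal": 0,
   "gold_submucosal": 1,
   "gold_count": 1,
   "procedure_o1_sagittal": "TCR",
   "procedure_o1_sr": "TCR",
   "procedure_o2_sagittal": "TCR",
   "procedure_o2_sr": "TCR",
   "count_o1_sagittal": 1,
   "count_o1_sr": 1,
   "count_o2_sagittal": 2,
   "count_o2_sr": 1
  }
 ],
 "summaries": [
  {
   "observer": 1,
   "measure": "time_s",
   "method": "sagittal",
   "mean": 19.7,
   "sd": 9.5,
   "n": 10
  },
  {
   "observer": 1,
   "measure": "time_s",
   "method": "sr",
   "mean": 10.4,
   "sd": 5.1,
   "n": 10
  },
  {
   "observer": 2,
   "measure": "time_s",
   "method": "sagittal",
   "mean": 47.5,
   "sd": 12.3,
   "n": 10
  },
  {
   "observer": 2,
   "measure": "time_s",
   "method": "sr",
   "mean": 19.7,
   "sd": 9.5,
   "n": 10
  },
  {
   "observer": 1,
   "measure": "difficulty",
   "method": "sagittal",
   "mean": 1.6,
   "sd": 0.7,
   "n": 10
  },
  {
   "observer": 1,
   "measure": "difficulty",
   "method": "sr",
   "mean": 1.4,
   "sd": 0.7,
   "n": 10
  },
  {
   "observer": 2,
   "measure": "difficulty",
   "method": "sagittal",
   "mean": 2.7,
   "sd": 0.7,
   "n": 10
  },
  {
   "observer": 2,
   "measure": "difficulty",
   "method": "sr",
   "mean": 2.4,
   "sd": 0.5,
   "n": 10
  }
 ]
}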