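# Printed summary statistics of the reference HC/MCI cohort used to
# parameterize the phantom generator's covariate defaults and to exercise
# the summary-statistic tests (values as printed, 2 decimals).
demographics:
  age:
    hc: {mean: 63.50, sd: 6.55, 'n': 16}
    mci: {mean: 70.35, sd: 8.09, 'n': 17}
  education:
    hc: {mean: 17.38, sd: 2.12, 'n': 16}
    mci: {mean: 16.62, sd: 3.26, 'n': 17}
  odor_id:
    hc: {mean: 16.50, sd: 2.16, 'n': 16}
    mci: {mean: 13.94, sd: 4.49, 'n': 17}
gender:
  hc: {m: 3, f: 13}
  mci: {m: 10, f: 7}
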