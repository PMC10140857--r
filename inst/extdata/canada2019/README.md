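# canada2019 fixtures

Published national summary tables for the Canadian 2019 free-sugars
reformulation scenario (adults, 19+), transcribed as plain CSV so the
package's reporting and share arithmetic can be exercised on real published
numbers:

- `exposure_baseline.csv` / `exposure_counterfactual.csv`: per sex x DRI
  group mean daily energy intake (with SE of the mean), mean BMI and mean
  height under the actual diet and under a systematic 20% reduction in the
  free-sugars content of foods and beverages. The `sd_bmi` column (5.0
  kg/m^2) is a **synthetic** population spread: the published table prints
  only the SE of the mean BMI, which is a sampling quantity, not the
  population SD the impact-fraction integrals need.
- `intake_totals.csv`: published population-level intake quantities
  (baseline mean free sugars and energy, counterfactual energy).
- `averted_published.csv`: published deaths averted or delayed per cause of
  death and sex, with 95% uncertainty intervals.
- `actual_deaths.csv`: observed 2019 deaths for the same causes (reporting
  denominators).
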