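published_estimates.csv
  Published regression effect estimates (clock units) for the newborn Down
  syndrome epigenetic-aging analyses, with the day-scale accelerations as
  printed alongside them. Day conversions divide the estimate by the
  reference slope of 0.001 clock units per day of chronological age in
  non-DS newborns (for VAF, days per 10% VAF = estimate * 0.1 / slope).
  Used as input by the reproduction checks in scripts/acceptance.R.

Clock coefficient CSV schema (for load_clock()):
  header: cpg_id,weight
  exactly one row with cpg_id "(Intercept)" holding the intercept; every
  other row is one CpG and its weight. Published coefficient sets
  (pan-tissue 353 CpGs, skin & blood 391 CpGs, Haftorn 176, Knight 148,
  Bohlin 96) can be exported to this schema from their original
  publications; they are not redistributed here. All package tests run on
  synthetic clocks.
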