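# Example pipeline configuration. Every field is optional; omitted fields
# fall back to the packaged defaults shown here.
calendar:
  study_start_date: 2016-04-03
  study_close_date: 2018-03-31
  maintenance_start: 2017-05-07
  maintenance_end: 2017-07-15
  week_convention: sunday_start   # sunday_start | monday_start | iso
committed_threshold: 2            # post-maintenance reports defining a committed user
moving_width: 4                   # trailing window width in weeks
moving_method: pooled             # pooled | mean
simulate: true                    # generate inputs with the synthetic cohort
simulation:                       # sim_config() overrides
  n_participants: 690
  seed: 1
# With simulate: false, point the pipeline at CSV inputs instead:
# inputs:
#   roster: path/to/roster.csv
#   reports: path/to/reports.csv
#   reference: path/to/reference.csv
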