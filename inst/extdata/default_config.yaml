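# Default pipeline configuration: the study-scale run (460 completers with
# planted aberrant respondents; 30 choice sets in 3 blocks of 10). The
# master seed expands deterministically to per-stage seeds.
seed: 20220215
unit: 10
design:
  n_sets: 30
  n_blocks: 3
  n_restarts: 5
cohort:
  n_per_income: {low: 150, middle: 155, high: 155}
  planted: {nontrader: 3, dominance_failer: 15, never_enroller: 12}
model:
  n_draws: 200
  draw_type: halton
  halton_skip: 100
  maxit: 500
postfit:
  kr_draws: 10000
  uptake_draws: 2000
  uptake_amounts: [50, 100, 200, 350, 500, 750, 1000]
  base_program: {type: Cash, schedule: Consistent, sessions: 1_week, location: Healthcare}
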