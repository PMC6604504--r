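# quizscreen

Eligibility screening for web-based studies of people who use drugs
(PWUD), where neither urine testing nor IP geolocation can verify who is
on the other end of a survey link. The package implements the
knowledge-quiz screen as a tested pipeline: county-residence quizzes
drawn 5-at-random from 10-item local-knowledge banks (pass = 3 of 5),
drug quizzes on dose, appearance and street price with a 50/50
correct-option construction rule (pass = either scored component
correct; synthetic opioids auto-pass; nonopioid users get an unscored
masking quiz), the full branching screening flow with non-exclusive
ineligibility reasons, and a 13-panel urine-drug-test (UDT) concordance
stage.

Around the screen it provides three research instruments:

* **an exact guessing oracle** — quiz scores are Poisson-binomial, so
  the pass probability for a respondent with per-item success
  probabilities $p_i$ is the mean of
  $P(\sum_{i \in D} X_i \ge 3)$ over all $\binom{10}{5}$ draws $D$;
  for a homogeneous 4-option bank this is the binomial tail
  $\sum_{j\ge3}\binom{5}{j}(1/4)^j(3/4)^{5-j} = 0.103515625$, the
  chance an out-of-area impostor passes the county quiz by luck.
  Screen-level sensitivity/specificity/PPV compose these closed forms
  through the flow's AND-logic;
* **a persona-based synthetic respondent simulator** (knowledge models
  per topic category, completion probabilities, coached retakes), whose
  empirical pass rates are checked against the oracle within
  Monte-Carlo error;
* **a marginal-constraint fixture synthesizer** that turns the printed
  screening counts into record-level datasets carrying responses (not
  outcomes), so every published percentage re-emerges only when the
  real scoring rules are re-applied — and that detects arithmetically
  infeasible printed marginals, reporting a minimal conflicting subset.

## Worked example

```r
library(quizscreen)
cfg <- load_config(example_config_path())

# an impostor's odds: county quiz by guessing, then the heroin quiz
county_pass_probability(rep(0.25, 10))
#> [1] 0.1035156
drug_pass_probability(drug_quiz_spec(cfg$catalog, "heroin", seed = 1))
#> [1] 0.4375

# replay the published funnel from a constraint-built fixture
fx <- build_fixture("funnel_reasons", seed = 1)
fr <- classify_funnel(screen_records(fx$records, cfg$flow, cfg$catalog))
print(fr)
#> Screening funnel
#>   entries              528
#>   incomplete           118 (22.3%)
#>   complete             410
#>   eligible             234 (57.1%)
#>   ineligible           176 (42.9%)
#>   reasons (non-exclusive, of ineligible):
#>     no_substance       116 (65.9%)
#>     age                72 (40.9%)
#>     outside_area       23 (13.1%)
#>     county_quiz_fail   5 (2.8%)
#>     drug_quiz_fail     7 (4.0%)

# the infeasible published marginal, caught with its conflicting subset
try(build_fixture("bup_pills_printed"))
#> Error : infeasible constraint set 'bup_pills_printed'; minimal
#>   conflicting subset: {passers=63, dose_correct=60, image_correct=58,
#>   both_correct=53}
```

Of the 410 complete screening entries, 57.1% are classified eligible by
re-scoring the fixture's per-item responses with the engine; the reason
tallies are non-exclusive (one respondent can be underage *and* report
no opioid). The infeasibility message records that 53 both-correct plus
7 dose-only plus 5 image-only passers cannot fit in 63.

## Analysis workflow

Numbered drivers under `analysis/` run the pipeline end to end and
write tables under `results/`:

1. `01_screen_setup.R` — configuration and quiz structure;
2. `02_guessing_oracle.R` — exact guessing/pass probabilities and
   screen operating characteristics;
3. `03_simulate_cohort.R` — synthetic cohort of 20,000 through the
   flow; oracle vs empirical pass rates per persona;
4. `04_fixture_replay.R` — every published percentage replayed through
   the engine;
5. `05_udt_concordance.R` — UDT panel positivity and self-report
   concordance.

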