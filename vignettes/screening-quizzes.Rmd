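---
title: "Knowledge-quiz eligibility screening: models, oracles and fixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-quiz eligibility screening: models, oracles and fixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The screening problem

Web-based studies of people who use drugs (PWUD) cannot verify
eligibility with urine testing or in-person inspection at screening
time, and IP-based geolocation is unreliable on mobile networks. The
screen implemented here verifies two claims with *knowledge quizzes*:

* **residence** in one of five eligible rural counties, tested by five
  questions drawn at random from a county-specific ten-item bank of
  local knowledge (largest town, smallest communities, presence of a
  jail or a Walmart, a landmark, a grocery chain, plus four
  county-specific topics); pass requires 3 of 5 correct;
* **opioid use**, tested by questions about the dose, appearance and
  street price of the opioid the respondent reports using most often.
  Heroin users must get the cap size (the local purchase unit, one
  tenth of a gram) or the street-price bracket ($10–$50) right; the
  ten-image recognition question is recorded but unscored, because
  injectors may only ever see dissolved heroin. Prescription-class
  drugs (pills, buprenorphine, methadone) use dose and image questions
  built under the **50/50 rule** — exactly half the offered options are
  correct — so a drug made in doses of 5, 15 and 30 mg yields a
  six-option dose question with three correct answers, and pass
  requires dose *or* image correct. Synthetic-opioid reporters
  auto-pass (the market moves too fast for a stable answer key), and
  respondents reporting only nonopioids receive an unscored masking
  quiz so the true eligibility criteria cannot be inferred from which
  answers get scored.

The flow never shortens on failure (also a masking property):
age, county report, county quiz (the generic unscorable bank for
out-of-area reports), substance checklist, most-often opioid (listing
opioids only), drug quiz. Ineligibility reasons are recorded
non-exclusively; a single respondent can be underage *and* report no
opioid.

## Pass probabilities: the Poisson-binomial oracle

Conditional on a respondent whose probability of answering item $i$
correctly is $p_i$, the number of correct answers among the five drawn
items is Poisson-binomial. The package computes
$P(\text{score} \ge k)$ by exact dynamic-programming convolution and
the county pass probability as the mean over all
$\binom{10}{5} = 252$ equally likely draws:

$$P(\text{pass}) = \frac{1}{252} \sum_{D} P\!\left(\sum_{i \in D}
X_i \ge 3\right), \qquad X_i \sim \text{Bernoulli}(p_i).$$

With a homogeneous four-option bank ($p_i = 1/4$) this collapses to
the binomial tail $\sum_{j\ge3}\binom{5}{j}(1/4)^j(3/4)^{5-j} =
0.103515625$ — the headline operating characteristic: an out-of-area
impostor who falsely claims an eligible county has about a 1-in-10
chance of passing the county quiz by guessing. Drug quizzes pass on an
OR over scored components, $1 - \prod_c (1 - p_c)$ under component
independence; the pure-guessing values are $1-(3/4)^2 = 0.4375$ for
heroin and $3/4$ for any drug built under the 50/50 rule. Screen-level
sensitivity, specificity and PPV compose these closed forms through
the flow's AND-logic and Bayes' rule over a persona mix.

The test oracle for the dynamic program is full $2^n$ enumeration for
banks up to size 12. R has no exact rational type, so the enumeration
uses dyadic-rational probabilities (multiples of $2^{-b}$), for which
every product and partial sum is exactly representable in double
precision; the comparison is then exact rather than approximate.

## The synthetic respondent generator

Personas are respondent classes: an age distribution, a reported
county, a distribution over reported substance sets, a completion
probability, and a *knowledge model* — a per-category probability of
answering correctly, falling back to the structural guessing
probability $|\text{correct}|/|\text{options}|$ for categories the
model does not name. Item-level responses are conditionally
independent given the persona; this is the simplest model consistent
with per-item accuracy reporting, and wrong answers are uniform over
the incorrect options because only correctness is ever recorded.

The shipped library has six personas. The eligible classes use the
observed item accuracies of the screened study population as knowledge
probabilities (cap size 0.946, street price 0.970, prescription dose
0.95; county items 0.98, chosen so that about 91% of passers answer
all five items correctly, matching the observed score distribution).
The recent mover halves the school-topic knowledge (mascot, colors),
reflecting the pilot finding that newer residents miss school
questions. The out-of-area guesser falsely claims an eligible county
and guesses everywhere — a stated lower bound, since no quantitative
knowledge profile of outsiders exists. Underage and nonopioid-only
classes exercise the report gates, and the abandoner completes 15% of
sessions. Where the source states no value (completion rates,
substance mix), values were fixed once at what a field study of this
kind would find unremarkable and are not tuned.

Two simulation paths share the same scoring rules: `run_session()`
walks one respondent through the full branching flow and returns a
transcript, and `simulate_cohort()` generates record tables at array
scale (100,000 respondents in a few seconds) for oracle comparisons.
Their equivalence on deterministic knowledge is itself tested.
`coached_retake()` models answer sharing: items seen in previous
transcripts are answered correctly with probability
$\max(\text{base}, \text{carryover})$; because two independent
5-of-10 draws share only 2.5 items in expectation, the bank design
caps what coaching can transfer.

## Fixtures: synthesizing records from printed counts

No record-level data are public, so the published marginal counts are
turned into *constraint slices*: YAML files stating, for one
internally consistent group of printed numbers, predicates over binary
record flags and the count each must attain. A deterministic exact
search over the $2^k$ cross-classification cells (most-constrained
cell first, largest feasible value first, with completability pruning
and backtracking) finds a nonnegative integer allocation; the flags
are then materialized into engine-schema records that carry
*responses* — per-item correctness — never outcomes, so the printed
pass counts and percentages re-emerge only by re-scoring with the real
rules. A pure most-specific-first greedy allocator provably fails on
these systems (the heroin image marginal overlaps the cap-and-price
cell), which is why the allocator searches with backtracking; it
remains deterministic given the constraints, and the seed only
permutes row order.

Slices are shipped per group rather than as one global set because the
printed counts are mutually inconsistent in places, all handled
explicitly:

* the funnel printed as drawn implies 15 quiz failures (249 met the
  report criteria, 234 passed), while the results text says 12 (5
  county and/or 7 drug — a union that cannot exceed 12); two funnel
  slices are shipped, one per cited location;
* the buprenorphine-pill passer marginals (60 dose, 58 image, 53 both,
  of 63) are integer-infeasible, since $53 + 7 + 5 = 65 > 63$; the
  slice that pins all four is kept as the infeasibility-detection
  case, and the feasibility checker reports exactly that minimal
  conflicting subset (verified against an exhaustive small-instance
  solver). The relaxed slice leaves both-correct free (it comes out
  as 55);
* the prescription-opioid drug list sums to 39 quizzed yet the text
  reports 38 passers with 2 failures; the slice pins the passer
  marginals and the identified failure drugs only;
* the combined drug-quiz population (294 quizzed, 285 passing, 96.9%
  — printed as 97.0%) is assembled by concatenating the per-drug
  slices with 3 synthetic-opioid auto-passes, which is exactly the
  count that makes the arithmetic close;
* mean days-to-specimen in the concordance table (0.22 over 21, 0.52
  over 9) are unattainable with whole-day counts; day values are
  fixed inside the printed ranges and means are recomputed, not
  asserted.

Under-determination is not an error: unconstrained cells default to
all-flags-false, and free fields are filled deterministically
(ages 27, counties cycled, an off-list drug for unpinned records).

## Urine drug testing

The 13-panel cup is modeled at the positive/negative level; detection
windows (days) and thresholds (ng/mL) are carried as metadata because
only binary panel results are ever reported. The drug-to-panel map
sends heroin to opiates, oxycodone brands to oxycodone, and
buprenorphine/methadone to their own panels; fentanyl and tramadol map
to an explicit never-detected marker. The default detection model is
deterministic — positive iff days since use plus days to specimen is
within the window's *upper* bound — with a uniform-in-window
stochastic variant for sensitivity analysis; the 2-to-5-hour onset
delay is below day resolution and ignored. The tested-34 fixture
encodes panel positivity directly (positivity *is* the response at
this stage), with cross-panel overlaps chosen so the any-opioid union
is 25 of 34: one heroin reporter and one buprenorphine reporter are
positive on both the opiates and buprenorphine panels.

## Nonparametric reporting

County-score differences across counties use the Kruskal-Wallis
statistic with midranks and the tie-correction divisor
$1 - \sum(t^3 - t)/(N^3 - N)$ (guarded so that an all-tied sample
yields $H = 0$), with the asymptotic $\chi^2$ p-value; length of
residence versus score uses the Spearman correlation as the
product-moment correlation of midranks. Both are validated against
the reference implementations in `stats` and against hand-computed
toy cases. The study's own test statistics ($\chi^2_4 = 6.9$,
$r_s = .03$) depend on the non-public microdata and are deliberately
not reproduction targets. Printed percentages are reproduced under
half-up rounding at the precision of the cited location (the source
mixes "95%" and "94.6%"); raw fractions are always computed alongside.

## Problem sizes and numerical choices

Oracle-versus-simulation agreement is checked at $n = 10^5$ per
persona within three Monte-Carlo standard errors; funnel-conservation
and determinism invariants run over 1,000 randomized populations of
30; the Kruskal-Wallis null rejection rate uses 10,000 replicates of
five groups of ten, asserted within 0.01 of the nominal 0.05 (three
Monte-Carlo standard errors plus slack for the asymptotic
approximation). All probabilities are computed in double precision;
the only exactness-critical comparison (DP versus enumeration) is
restricted to dyadic inputs as described above. Money is held in
integer US cents; the overlapping printed price brackets are kept
as printed.

## What passing does and does not show

The generator emulates branch logic, guessing structure and item-level
accuracy; it does not model correlated knowledge within respondents,
response times, device effects, coaching networks beyond the carryover
model, or deliberate fraud strategies (published separately for the
original study). Agreement between simulator and oracle therefore
validates the implementation and the closed forms, not the behavioral
realism of any persona; and fixture replay validates that the printed
results are exactly recoverable from some response-level dataset under
the stated scoring rules — it cannot recover the study's actual
microdata, and the shipped bank wording is illustrative, not the
study's.
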