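test_that("poisson_binomial_tail matches closed forms", {
  # binomial case: five 4-option guesses, need 3
  expect_equal(poisson_binomial_tail(rep(0.25, 5), 3), 0.103515625,
               tolerance = 1e-12)
  expect_identical(poisson_binomial_tail(rep(1, 7), 5), 1)
  expect_equal(poisson_binomial_tail(c(0.5, 0.5), 1), 0.75,
               tolerance = 1e-12)
  # complement rule: k = 0 is certain
  expect_identical(poisson_binomial_tail(runif(6), 0), 1)
  expect_error(poisson_binomial_tail(c(0.5, 1.2), 1), "\\[0, 1\\]")
})

test_that("DP tail equals full enumeration for banks up to size 12", {
  withr::with_seed(2024, {
    for (n in 1:12) {
      # dyadic-rational probabilities: double arithmetic is exact, so
      # the enumeration is an exact oracle
      probs <- sample(0:16, n, replace = TRUE) / 16
      for (k in c(0L, 1L, sample.int(n, 1L), n)) {
        expect_equal(poisson_binomial_tail(probs, k),
                     enumerate_tail(probs, k), tolerance = 1e-14)
      }
    }
  })
})

test_that("county pass probability reduces to the binomial and is exact", {
  expect_equal(county_pass_probability(rep(0.25, 10)), 0.103515625,
               tolerance = 1e-12)
  expect_identical(county_pass_probability(rep(1, 10)), 1)
  expect_error(county_pass_probability(rep(0.5, 4)), "smaller than")
  # heterogeneous bank: 5 yes/no (1/2) + 5 four-option (1/4) items,
  # checked against enumeration over every draw x outcome path
  profile <- c(rep(0.5, 5), rep(0.25, 5))
  spec <- county_quiz_spec()
  draws <- utils::combn(10, 5)
  by_enum <- mean(apply(draws, 2, function(idx) {
    enumerate_tail(profile[idx], spec$pass_threshold)
  }))
  expect_equal(county_pass_probability(profile, spec), by_enum,
               tolerance = 1e-12)
})

test_that("raising any item probability never lowers a pass probability", {
  withr::with_seed(7, {
    for (rep_i in 1:20) {
      profile <- runif(10)
      base <- county_pass_probability(profile)
      j <- sample.int(10, 1)
      bumped <- profile
      bumped[j] <- min(1, profile[j] + runif(1, 0, 1 - profile[j]))
      expect_gte(county_pass_probability(bumped) + 1e-12, base)
    }
  })
})

test_that("drug pass probabilities follow the either/or closed form", {
  heroin <- drug_quiz_spec(test_cfg$catalog, "heroin", seed = 1)
  # pure guesser: two 4-option questions -> 1 - (3/4)^2
  expect_equal(drug_pass_probability(heroin), 0.4375, tolerance = 1e-12)
  rox <- drug_quiz_spec(test_cfg$catalog, "roxicodone", seed = 1)
  # 50/50 rule makes both guessing probabilities 1/2 -> 3/4
  expect_equal(drug_pass_probability(rox), 0.75, tolerance = 1e-12)
  fent <- drug_quiz_spec(test_cfg$catalog, "fentanyl", seed = 1)
  expect_identical(drug_pass_probability(fent), 1)
  expect_error(drug_pass_probability(heroin, c(cap_size = 0.9)),
               "missing scored component")
})

test_that("screen operating characteristics compose the flow's AND-logic", {
  cfg <- mc4_config()
  all_known <- persona(
    "all_known", 18:35,
    county_weights = stats::setNames(rep(0.2, 5),
                                     cfg$flow$eligible_counties),
    substance_sets = list(list(drugs = "heroin",
                               most_often_weights = c(heroin = 1))),
    knowledge = stats::setNames(
      rep(1, 14),
      c("largest_town", "smallest_communities", "jail", "walmart",
        "landmark", "grocery", "mascot", "school_colors", "festival",
        "pizza", "cap_size", "price", "dose", "image")),
    truly_eligible = TRUE)
  truthful_outsider <- persona(
    "truthful_outsider", 18:35, county_weights = c(outside = 1),
    substance_sets = list(list(drugs = "heroin",
                               most_often_weights = c(heroin = 1))),
    knowledge = numeric(), truly_eligible = FALSE)
  false_claimer <- persona(
    "false_claimer", 18:35,
    county_weights = stats::setNames(rep(0.2, 5),
                                     cfg$flow$eligible_counties),
    substance_sets = list(list(drugs = "heroin",
                               most_often_weights = c(heroin = 1))),
    knowledge = numeric(), truly_eligible = FALSE)
  oc <- screen_operating_characteristics(
    list(all_known, truthful_outsider), c(0.5, 0.5),
    cfg$flow, cfg$banks, cfg$catalog)
  expect_equal(oc$sensitivity, 1, tolerance = 1e-12)
  # truthfully reporting an outside county disqualifies before any quiz
  expect_equal(oc$specificity, 1, tolerance = 1e-12)
  expect_equal(oc$ppv, 1, tolerance = 1e-12)
  # a guesser claiming an eligible county must pass both quizzes by luck
  p_false <- persona_pass_probability(false_claimer, cfg$flow, cfg$banks,
                                      cfg$catalog)
  expect_equal(p_false, 0.103515625 * 0.4375, tolerance = 1e-12)
})
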