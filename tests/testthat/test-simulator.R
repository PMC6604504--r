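test_that("forced personas produce the forced outcome", {
  cfg <- test_cfg
  know_all <- stats::setNames(
    rep(1, 14),
    c("largest_town", "smallest_communities", "jail", "walmart",
      "landmark", "grocery", "mascot", "school_colors", "festival",
      "pizza", "cap_size", "price", "dose", "image"))
  sure <- persona("sure", 18:35,
                  county_weights = stats::setNames(rep(0.2, 5),
                                                   cfg$flow$eligible_counties),
                  substance_sets = list(list(drugs = "heroin",
                                             most_often_weights =
                                               c(heroin = 1))),
                  knowledge = know_all, truly_eligible = TRUE)
  rec <- simulate_cohort(population_spec(list(sure), seed = 1), 400,
                         cfg$flow, cfg$banks, cfg$catalog, seed = 2)
  scr <- screen_records(rec, cfg$flow, cfg$catalog)
  expect_true(all(scr$eligible))
  # out-of-area persona: every member ineligible with outside_area
  away <- persona("away", 18:35, county_weights = c(nowhere = 1),
                  substance_sets = list(list(drugs = "heroin",
                                             most_often_weights =
                                               c(heroin = 1))),
                  knowledge = know_all)
  rec2 <- simulate_cohort(population_spec(list(away), seed = 1), 200,
                          cfg$flow, cfg$banks, cfg$catalog, seed = 3)
  scr2 <- screen_records(rec2, cfg$flow, cfg$catalog)
  expect_true(all(!scr2$eligible))
  expect_true(all(scr2$reason_outside_area))
})

test_that("county guessers pass 3-of-5 on 4-option banks at the binomial rate", {
  cfg <- mc4_config()
  guesser <- persona("guesser", 18:35,
                     county_weights = stats::setNames(
                       rep(0.2, 5), cfg$flow$eligible_counties),
                     substance_sets = list(list(drugs = "heroin",
                                                most_often_weights =
                                                  c(heroin = 1))),
                     knowledge = numeric())
  n <- 10000L
  rec <- simulate_cohort(population_spec(list(guesser), seed = 4), n,
                         cfg$flow, cfg$banks, cfg$catalog, seed = 5)
  scr <- screen_records(rec, cfg$flow, cfg$catalog)
  p_hat <- mean(scr$county_quiz_pass %in% TRUE)
  p <- 0.103515625
  expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("population sampling is reproducible and respects weights", {
  spec <- population_spec(unname(test_personas), seed = 77)
  a <- sample_population(spec, 50)
  b <- sample_population(spec, 50)
  expect_identical(vapply(a, `[[`, "", "persona_id"),
                   vapply(b, `[[`, "", "persona_id"))
  expect_error(population_spec(unname(test_personas), weights = c(1, 1)),
               "length")
})

test_that("vectorized cohort and session engine agree on deterministic knowledge", {
  cfg <- test_cfg
  know_all <- stats::setNames(
    rep(1, 14),
    c("largest_town", "smallest_communities", "jail", "walmart",
      "landmark", "grocery", "mascot", "school_colors", "festival",
      "pizza", "cap_size", "price", "dose", "image"))
  sure <- persona("sure", 25, county_weights = c(amberley = 1),
                  substance_sets = list(list(drugs = "percocet",
                                             most_often_weights =
                                               c(percocet = 1))),
                  knowledge = know_all, truly_eligible = TRUE)
  srcs <- sample_population(population_spec(list(sure), seed = 8), 10)
  for (i in seq_along(srcs)) {
    out <- run_session(srcs[[i]], cfg$flow, cfg$banks, cfg$catalog,
                       seed = 60 + i)
    expect_true(out$result$eligible)
  }
  rec <- simulate_cohort(population_spec(list(sure), seed = 8), 50,
                         cfg$flow, cfg$banks, cfg$catalog, seed = 9)
  expect_true(all(screen_records(rec, cfg$flow, cfg$catalog)$eligible))
})

test_that("coached retakes behave as the carryover model dictates", {
  cfg <- test_cfg
  bank <- cfg$banks[["amberley"]]
  naive <- persona("naive", 25, county_weights = c(amberley = 1),
                   substance_sets = list(list(drugs = "heroin",
                                              most_often_weights =
                                                c(heroin = 1))),
                   knowledge = numeric())
  src <- sample_population(population_spec(list(naive), seed = 10), 1)[[1]]
  first <- run_session(src, cfg$flow, cfg$banks, cfg$catalog, seed = 501)
  # carryover 1 and the identical draw: pass guaranteed
  coached <- coached_retake(src, list(first$transcript), carryover = 1)
  again <- run_session(coached, cfg$flow, cfg$banks, cfg$catalog,
                       seed = 501)
  expect_true(again$result$county_quiz_pass)
  # carryover 0 reduces to the first-attempt oracle value
  uncoached <- coached_retake(src, list(first$transcript), carryover = 0)
  it <- bank$items[[1]]
  expect_equal(uncoached$p_correct(it), src$p_correct(it))
  # expected overlap of two independent 5-of-10 draws is hypergeometric:
  # 5 * 5/10 = 2.5
  overlaps <- withr::with_seed(11, vapply(1:4000, function(i) {
    d1 <- vapply(draw_county_quiz(bank), `[[`, "", "item_id")
    d2 <- vapply(draw_county_quiz(bank), `[[`, "", "item_id")
    length(intersect(d1, d2))
  }, numeric(1)))
  se <- sqrt(stats::var(overlaps) / length(overlaps))
  expect_lt(abs(mean(overlaps) - 2.5), 3 * se)
})

test_that("incomplete sessions carry partial records only", {
  cfg <- test_cfg
  quitter <- persona("quitter", 25, county_weights = c(amberley = 1),
                     substance_sets = list(list(drugs = "heroin",
                                                most_often_weights =
                                                  c(heroin = 1))),
                     knowledge = numeric(), p_complete = 0)
  rec <- simulate_cohort(population_spec(list(quitter), seed = 12), 100,
                         cfg$flow, cfg$banks, cfg$catalog, seed = 13)
  expect_true(all(!rec$complete))
  fr <- classify_funnel(screen_records(rec, cfg$flow, cfg$catalog))
  expect_identical(fr$n_incomplete, 100L)
  expect_identical(fr$n_complete, 0L)
  expect_identical(fr$n_eligible, 0L)
})
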