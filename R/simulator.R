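#' @title Synthetic respondent simulator
#'
#' @description Personas are simulated respondent classes: demographic
#'   distributions, reported substances, a completion probability, and a
#'   knowledge model giving per-category correctness probabilities.
#'   Item-level responses are conditionally independent given the
#'   persona (the simplest model consistent with per-item accuracy
#'   reporting); wrong multiple-choice answers are uniform over the
#'   incorrect options. Every generator is reproducible under a seed.
#' @name simulator
NULL

SESSION_STAGES <- c("age", "county_quiz", "substances", "drug_quiz")

#' Construct a persona
#'
#' @param persona_id Identifier.
#' @param age_values,age_weights Reported-age distribution (weights are
#'   normalized).
#' @param county_weights Named weights over reported counties (county
#'   ids or `"outside"`).
#' @param substance_sets List of `list(drugs = <chr>, most_often_weights
#'   = <named numeric or NULL>)`; together with `substance_weights` this
#'   is the distribution of the reported 30-day checklist.
#' @param p_used_24h Probability of reporting opioid use in the past 24
#'   hours (the UDT gate).
#' @param knowledge Named numeric vector of per-category correctness
#'   probabilities; categories not named fall back to structural
#'   guessing `|correct|/|options|`.
#' @param p_complete Probability the session is completed.
#' @param truly_eligible Ground-truth eligibility of the class, used by
#'   the operating-characteristics oracle.
#' @return A `persona` object.
#' @export
persona <- function(persona_id, age_values, age_weights = NULL,
                    county_weights, substance_sets,
                    substance_weights = NULL, p_used_24h = 0,
                    knowledge = numeric(), p_complete = 1,
                    truly_eligible = FALSE) {
  if (is.null(age_weights)) {
    age_weights <- rep(1 / length(age_values), length(age_values))
  }
  if (is.null(substance_weights)) {
    substance_weights <- rep(1 / length(substance_sets),
                             length(substance_sets))
  }
  norm <- function(w) {
    stopifnot(all(w >= 0), sum(w) > 0)
    w / sum(w)
  }
  stopifnot(length(age_values) == length(age_weights),
            length(substance_sets) == length(substance_weights),
            p_complete >= 0, p_complete <= 1,
            p_used_24h >= 0, p_used_24h <= 1,
            all(knowledge >= 0), all(knowledge <= 1))
  for (s in substance_sets) {
    mo <- s$most_often_weights
    if (!is.null(mo)) stopifnot(all(names(mo) %in% s$drugs))
  }
  structure(
    list(persona_id = persona_id, age_values = as.integer(age_values),
         age_weights = norm(age_weights),
         county_weights = norm(county_weights),
         substance_sets = substance_sets,
         substance_weights = norm(substance_weights),
         p_used_24h = p_used_24h, knowledge = knowledge,
         p_complete = p_complete, truly_eligible = isTRUE(truly_eligible)),
    class = "persona"
  )
}

#' Construct a population specification
#'
#' @param personas List of [persona()]s.
#' @param weights Mixing weights (normalized) or `NULL` for equal.
#' @param seed Integer seed owned by the spec.
#' @return A `population_spec` object.
#' @export
population_spec <- function(personas, weights = NULL, seed = 1L) {
  stopifnot(all(vapply(personas, inherits, TRUE, "persona")))
  if (is.null(weights)) weights <- rep(1, length(personas))
  stopifnot(length(weights) == length(personas), all(weights >= 0),
            sum(weights) > 0)
  structure(list(personas = personas, weights = weights / sum(weights),
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' The shipped persona library
#'
#' Six classes spanning the screen's failure modes: a knowledgeable
#' eligible resident, an eligible recent mover (weaker on
#' school-related topics), an out-of-area guesser who falsely claims an
#' eligible county and guesses on every item, an underage user, a
#' nonopioid-only user, and an abandoner who rarely completes.
#' Knowledge probabilities for the eligible classes follow the observed
#' per-item accuracies of the study population (cap size 0.946, street
#' price 0.970, heroin image 0.994, prescription dose 0.95, county items
#' 0.98).
#'
#' @param flow A [screening_flow_spec()] supplying county ids.
#' @return Named list of [persona()]s.
#' @export
default_personas <- function(flow) {
  cty <- flow$eligible_counties
  even <- stats::setNames(rep(1 / 5, 5), cty)
  know_county <- stats::setNames(rep(0.98, 10),
                                 c(PARALLEL_CATEGORIES,
                                   "mascot", "school_colors", "festival",
                                   "pizza"))
  know_drugs <- c(cap_size = 0.946, price = 0.970, dose = 0.95,
                  image = 0.9)
  opioid_sets <- list(
    list(drugs = "heroin", most_often_weights = c(heroin = 1)),
    list(drugs = c("buprenorphine_pill", "methamphetamine"),
         most_often_weights = c(buprenorphine_pill = 1)),
    list(drugs = "percocet", most_often_weights = c(percocet = 1))
  )
  opioid_set_w <- c(0.5, 0.3, 0.2)
  list(
    eligible_knowledgeable = persona(
      "eligible_knowledgeable", 18:35, county_weights = even,
      substance_sets = opioid_sets, substance_weights = opioid_set_w,
      p_used_24h = 0.3, knowledge = c(know_county, know_drugs),
      p_complete = 0.9, truly_eligible = TRUE),
    eligible_recent_mover = persona(
      "eligible_recent_mover", 18:35, county_weights = even,
      substance_sets = opioid_sets, substance_weights = opioid_set_w,
      p_used_24h = 0.3,
      knowledge = c(replace(know_county,
                            c("mascot", "school_colors"), 0.5),
                    know_drugs),
      p_complete = 0.9, truly_eligible = TRUE),
    out_of_area_guesser = persona(
      "out_of_area_guesser", 18:35, county_weights = even,
      substance_sets = list(list(drugs = "heroin",
                                 most_often_weights = c(heroin = 1))),
      knowledge = numeric(),  # pure structural guessing everywhere
      p_complete = 0.9, truly_eligible = FALSE),
    underage = persona(
      "underage", 16:17, county_weights = even,
      substance_sets = opioid_sets, substance_weights = opioid_set_w,
      knowledge = c(know_county, know_drugs),
      p_complete = 0.9, truly_eligible = FALSE),
    nonopioid_user = persona(
      "nonopioid_user", 18:35, county_weights = even,
      substance_sets = list(list(drugs = "methamphetamine")),
      knowledge = know_county,
      p_complete = 0.9, truly_eligible = FALSE),
    abandoner = persona(
      "abandoner", 18:35, county_weights = even,
      substance_sets = opioid_sets, substance_weights = opioid_set_w,
      p_used_24h = 0.3, knowledge = c(know_county, know_drugs),
      p_complete = 0.15, truly_eligible = TRUE)
  )
}

# sample() treats a length-1 numeric x as 1:x; always index instead
sample_from <- function(x, n, prob = NULL) {
  x[sample.int(length(x), n, replace = TRUE, prob = prob)]
}

item_success_prob <- function(knowledge, item) {
  if (!item$scorable) return(NA_real_)
  if (item$category %in% names(knowledge)) knowledge[[item$category]]
  else item_guess_prob(item)
}

answer_with_knowledge <- function(knowledge) {
  function(item) {
    if (!item$scorable) return(sample(item$options, 1L))
    p <- item_success_prob(knowledge, item)
    if (stats::runif(1) < p) {
      sample(item$correct, 1L)
    } else {
      wrong <- setdiff(item$options, item$correct)
      sample(wrong, 1L)
    }
  }
}

draw_one <- function(persona) {
  age <- sample_from(persona$age_values, 1L, persona$age_weights)
  county <- sample(names(persona$county_weights), 1L,
                   prob = persona$county_weights)
  si <- sample.int(length(persona$substance_sets), 1L,
                   prob = persona$substance_weights)
  set <- persona$substance_sets[[si]]
  mo <- if (!is.null(set$most_often_weights)) {
    sample(names(set$most_often_weights), 1L,
           prob = set$most_often_weights)
  } else NULL
  complete <- stats::runif(1) < persona$p_complete
  list(
    persona_id = persona$persona_id,
    reported_age = age,
    reported_county = county,
    reported_substances = set$drugs,
    most_often_opioid = mo,
    used_opioid_24h = stats::runif(1) < persona$p_used_24h,
    abandon_at = if (complete) NULL else sample(SESSION_STAGES, 1L),
    knowledge = persona$knowledge,
    p_correct = function(item) item_success_prob(persona$knowledge, item),
    answer = answer_with_knowledge(persona$knowledge)
  )
}

#' Sample a population of answer sources
#'
#' Draws `n` respondents from the persona mix; each answer source can be
#' run through [run_session()]. Demographics are fixed at sampling time;
#' item answers are drawn when the session presents the item (under the
#' session seed).
#'
#' @param spec A [population_spec()].
#' @param n Number of respondents.
#' @return List of answer sources (each carries its `persona_id`).
#' @export
sample_population <- function(spec, n) {
  stopifnot(inherits(spec, "population_spec"))
  withr::with_seed(spec$seed, {
    idx <- sample.int(length(spec$personas), n, replace = TRUE,
                      prob = spec$weights)
    lapply(idx, function(i) draw_one(spec$personas[[i]]))
  })
}

#' Answer source for a coached or repeated attempt
#'
#' Items already seen in previous transcripts are answered correctly
#' with probability `max(base, carryover)`, where `base` is the
#' respondent's own knowledge-model probability; unseen items are
#' answered at base knowledge. Used to study how the 5-of-10 bank draw
#' resists coaching and retakes.
#'
#' @param source An answer source (from [sample_population()]).
#' @param previous_transcripts List of transcript tibbles from earlier
#'   attempts.
#' @param carryover Probability a previously seen item is now known.
#' @return A new answer source.
#' @export
coached_retake <- function(source, previous_transcripts, carryover) {
  stopifnot(length(previous_transcripts) >= 1L,
            carryover >= 0, carryover <= 1)
  seen <- unique(unlist(lapply(previous_transcripts, `[[`, "item_id")))
  out <- source
  out$answer <- function(item) {
    if (!item$scorable) return(sample(item$options, 1L))
    base <- source$p_correct(item)
    p <- if (item$item_id %in% seen) max(base, carryover) else base
    if (stats::runif(1) < p) sample(item$correct, 1L)
    else sample(setdiff(item$options, item$correct), 1L)
  }
  out$p_correct <- function(item) {
    base <- source$p_correct(item)
    if (item$item_id %in% seen) max(base, carryover) else base
  }
  out
}

#' Vectorized cohort simulation into the record schema
#'
#' Generates `n` respondent records from a persona mix in one pass,
#' drawing the same quantities as [run_session()] (age, county, 5-of-10
#' county-quiz draw with per-item Bernoulli correctness, substance
#' checklist, drug-quiz component correctness, completion) but at array
#' scale, so oracle-vs-simulation comparisons at `n = 1e5` run in
#' seconds. Scoring is left to [screen_records()], the same re-scorer
#' the session engine uses.
#'
#' @param spec A [population_spec()].
#' @param n Cohort size.
#' @param flow,banks,catalog Screen configuration.
#' @param seed Integer seed (defaults to the spec's own).
#' @return Record tibble with an extra `persona_id` column.
#' @export
simulate_cohort <- function(spec, n, flow, banks, catalog,
                            seed = spec$seed) {
  stopifnot(inherits(spec, "population_spec"))
  withr::with_seed(seed, {
    pidx <- sample.int(length(spec$personas), n, replace = TRUE,
                       prob = spec$weights)
    rec <- empty_record(n)
    rec$respondent_id <- sprintf("sim%06d", seq_len(n))
    rec$persona_id <- vapply(spec$personas, `[[`, "", "persona_id")[pidx]

    for (pi in seq_along(spec$personas)) {
      p <- spec$personas[[pi]]
      rows <- which(pidx == pi)
      m <- length(rows)
      if (m == 0L) next
      rec$age[rows] <- sample_from(p$age_values, m, p$age_weights)
      rec$reported_county[rows] <- sample(names(p$county_weights), m,
                                          replace = TRUE,
                                          prob = p$county_weights)
      complete <- stats::runif(m) < p$p_complete
      rec$complete[rows] <- complete
      rec$used_opioid_24h[rows] <- stats::runif(m) < p$p_used_24h

      si <- sample.int(length(p$substance_sets), m, replace = TRUE,
                       prob = p$substance_weights)
      rec$reported_substances[rows] <- vapply(si, function(i) {
        paste(p$substance_sets[[i]]$drugs, collapse = ";")
      }, "")
      rec$most_often_opioid[rows] <- vapply(si, function(i) {
        mo <- p$substance_sets[[i]]$most_often_weights
        if (is.null(mo)) NA_character_
        else sample(names(mo), 1L, prob = mo)
      }, "")

      # county quiz: 5-of-10 draw per respondent, Bernoulli per item
      for (cty in intersect(unique(rec$reported_county[rows]),
                            flow$eligible_counties)) {
        r2 <- rows[rec$reported_county[rows] == cty]
        prof <- knowledge_success_profile(p$knowledge, banks[[cty]])
        k <- flow$county_quiz$draw_size
        drawn <- vapply(seq_along(r2),
                        function(i) sample.int(length(prof), k),
                        integer(k))
        pmat <- matrix(prof[drawn], nrow = k)
        cmat <- matrix(stats::runif(k * length(r2)), nrow = k) < pmat
        for (j in seq_len(k)) {
          rec[[paste0("county_item", j)]][r2] <- cmat[j, ]
        }
      }

      # drug quiz components for the most-often opioid
      mos <- rec$most_often_opioid[rows]
      for (d in unique(stats::na.omit(mos))) {
        r2 <- rows[!is.na(mos) & mos == d]
        dq <- drug_quiz_spec(catalog, d)
        for (cmp in names(dq$items)) {
          it <- dq$items[[cmp]]
          if (!it$scorable || !cmp %in% DRUG_COMPONENTS) next
          pr <- item_success_prob(p$knowledge, it)
          rec[[paste0("comp_", cmp)]][r2] <-
            stats::runif(length(r2)) < pr
        }
      }
    }

    # abandoned sessions: blank the fields after the abandonment stage
    inc <- which(!rec$complete)
    if (length(inc)) {
      stage <- sample(SESSION_STAGES, length(inc), replace = TRUE)
      blank_from <- function(rows2, cols) {
        for (cl in cols) rec[[cl]][rows2] <<- NA
      }
      item_cols <- paste0("county_item", 1:5)
      comp_cols <- paste0("comp_", DRUG_COMPONENTS)
      blank_from(inc[stage == "age"],
                 c("age", "reported_county", "reported_substances",
                   "most_often_opioid", item_cols, comp_cols))
      blank_from(inc[stage == "county_quiz"],
                 c("reported_substances", "most_often_opioid", item_cols,
                   comp_cols))
      blank_from(inc[stage == "substances"],
                 c("reported_substances", "most_often_opioid", comp_cols))
      blank_from(inc[stage == "drug_quiz"], comp_cols)
    }
    rec
  })
}
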