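#' @title Screening engine
#'
#' @description Executes one respondent session through the branching
#'   eligibility flow (age, county report, county quiz, substance
#'   checklist, drug quiz) and scores the result; also provides a
#'   vectorized re-scorer for record tables and the funnel aggregator.
#'   Masking behaviour is preserved: out-of-area respondents get the
#'   generic unscored bank, non-opioid users get an unscored three-item
#'   quiz, and the flow never terminates early on failure.
#' @name engine
NULL

INELIGIBILITY_REASONS <- c("no_substance", "age", "outside_area",
                           "county_quiz_fail", "drug_quiz_fail")

#' Draw the county quiz from a bank
#'
#' Uniform without-replacement draw of `spec$draw_size` items;
#' presentation order is draw order. A bank is used (rather than a fixed
#' quiz) so that coaching or repeated attempts face different questions.
#'
#' @param bank A [question_bank()].
#' @param spec A [county_quiz_spec()].
#' @param seed Optional integer; when given the draw is reproducible,
#'   otherwise the caller's RNG stream is used.
#' @return List of `quiz_item`s of length `draw_size`.
#' @export
draw_county_quiz <- function(bank, spec = county_quiz_spec(), seed = NULL) {
  n <- length(bank$items)
  if (n < spec$draw_size) {
    stop("bank '", bank$bank_id, "' has ", n, " items; cannot draw ",
         spec$draw_size, call. = FALSE)
  }
  draw <- function() sample.int(n, spec$draw_size)
  idx <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  bank$items[idx]
}

#' Score a county quiz
#'
#' @param items Items as presented (list of `quiz_item`).
#' @param responses Character vector of chosen options, named by
#'   `item_id` (or unnamed, in presentation order).
#' @param spec A [county_quiz_spec()].
#' @return List with `score` (count correct), `pass` (`score >=
#'   pass_threshold`; `NA` for an unscored quiz), and `correct` (per-item
#'   logical, `NA` for unscorable items).
#' @export
score_county_quiz <- function(items, responses, spec = county_quiz_spec()) {
  ids <- vapply(items, `[[`, "", "item_id")
  if (!is.null(names(responses))) {
    extra <- setdiff(names(responses), ids)
    if (length(extra)) {
      stop("response to unpresented item(s): ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    responses <- responses[ids]
  }
  if (length(responses) != length(items) || anyNA(responses)) {
    stop("expected exactly ", length(items), " responses", call. = FALSE)
  }
  correct <- vapply(seq_along(items), function(i) {
    it <- items[[i]]
    if (!it$scorable) return(NA)
    responses[[i]] %in% it$correct
  }, NA)
  scorable <- vapply(items, `[[`, TRUE, "scorable")
  if (!spec$scored || !any(scorable)) {
    return(list(score = NA_integer_, pass = NA, correct = correct))
  }
  score <- sum(correct, na.rm = TRUE)
  list(score = as.integer(score), pass = score >= spec$pass_threshold,
       correct = correct)
}

#' Score a drug quiz
#'
#' Grades each presented component against its item key and applies the
#' pass rule: an OR over the scored components (heroin: cap size or
#' price; prescription-class: dose or image). Unscored components are
#' graded and recorded but ignored by the rule. Synthetic-opioid specs
#' auto-pass; nonopioid masking specs return `NA` (not applicable).
#'
#' @param spec A [drug_quiz_spec()].
#' @param responses Named list/character of chosen options per presented
#'   component.
#' @return List with `component_outcomes` (named logical; `NA` for
#'   unscorable items) and `pass` (logical; `TRUE` for auto-pass, `NA`
#'   for not-applicable).
#' @export
score_drug_quiz <- function(spec, responses) {
  stopifnot(inherits(spec, "drug_quiz_spec"))
  outcomes <- vapply(names(spec$items), function(cmp) {
    it <- spec$items[[cmp]]
    ch <- responses[[cmp]]
    if (is.null(ch)) return(NA)
    if (!it$scorable) return(NA)
    ch %in% it$correct
  }, NA)
  if (spec$auto_pass) {
    return(list(component_outcomes = outcomes, pass = TRUE))
  }
  if (!spec$applicable) {
    return(list(component_outcomes = outcomes, pass = NA))
  }
  missing <- spec$scored[vapply(spec$scored,
                                function(cmp) is.null(responses[[cmp]]),
                                TRUE)]
  if (length(missing)) {
    stop("missing scored-component response(s) for '", spec$drug_id,
         "': ", paste(missing, collapse = ", "), call. = FALSE)
  }
  list(component_outcomes = outcomes,
       pass = any(outcomes[spec$scored], na.rm = TRUE))
}

#' An empty (or blank) record table in the common schema
#'
#' Every stage of the pipeline (session engine, simulator, fixture
#' synthesizer) exchanges respondent data in this schema: reported
#' fields plus per-item and per-component correctness flags (`NA` =
#' not presented / not applicable).
#'
#' @param n Number of blank rows (default 0).
#' @return Tibble with `n` rows.
#' @export
empty_record <- function(n = 0L) {
  tibble::tibble(
    respondent_id = rep(NA_character_, n), complete = rep(TRUE, n),
    age = rep(NA_integer_, n),
    reported_county = rep(NA_character_, n),
    reported_substances = rep(NA_character_, n),
    most_often_opioid = rep(NA_character_, n),
    used_opioid_24h = rep(FALSE, n),
    county_item1 = rep(NA, n), county_item2 = rep(NA, n),
    county_item3 = rep(NA, n), county_item4 = rep(NA, n),
    county_item5 = rep(NA, n),
    comp_dose = rep(NA, n), comp_image = rep(NA, n),
    comp_cap_size = rep(NA, n), comp_price = rep(NA, n)
  )
}

#' Run one respondent through the screening flow
#'
#' Branch order: age, county report, county quiz (scored bank for an
#' eligible county, generic unscored bank otherwise), substance
#' checklist, most-often opioid (the follow-up lists opioids only, so a
#' respondent co-reporting nonopioids is still quizzed on an opioid),
#' then the drug quiz -- or the unscored nonopioid masking quiz for
#' nonopioid-only users. Failing a quiz never shortens the flow, and
#' abandonment yields `complete = FALSE` with a partial transcript.
#'
#' @param source An answer source: a list with `reported_age`,
#'   `reported_county`, `reported_substances` (character vector, may be
#'   empty), `most_often_opioid` (optional), `used_opioid_24h`, optional
#'   `abandon_at` (one of `"age"`, `"county_quiz"`, `"substances"`,
#'   `"drug_quiz"`), and `answer(item)` returning a chosen option id.
#' @param flow A [screening_flow_spec()].
#' @param banks Named list of [question_bank()]s (must include
#'   `"generic"`).
#' @param catalog A [drug_catalog()].
#' @param seed Integer seed making the session (quiz draw and any
#'   stochastic answering) reproducible.
#' @param respondent_id Identifier stored in the transcript.
#' @return List with `transcript` (tibble: stage, item_id, category,
#'   chosen, correct), `record` (one-row tibble in the common record
#'   schema), and `result` (one-row tibble as from [screen_records()]).
#' @export
run_session <- function(source, flow, banks, catalog, seed,
                        respondent_id = "r1") {
  withr::with_seed(seed, {
    entries <- list()
    log_item <- function(stage, item, chosen) {
      entries[[length(entries) + 1L]] <<- tibble::tibble(
        stage = stage, item_id = item$item_id, category = item$category,
        chosen = as.character(chosen),
        correct = if (item$scorable) chosen %in% item$correct else NA)
    }
    abandon <- source$abandon_at %||% NA_character_
    rec <- empty_record(1L)
    rec$respondent_id <- respondent_id
    rec$used_opioid_24h <- isTRUE(source$used_opioid_24h)
    done <- function(stage) !is.na(abandon) && identical(abandon, stage)

    finish <- function(complete) {
      rec$complete <- complete
      transcript <- if (length(entries)) do.call(rbind, entries)
                    else tibble::tibble(stage = character(),
                                        item_id = character(),
                                        category = character(),
                                        chosen = character(),
                                        correct = logical())
      result <- screen_records(rec, flow, catalog)
      list(transcript = transcript, record = rec, result = result)
    }

    # age
    if (done("age")) return(finish(FALSE))
    rec$age <- as.integer(source$reported_age)

    # county report + quiz
    rec$reported_county <- as.character(source$reported_county)
    eligible_cty <- rec$reported_county %in% flow$eligible_counties
    bank <- if (eligible_cty) banks[[rec$reported_county]]
            else banks[["generic"]]
    cq_spec <- flow$county_quiz
    if (!eligible_cty) cq_spec$scored <- FALSE
    items <- draw_county_quiz(bank, cq_spec)
    if (done("county_quiz")) return(finish(FALSE))
    chosen <- vapply(items, function(it) as.character(source$answer(it)), "")
    for (i in seq_along(items)) log_item("county_quiz", items[[i]], chosen[i])
    cq <- score_county_quiz(items, chosen, cq_spec)
    for (i in 1:5) rec[[paste0("county_item", i)]] <- cq$correct[i]

    # substance checklist
    if (done("substances")) return(finish(FALSE))
    subs <- as.character(source$reported_substances %||% character())
    rec$reported_substances <- paste(subs, collapse = ";")
    opioids <- subs[vapply(subs, function(d) is_opioid(catalog, d), TRUE)]
    rec$most_often_opioid <- NA_character_
    quiz_drug <- NULL
    if (length(opioids)) {
      mo <- source$most_often_opioid %||% opioids[[1L]]
      if (!mo %in% opioids) {
        stop("most_often_opioid '", mo, "' not among reported opioids",
             call. = FALSE)
      }
      rec$most_often_opioid <- mo
      quiz_drug <- mo
    } else if (length(subs)) {
      quiz_drug <- subs[[1L]]  # nonopioid masking quiz
    }

    # drug quiz (or masking quiz); none reported -> skipped entirely
    if (!is.null(quiz_drug)) {
      if (done("drug_quiz")) return(finish(FALSE))
      dq <- drug_quiz_spec(catalog, quiz_drug)
      responses <- list()
      for (cmp in names(dq$items)) {
        it <- dq$items[[cmp]]
        ch <- as.character(source$answer(it))
        responses[[cmp]] <- ch
        log_item("drug_quiz", it, ch)
        # incorrect dose branches to the all-doses image question, so the
        # respondent still has a chance to identify the correct image;
        # with abstract options the all-doses item is the one presented,
        # so no extra item is needed here.
      }
      sc <- score_drug_quiz(dq, responses)
      for (cmp in intersect(names(sc$component_outcomes), DRUG_COMPONENTS)) {
        rec[[paste0("comp_", cmp)]] <- sc$component_outcomes[[cmp]]
      }
    }
    finish(TRUE)
  })
}

#' Re-score a record table with the real screening rules
#'
#' Vectorized over a table in the common record schema (per-item and
#' per-component correctness flags plus the reported fields); pass/fail
#' and ineligibility reasons emerge from the same rules the session
#' engine applies. Reasons are non-exclusive; a record can be ineligible
#' on several criteria at once.
#'
#' @param records Tibble in the schema of [empty_record()].
#' @param flow A [screening_flow_spec()].
#' @param catalog A [drug_catalog()].
#' @return Tibble with one row per record: `age_ok`,
#'   `residence_reported_ok`, `county_quiz_score`, `county_quiz_pass`,
#'   `substance_reported_ok`, `drug_quiz_pass`, `eligible`, and one
#'   logical `reason_*` column per ineligibility reason.
#' @export
screen_records <- function(records, flow, catalog) {
  n <- nrow(records)
  age_ok <- !is.na(records$age) &
    records$age >= flow$age_range[1] & records$age <= flow$age_range[2]
  residence_ok <- !is.na(records$reported_county) &
    records$reported_county %in% flow$eligible_counties
  item_mat <- as.matrix(records[paste0("county_item", 1:5)])
  presented <- rowSums(!is.na(item_mat)) > 0L
  score <- ifelse(residence_ok & presented,
                  rowSums(item_mat, na.rm = TRUE), NA_integer_)
  county_pass <- ifelse(residence_ok & presented,
                        score >= flow$county_quiz$pass_threshold, NA)

  subs <- strsplit(as.character(ifelse(is.na(records$reported_substances),
                                       "", records$reported_substances)),
                   ";", fixed = TRUE)
  opioid_ids <- names(catalog)[vapply(names(catalog),
                                      function(d) is_opioid(catalog, d),
                                      TRUE)]
  substance_ok <- vapply(subs, function(s) any(s %in% opioid_ids), TRUE)

  mo_class <- rep(NA_character_, n)
  has_mo <- !is.na(records$most_often_opioid)
  mo_class[has_mo] <- vapply(records$most_often_opioid[has_mo],
                             function(d) drug_class_of(catalog, d), "")
  or_na <- function(a, b) {
    # OR treating NA as "not presented" (counts as incorrect)
    out <- (a %in% TRUE) | (b %in% TRUE)
    out
  }
  drug_pass <- rep(NA, n)
  drug_pass[mo_class %in% "heroin"] <-
    or_na(records$comp_cap_size, records$comp_price)[mo_class %in% "heroin"]
  rx <- mo_class %in% c("prescription_opioid", "buprenorphine", "methadone")
  drug_pass[rx] <- or_na(records$comp_dose, records$comp_image)[rx]
  drug_pass[mo_class %in% "synthetic_opioid"] <- TRUE

  complete <- records$complete %in% TRUE
  eligible <- complete & age_ok & residence_ok & (county_pass %in% TRUE) &
    substance_ok & (drug_pass %in% TRUE)

  tibble::tibble(
    respondent_id = records$respondent_id,
    complete = complete,
    age_ok = age_ok,
    residence_reported_ok = residence_ok,
    county_quiz_score = as.integer(score),
    county_quiz_pass = county_pass,
    substance_reported_ok = substance_ok,
    drug_quiz_pass = drug_pass,
    eligible = eligible,
    reason_incomplete = !complete,
    reason_age = complete & !age_ok,
    reason_outside_area = complete & !residence_ok,
    reason_no_substance = complete & !substance_ok,
    reason_county_quiz_fail = complete & residence_ok &
      (county_pass %in% FALSE),
    reason_drug_quiz_fail = complete & substance_ok &
      (drug_pass %in% FALSE)
  )
}

#' Aggregate screening results into a funnel report
#'
#' Counts every node of the screening funnel. Percentage denominators
#' use complete entries only; incomplete sessions are counted but
#' excluded from eligibility. Reasons are tallied both non-exclusively
#' (a record can appear under several) and by first failure in flow
#' order (age, outside area, county quiz, no substance, drug quiz).
#'
#' @param results Tibble from [screen_records()].
#' @return A `funnel_report` list.
#' @export
classify_funnel <- function(results) {
  n_total <- nrow(results)
  complete <- results$complete %in% TRUE
  n_complete <- sum(complete)
  n_eligible <- sum(results$eligible %in% TRUE)
  n_ineligible <- n_complete - n_eligible
  inelig <- complete & !(results$eligible %in% TRUE)
  reasons <- c(
    no_substance = sum(results$reason_no_substance & inelig),
    age = sum(results$reason_age & inelig),
    outside_area = sum(results$reason_outside_area & inelig),
    county_quiz_fail = sum(results$reason_county_quiz_fail & inelig),
    drug_quiz_fail = sum(results$reason_drug_quiz_fail & inelig)
  )
  first_fail <- integer(length(INELIGIBILITY_REASONS))
  names(first_fail) <- INELIGIBILITY_REASONS
  order_cols <- c("reason_age", "reason_outside_area",
                  "reason_county_quiz_fail", "reason_no_substance",
                  "reason_drug_quiz_fail")
  taken <- rep(FALSE, n_total)
  for (col in order_cols) {
    hit <- inelig & !taken & (results[[col]] %in% TRUE)
    nm <- sub("^reason_", "", col)
    first_fail[nm] <- sum(hit)
    taken <- taken | hit
  }
  structure(
    list(n_total = n_total, n_incomplete = n_total - n_complete,
         n_complete = n_complete, n_eligible = n_eligible,
         n_ineligible = n_ineligible, reasons = reasons,
         first_failure = first_fail[INELIGIBILITY_REASONS]),
    class = "funnel_report"
  )
}

#' @export
print.funnel_report <- function(x, ...) {
  pctc <- function(num, den) {
    if (den == 0) return(sprintf("%d", num))
    sprintf("%d (%.1f%%)", num, 100 * num / den)
  }
  cat("Screening funnel\n")
  cat(sprintf("  entries              %d\n", x$n_total))
  cat(sprintf("  incomplete           %s\n", pctc(x$n_incomplete, x$n_total)))
  cat(sprintf("  complete             %d\n", x$n_complete))
  cat(sprintf("  eligible             %s\n", pctc(x$n_eligible, x$n_complete)))
  cat(sprintf("  ineligible           %s\n",
              pctc(x$n_ineligible, x$n_complete)))
  cat("  reasons (non-exclusive, of ineligible):\n")
  for (r in names(x$reasons)) {
    cat(sprintf("    %-19s%s\n", r, pctc(x$reasons[[r]],
                                         max(x$n_ineligible, 1L))))
  }
  invisible(x)
}
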