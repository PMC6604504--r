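#' @title Drug catalog and drug quiz specifications
#'
#' @description The catalog registers each quizzable drug: its class
#'   (which decides the quiz form and pass rule), manufactured doses and
#'   decoys for the 50/50 dose question, and for heroin the local purchase
#'   unit ("cap", one-tenth of a gram) and street-price bracket. Money is
#'   held in integer US cents.
#' @name drug-catalog
NULL

#' Construct a catalog entry for one drug (or drug/formulation)
#'
#' @param drug_id Identifier (ASCII), e.g. `"roxicodone"`,
#'   `"buprenorphine_pill"`.
#' @param drug_class One of `r paste0('"', DRUG_CLASSES, '"', collapse=", ")`.
#' @param formulation Optional formulation tag (`"pill"`, `"strip"`,
#'   `"liquid"`, ...).
#' @param true_doses,decoy_doses Numeric mg vectors for the dose question
#'   (prescription-class drugs must register at least one true dose).
#' @param price_brackets_cents List of `c(lo, hi)` cents intervals offered
#'   for the price question (`hi = Inf` allowed); `price_correct` is the
#'   index of the correct bracket. Used for heroin; prescription street
#'   price is an unscored open-ended question.
#' @param cap_size_answer_g Correct cap size in grams (heroin only).
#' @param cap_size_options_g Offered cap sizes in grams.
#' @return A `drug_entry` object.
#' @export
drug_entry <- function(drug_id, drug_class, formulation = NA_character_,
                       true_doses = numeric(), decoy_doses = numeric(),
                       price_brackets_cents = NULL, price_correct = NA_integer_,
                       cap_size_answer_g = NA_real_,
                       cap_size_options_g = NULL) {
  drug_class <- match.arg(drug_class, DRUG_CLASSES)
  if (drug_class %in% c("prescription_opioid", "buprenorphine", "methadone") &&
      length(true_doses) == 0L) {
    stop("drug '", drug_id, "': prescription-class drugs need >= 1 true dose",
         call. = FALSE)
  }
  if (drug_class == "heroin") {
    stopifnot(!is.na(cap_size_answer_g), !is.null(price_brackets_cents),
              !is.na(price_correct))
  }
  structure(
    list(drug_id = as.character(drug_id), drug_class = drug_class,
         formulation = formulation,
         true_doses = as.numeric(true_doses),
         decoy_doses = as.numeric(decoy_doses),
         price_brackets_cents = price_brackets_cents,
         price_correct = as.integer(price_correct),
         cap_size_answer_g = cap_size_answer_g,
         cap_size_options_g = as.numeric(cap_size_options_g)),
    class = "drug_entry"
  )
}

#' Construct a drug catalog
#'
#' @param entries List of [drug_entry()] objects.
#' @return Named list of entries with class `drug_catalog`.
#' @export
drug_catalog <- function(entries) {
  stopifnot(all(vapply(entries, inherits, TRUE, "drug_entry")))
  ids <- vapply(entries, `[[`, "", "drug_id")
  if (anyDuplicated(ids)) stop("duplicated drug_ids", call. = FALSE)
  structure(stats::setNames(entries, ids), class = "drug_catalog")
}

#' Drug class of a catalog drug
#'
#' @param catalog A `drug_catalog`.
#' @param drug_id Drug identifier.
#' @return Character scalar.
#' @export
drug_class_of <- function(catalog, drug_id) {
  if (!drug_id %in% names(catalog)) {
    stop("unknown drug '", drug_id, "'", call. = FALSE)
  }
  catalog[[drug_id]]$drug_class
}

#' Is a catalog drug an opioid?
#' @inheritParams drug_class_of
#' @return Logical scalar.
#' @export
is_opioid <- function(catalog, drug_id) {
  drug_class_of(catalog, drug_id) %in% OPIOID_CLASSES
}

#' Build the quiz specification for one drug
#'
#' The quiz form follows the drug class:
#' * heroin: cap-size and street-price questions (scored, pass = either
#'   correct) plus the 10-image recognition question (recorded, unscored);
#' * prescription opioids, buprenorphine, methadone: dose and image
#'   questions under the 50/50 rule (scored, pass = either correct); an
#'   incorrect dose answer branches to the all-doses image question; the
#'   open-ended street price is unscored;
#' * synthetic opioids: three unscored questions, automatic pass (the
#'   market moves too fast for a scorable key);
#' * nonopioids: a three-question masking quiz, never scored, so scored
#'   quizzes do not reveal the eligibility criteria.
#'
#' @param catalog A `drug_catalog`.
#' @param drug_id Drug identifier.
#' @param seed Optional seed for option shuffling.
#' @return A `drug_quiz_spec` object with fields `drug_id`, `drug_class`,
#'   `scored` (component names entering the pass rule), `auto_pass`,
#'   `applicable`, and `items` (named by component).
#' @export
drug_quiz_spec <- function(catalog, drug_id, seed = NULL) {
  drug <- catalog[[drug_id]]
  if (is.null(drug)) stop("unknown drug '", drug_id, "'", call. = FALSE)
  cls <- drug$drug_class
  items <- list()
  scored <- character()
  auto_pass <- FALSE
  applicable <- TRUE
  if (cls == "heroin") {
    cap_opts <- paste0(drug$cap_size_options_g, "g")
    cap_correct <- paste0(drug$cap_size_answer_g, "g")
    items$cap_size <- quiz_item("heroin_cap_size", "multiple_choice",
                                cap_opts, cap_correct, "cap_size")
    br <- drug$price_brackets_cents
    lab <- vapply(br, function(b) {
      if (is.infinite(b[2])) sprintf("over $%d", b[1] %/% 100L)
      else sprintf("$%d-$%d", b[1] %/% 100L, b[2] %/% 100L)
    }, "")
    items$price <- quiz_item("heroin_price", "multiple_choice", lab,
                             lab[drug$price_correct], "price")
    items$image <- build_heroin_image_item(seed)
    scored <- c("cap_size", "price")
  } else if (cls %in% c("prescription_opioid", "buprenorphine", "methadone")) {
    items$dose <- build_dose_item(drug_id, drug$true_doses,
                                  drug$decoy_doses, seed)
    items$image <- build_image_item(drug, "all", seed)
    scored <- c("dose", "image")
  } else if (cls == "synthetic_opioid") {
    items$source <- quiz_item(paste0(drug_id, "_source"), "multiple_choice",
                              c("online", "gas_station", "paraphernalia_store",
                                "other"), character(), "source",
                              scorable = FALSE)
    items$form <- quiz_item(paste0(drug_id, "_form"), "multiple_choice",
                            c("pills", "powder", "liquid", "other"),
                            character(), "form", scorable = FALSE)
    auto_pass <- TRUE
  } else {  # nonopioid masking quiz
    items$color <- quiz_item(paste0(drug_id, "_color"), "multiple_choice",
                             c("white", "brown", "clear", "other"),
                             character(), "color", scorable = FALSE)
    items$texture <- quiz_item(paste0(drug_id, "_texture"), "multiple_choice",
                               c("pill", "liquid", "powder", "rocks", "other"),
                               character(), "texture", scorable = FALSE)
    applicable <- FALSE
  }
  structure(
    list(drug_id = drug_id, drug_class = cls, scored = scored,
         auto_pass = auto_pass, applicable = applicable, items = items),
    class = "drug_quiz_spec"
  )
}

#' Per-component success probabilities for a pure guesser
#'
#' @param spec A `drug_quiz_spec`.
#' @return Named numeric vector over the scored components.
#' @export
drug_guess_profile <- function(spec) {
  stopifnot(inherits(spec, "drug_quiz_spec"))
  vapply(spec$scored, function(cmp) item_guess_prob(spec$items[[cmp]]),
         numeric(1))
}
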