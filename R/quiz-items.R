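#' @title Quiz items and question banks
#'
#' @description Domain types for the eligibility screen: a single quiz
#'   question (`quiz_item`), a county's 10-item bank (`question_bank`), and
#'   the draw/pass rule for the county quiz (`county_quiz_spec`). Items are
#'   abstract: an option is an identifier carrying a correct/incorrect
#'   label, which is all the scoring rules need (images are modelled the
#'   same way, without binary assets).
#' @name quiz-items
NULL

# The six local-knowledge topics asked identically in every eligible
# county's bank; the remaining four bank items vary by county.
PARALLEL_CATEGORIES <- c(
  "largest_town", "smallest_communities", "jail", "walmart",
  "landmark", "grocery"
)

COUNTY_SPECIFIC_CATEGORIES <- c(
  "mascot", "school_colors", "festival", "pizza", "towns", "courthouse"
)

DRUG_COMPONENTS <- c("dose", "image", "cap_size", "price")

DRUG_CLASSES <- c(
  "heroin", "prescription_opioid", "buprenorphine", "methadone",
  "synthetic_opioid", "nonopioid"
)

OPIOID_CLASSES <- setdiff(DRUG_CLASSES, "nonopioid")

#' Construct a quiz item
#'
#' @param item_id Unique identifier.
#' @param kind `"yes_no"` or `"multiple_choice"`.
#' @param options Character vector of option identifiers, in presentation
#'   order.
#' @param correct Character vector: the subset of `options` labelled
#'   correct. May be empty only when `scorable = FALSE` (masking items,
#'   e.g. the generic county bank, carry no answer key).
#' @param category Topic tag (e.g. `"jail"`, `"dose"`, `"image"`).
#' @param scorable Whether the item carries an answer key.
#' @return A `quiz_item` object.
#' @export
quiz_item <- function(item_id, kind, options, correct, category,
                      scorable = TRUE) {
  kind <- match.arg(kind, c("yes_no", "multiple_choice"))
  stopifnot(is.character(options), length(options) >= 2L)
  if (anyDuplicated(options)) {
    stop("quiz_item '", item_id, "': duplicated options", call. = FALSE)
  }
  if (kind == "yes_no" && length(options) != 2L) {
    stop("quiz_item '", item_id, "': yes_no items have exactly 2 options",
         call. = FALSE)
  }
  correct <- as.character(correct)
  if (scorable) {
    if (length(correct) == 0L || length(correct) >= length(options)) {
      stop("quiz_item '", item_id,
           "': correct must be a nonempty strict subset of options",
           call. = FALSE)
    }
    if (!all(correct %in% options)) {
      stop("quiz_item '", item_id, "': correct options not among options",
           call. = FALSE)
    }
  } else if (length(correct) != 0L) {
    stop("quiz_item '", item_id, "': unscorable item with an answer key",
         call. = FALSE)
  }
  structure(
    list(item_id = as.character(item_id), kind = kind, options = options,
         correct = correct, category = as.character(category),
         scorable = isTRUE(scorable)),
    class = "quiz_item"
  )
}

#' @export
print.quiz_item <- function(x, ...) {
  cat(sprintf("<quiz_item %s [%s/%s] %d options, %d correct%s>\n",
              x$item_id, x$kind, x$category, length(x$options),
              length(x$correct), if (x$scorable) "" else ", unscored"))
  invisible(x)
}

#' Probability a pure guesser answers an item correctly
#'
#' `|correct| / |options|` for a scorable item; `NA` for masking items.
#'
#' @param item A `quiz_item`.
#' @return Probability in \[0, 1\], or `NA_real_`.
#' @export
item_guess_prob <- function(item) {
  stopifnot(inherits(item, "quiz_item"))
  if (!item$scorable) return(NA_real_)
  length(item$correct) / length(item$options)
}

#' Construct a county question bank
#'
#' Eligible-county banks hold exactly 10 items: 6 on the parallel
#' cross-county topics and 4 on county-specific topics. The `"generic"`
#' bank, shown to respondents reporting a county outside the study area so
#' that the eligible counties are not unmasked, mirrors the structure but
#' its items are unscorable.
#'
#' @param bank_id County identifier, or `"generic"`.
#' @param items List of `quiz_item`s.
#' @return A `question_bank` object.
#' @export
question_bank <- function(bank_id, items) {
  stopifnot(is.list(items), all(vapply(items, inherits, TRUE, "quiz_item")))
  ids <- vapply(items, `[[`, "", "item_id")
  if (anyDuplicated(ids)) {
    stop("bank '", bank_id, "': duplicated item_ids", call. = FALSE)
  }
  if (length(items) != 10L) {
    stop("bank '", bank_id, "': county banks contain exactly 10 items, got ",
         length(items), call. = FALSE)
  }
  cats <- vapply(items, `[[`, "", "category")
  n_par <- sum(cats %in% PARALLEL_CATEGORIES)
  if (n_par != 6L) {
    stop("bank '", bank_id, "': expected 6 parallel-category items, got ",
         n_par, call. = FALSE)
  }
  generic <- identical(bank_id, "generic")
  scorable <- vapply(items, `[[`, TRUE, "scorable")
  if (generic && any(scorable)) {
    stop("bank 'generic': items must be unscorable", call. = FALSE)
  }
  if (!generic && !all(scorable)) {
    stop("bank '", bank_id, "': county items must carry answer keys",
         call. = FALSE)
  }
  structure(list(bank_id = as.character(bank_id), items = items),
            class = "question_bank")
}

#' @export
print.question_bank <- function(x, ...) {
  cat(sprintf("<question_bank %s: %d items>\n", x$bank_id, length(x$items)))
  invisible(x)
}

#' County quiz draw/pass rule
#'
#' @param draw_size Number of items drawn at random from the bank
#'   (default 5).
#' @param pass_threshold Minimum correct to pass (default 3).
#' @param scored Whether the quiz counts toward eligibility (`FALSE` for
#'   the generic masking quiz).
#' @return A `county_quiz_spec` object.
#' @export
county_quiz_spec <- function(draw_size = 5L, pass_threshold = 3L,
                             scored = TRUE) {
  draw_size <- as.integer(draw_size)
  pass_threshold <- as.integer(pass_threshold)
  stopifnot(pass_threshold >= 0L, pass_threshold <= draw_size)
  structure(list(draw_size = draw_size, pass_threshold = pass_threshold,
                 scored = isTRUE(scored)),
            class = "county_quiz_spec")
}

#' Build a dose question under the 50/50 option rule
#'
#' Multiple-choice dose questions are built so that exactly half the
#' options are real manufactured doses and half are decoys; e.g. a drug
#' made in 5, 15 and 30 mg pills yields a 6-option item with 3 correct.
#'
#' @param drug_id Drug identifier (used in option labels).
#' @param true_doses Numeric vector of real doses (mg).
#' @param decoy_doses Numeric vector of fake doses, disjoint from
#'   `true_doses`, length at least `length(true_doses)`.
#' @param seed Optional integer; when given, option order is shuffled
#'   reproducibly, otherwise the caller's RNG stream is used.
#' @return A `quiz_item` with `2m` options, `m = length(true_doses)`
#'   correct.
#' @export
build_dose_item <- function(drug_id, true_doses, decoy_doses, seed = NULL) {
  m <- length(true_doses)
  if (m == 0L) stop("no true doses for '", drug_id, "'", call. = FALSE)
  if (length(decoy_doses) < m) {
    stop("insufficient decoys for '", drug_id, "': need ", m, ", got ",
         length(decoy_doses), call. = FALSE)
  }
  if (length(intersect(true_doses, decoy_doses)) > 0L) {
    stop("decoy doses overlap true doses for '", drug_id, "': ",
         paste(intersect(true_doses, decoy_doses), collapse = ", "),
         call. = FALSE)
  }
  decoys <- decoy_doses[seq_len(m)]
  opts <- c(paste0(true_doses, "mg"), paste0(decoys, "mg"))
  correct <- opts[seq_len(m)]
  shuffle <- function() sample(opts)
  opts <- if (is.null(seed)) shuffle() else withr::with_seed(seed, shuffle())
  quiz_item(paste0(drug_id, "_dose"), "multiple_choice", opts, correct,
            "dose")
}

#' Build an image-recognition question under the 50/50 option rule
#'
#' Image options are abstract labels: one correct label per registered
#' true-dose image plus an equal number of decoy labels. With
#' `dose_context = "all"` (the branch shown after an incorrect dose
#' answer) the correct set spans the images of every true dose.
#'
#' @param drug Catalog entry (see [drug_catalog()]).
#' @param dose_context One true dose, or `"all"`.
#' @param seed Optional integer seed for option shuffling.
#' @return A `quiz_item` with half its options correct.
#' @export
build_image_item <- function(drug, dose_context = "all", seed = NULL) {
  if (is.null(drug$true_doses) || length(drug$true_doses) == 0L) {
    stop("no registered images for '", drug$drug_id, "'", call. = FALSE)
  }
  doses <- if (identical(dose_context, "all")) drug$true_doses
           else {
             if (!dose_context %in% drug$true_doses) {
               stop("unknown dose ", dose_context, " for '", drug$drug_id,
                    "'", call. = FALSE)
             }
             dose_context
           }
  correct <- paste0("img_", drug$drug_id, "_", doses, "mg")
  decoys <- paste0("img_", drug$drug_id, "_fake", seq_along(correct))
  opts <- c(correct, decoys)
  shuffle <- function() sample(opts)
  opts <- if (is.null(seed)) shuffle() else withr::with_seed(seed, shuffle())
  quiz_item(paste0(drug$drug_id, "_image_", dose_context),
            "multiple_choice", opts, correct, "image")
}

#' Build the heroin image item (10 options, 5 correct)
#'
#' Ten photographs are offered, five showing powder heroin (white through
#' dark brown) and five obvious non-heroin textures. Image recognition is
#' recorded but never scored for heroin, since injectors may only see the
#' drug dissolved.
#'
#' @param seed Optional integer seed for option shuffling.
#' @return An unscored-in-quiz `quiz_item` (the item itself carries its
#'   key; the quiz spec decides scoring).
#' @export
build_heroin_image_item <- function(seed = NULL) {
  correct <- paste0("img_heroin_powder", 1:5)
  decoys <- paste0("img_heroin_fake", 1:5)
  opts <- c(correct, decoys)
  shuffle <- function() sample(opts)
  opts <- if (is.null(seed)) shuffle() else withr::with_seed(seed, shuffle())
  quiz_item("heroin_image", "multiple_choice", opts, correct, "image")
}
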