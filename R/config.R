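#' @title Screening-flow configuration
#'
#' @description The whole screen is driven by one configuration: the flow
#'   rules (eligible counties, inclusive age range, recall windows), the
#'   county question banks, and the drug catalog. The configuration
#'   round-trips through YAML; [load_config()] validates every type
#'   invariant and reports violations with item-level paths.
#' @name config
NULL

#' Construct the screening flow specification
#'
#' @param eligible_counties Character vector of exactly 5 county ids.
#' @param age_range Inclusive integer bounds, default `c(18, 35)`.
#' @param recall_days_use Substance-use recall window in days (30).
#' @param recall_hours_udt Recency gate for UDT randomization in hours
#'   (24).
#' @param county_quiz A [county_quiz_spec()].
#' @return A `screening_flow_spec` object.
#' @export
screening_flow_spec <- function(eligible_counties, age_range = c(18L, 35L),
                                recall_days_use = 30L,
                                recall_hours_udt = 24L,
                                county_quiz = county_quiz_spec()) {
  if (length(eligible_counties) != 5L) {
    stop("flow: exactly 5 eligible counties required, got ",
         length(eligible_counties), call. = FALSE)
  }
  stopifnot(length(age_range) == 2L, age_range[1] <= age_range[2],
            inherits(county_quiz, "county_quiz_spec"))
  structure(
    list(eligible_counties = as.character(eligible_counties),
         age_range = as.integer(age_range),
         recall_days_use = as.integer(recall_days_use),
         recall_hours_udt = as.integer(recall_hours_udt),
         county_quiz = county_quiz),
    class = "screening_flow_spec"
  )
}

#' Default study configuration
#'
#' Five illustrative rural county banks (10 items each: 6 parallel
#' topics, 4 county-specific), the unscorable generic masking bank, and a
#' drug catalog covering heroin, common prescription opioids,
#' buprenorphine (pill and strip), methadone (pill and liquid), a
#' synthetic opioid, and masking nonopioids. Bank wording is invented;
#' only the structure (topics, option counts, answer keys) carries
#' meaning.
#'
#' @return A list with elements `flow`, `banks`, `catalog`.
#' @export
default_config <- function() {
  counties <- c("amberley", "beechfork", "cartwright", "dunmore", "eldridge")
  mk_bank <- function(cty, keyed = TRUE) {
    corr <- function(x) if (keyed) x else character()
    opt4 <- function(stub) paste0(cty, "_", stub, 1:4)
    items <- list(
      quiz_item(paste0(cty, "_largest_town"), "multiple_choice",
                opt4("town"), corr(paste0(cty, "_town1")), "largest_town",
                scorable = keyed),
      quiz_item(paste0(cty, "_smallest_communities"), "multiple_choice",
                paste0(cty, "_commlist", 1:5),
                corr(paste0(cty, "_commlist2")), "smallest_communities",
                scorable = keyed),
      quiz_item(paste0(cty, "_jail"), "yes_no", c("yes", "no"),
                corr("yes"), "jail", scorable = keyed),
      quiz_item(paste0(cty, "_walmart"), "yes_no", c("yes", "no"),
                corr("no"), "walmart", scorable = keyed),
      quiz_item(paste0(cty, "_landmark"), "multiple_choice",
                opt4("landmark"), corr(paste0(cty, "_landmark3")),
                "landmark", scorable = keyed),
      quiz_item(paste0(cty, "_grocery"), "multiple_choice",
                opt4("grocery"), corr(paste0(cty, "_grocery2")), "grocery",
                scorable = keyed),
      quiz_item(paste0(cty, "_mascot"), "multiple_choice",
                opt4("mascot"), corr(paste0(cty, "_mascot1")), "mascot",
                scorable = keyed),
      quiz_item(paste0(cty, "_school_colors"), "multiple_choice",
                opt4("colors"), corr(paste0(cty, "_colors4")),
                "school_colors", scorable = keyed),
      quiz_item(paste0(cty, "_festival"), "multiple_choice",
                opt4("festival"), corr(paste0(cty, "_festival2")),
                "festival", scorable = keyed),
      quiz_item(paste0(cty, "_pizza"), "yes_no", c("yes", "no"),
                corr("yes"), "pizza", scorable = keyed)
    )
    question_bank(if (keyed) cty else "generic", items)
  }
  banks <- c(stats::setNames(lapply(counties, mk_bank), counties),
             list(generic = mk_bank("generic", keyed = FALSE)))
  usd <- function(lo, hi) c(lo * 100, if (is.infinite(hi)) Inf else hi * 100)
  catalog <- drug_catalog(list(
    drug_entry("heroin", "heroin",
               cap_size_answer_g = 0.1,
               cap_size_options_g = c(0.1, 1, 5, 20),
               price_brackets_cents = list(usd(0, 10), usd(10, 50),
                                           usd(50, 75), usd(75, Inf)),
               price_correct = 2L),
    drug_entry("roxicodone", "prescription_opioid", "pill",
               true_doses = c(5, 15, 30), decoy_doses = c(10, 20, 40)),
    drug_entry("percocet", "prescription_opioid", "pill",
               true_doses = c(2.5, 5, 7.5, 10),
               decoy_doses = c(15, 20, 30, 40)),
    drug_entry("norco", "prescription_opioid", "pill",
               true_doses = c(5, 7.5, 10), decoy_doses = c(2.5, 15, 20)),
    drug_entry("lortab", "prescription_opioid", "pill",
               true_doses = c(5, 7.5, 10), decoy_doses = c(2.5, 15, 20)),
    drug_entry("tylox", "prescription_opioid", "pill",
               true_doses = 5, decoy_doses = 10),
    drug_entry("oxycontin", "prescription_opioid", "pill",
               true_doses = c(10, 20, 40, 80),
               decoy_doses = c(5, 25, 50, 100)),
    drug_entry("opana", "prescription_opioid", "pill",
               true_doses = c(5, 10, 20, 40),
               decoy_doses = c(2.5, 15, 30, 60)),
    drug_entry("tramadol", "prescription_opioid", "pill",
               true_doses = c(50, 100), decoy_doses = c(25, 75)),
    drug_entry("buprenorphine_pill", "buprenorphine", "pill",
               true_doses = c(2, 8), decoy_doses = c(4, 16)),
    drug_entry("buprenorphine_strip", "buprenorphine", "strip",
               true_doses = c(2, 8), decoy_doses = c(4, 12)),
    drug_entry("methadone_pill", "methadone", "pill",
               true_doses = c(5, 10, 40), decoy_doses = c(15, 20, 80)),
    drug_entry("methadone_liquid", "methadone", "liquid",
               true_doses = 10, decoy_doses = 5),
    drug_entry("fentanyl", "synthetic_opioid"),
    drug_entry("methamphetamine", "nonopioid"),
    drug_entry("cocaine", "nonopioid"),
    drug_entry("gabapentin", "nonopioid")
  ))
  list(flow = screening_flow_spec(counties), banks = banks,
       catalog = catalog)
}

item_to_list <- function(it) {
  list(item_id = it$item_id, kind = it$kind, category = it$category,
       options = as.list(it$options), correct = as.list(it$correct))
}

drug_to_list <- function(d) {
  out <- list(drug_class = d$drug_class)
  if (!is.na(d$formulation)) out$formulation <- d$formulation
  if (length(d$true_doses)) out$true_doses <- as.list(d$true_doses)
  if (length(d$decoy_doses)) out$decoy_doses <- as.list(d$decoy_doses)
  if (!is.null(d$price_brackets_cents)) {
    out$price_brackets_cents <- lapply(d$price_brackets_cents, as.list)
    out$price_correct <- d$price_correct
  }
  if (!is.na(d$cap_size_answer_g)) {
    out$cap_size_answer_g <- d$cap_size_answer_g
    out$cap_size_options_g <- as.list(d$cap_size_options_g)
  }
  out
}

#' Write a configuration to YAML
#'
#' @param config List with `flow`, `banks`, `catalog` (as from
#'   [default_config()] or [load_config()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  doc <- list(
    flow = list(
      eligible_counties = as.list(config$flow$eligible_counties),
      age_range = as.list(config$flow$age_range),
      recall_days_use = config$flow$recall_days_use,
      recall_hours_udt = config$flow$recall_hours_udt,
      county_quiz = list(
        draw_size = config$flow$county_quiz$draw_size,
        pass_threshold = config$flow$county_quiz$pass_threshold
      )
    ),
    banks = lapply(config$banks, function(b) lapply(b$items, item_to_list)),
    drugs = lapply(unclass(config$catalog), drug_to_list)
  )
  yaml::write_yaml(doc, path, precision = 12L)
  invisible(path)
}

#' Load and validate a configuration
#'
#' Parses a YAML document with top-level keys `flow`, `banks`, `drugs`,
#' rebuilds the domain objects, and enforces every structural invariant
#' (5 eligible counties; 10-item banks split 6 parallel / 4 specific;
#' unscorable generic bank; 50/50-constructible dose entries). All
#' violations are collected and reported together, each with the path of
#' the offending field.
#'
#' @param path YAML file path.
#' @return A list with `flow`, `banks`, `catalog`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  problems <- character()
  note <- function(...) problems <<- c(problems, paste0(...))
  for (key in c("flow", "banks", "drugs")) {
    if (is.null(doc[[key]])) note("missing top-level key '", key, "'")
  }
  if (length(problems)) {
    stop("config schema violations:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  banks <- list()
  for (bid in names(doc$banks)) {
    items <- list()
    raw_items <- doc$banks[[bid]]
    for (i in seq_along(raw_items)) {
      ri <- raw_items[[i]]
      pth <- paste0("banks/", bid, "/", i)
      it <- tryCatch(
        quiz_item(ri$item_id, ri$kind, unlist(ri$options),
                  unlist(ri$correct) %||% character(), ri$category,
                  scorable = length(ri$correct) > 0L),
        error = function(e) {
          note(pth, ": ", conditionMessage(e)); NULL
        })
      if (!is.null(it)) items <- c(items, list(it))
    }
    bk <- tryCatch(question_bank(bid, items),
                   error = function(e) {
                     note("banks/", bid, ": ", conditionMessage(e)); NULL
                   })
    if (!is.null(bk)) banks[[bid]] <- bk
  }
  entries <- list()
  for (did in names(doc$drugs)) {
    rd <- doc$drugs[[did]]
    en <- tryCatch(
      drug_entry(did, rd$drug_class,
                 formulation = rd$formulation %||% NA_character_,
                 true_doses = unlist(rd$true_doses) %||% numeric(),
                 decoy_doses = unlist(rd$decoy_doses) %||% numeric(),
                 price_brackets_cents =
                   if (!is.null(rd$price_brackets_cents))
                     lapply(rd$price_brackets_cents, unlist),
                 price_correct = rd$price_correct %||% NA_integer_,
                 cap_size_answer_g = rd$cap_size_answer_g %||% NA_real_,
                 cap_size_options_g = unlist(rd$cap_size_options_g)),
      error = function(e) {
        note("drugs/", did, ": ", conditionMessage(e)); NULL
      })
    if (!is.null(en)) entries <- c(entries, list(en))
  }
  flow <- tryCatch(
    screening_flow_spec(
      unlist(doc$flow$eligible_counties),
      age_range = unlist(doc$flow$age_range),
      recall_days_use = doc$flow$recall_days_use %||% 30L,
      recall_hours_udt = doc$flow$recall_hours_udt %||% 24L,
      county_quiz = county_quiz_spec(
        doc$flow$county_quiz$draw_size %||% 5L,
        doc$flow$county_quiz$pass_threshold %||% 3L)),
    error = function(e) {
      note("flow: ", conditionMessage(e)); NULL
    })
  if (!length(problems)) {
    for (cty in flow$eligible_counties) {
      if (is.null(banks[[cty]])) {
        note("banks: no bank for eligible county '", cty, "'")
      }
    }
  }
  if (length(problems)) {
    stop("config schema violations:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  list(flow = flow, banks = banks, catalog = drug_catalog(entries))
}

#' Path to the shipped example configuration
#' @return File path of `study_config.yaml` under the package's
#'   `extdata`.
#' @export
example_config_path <- function() {
  system.file("extdata", "study_config.yaml", package = "quizscreen",
              mustWork = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
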