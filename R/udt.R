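#' @title Urine-drug-test subsampling, simulation and concordance
#'
#' @description Models the 13-panel point-of-care cup: per-panel
#'   detection windows (days) and thresholds (ng/mL, carried as
#'   metadata; results are binary), the drug-to-panel map for the
#'   catalog's opioids, random subsampling of recent users for testing,
#'   a day-resolution detection model, and self-report concordance
#'   summaries.
#' @name udt
NULL

#' The 13 assay panels
#'
#' Detection windows and thresholds of the 13-panel cup. The window is
#' a day interval; the default detection model uses its upper bound.
#'
#' @return Tibble: `panel_id`, `window_lo`, `window_hi` (days),
#'   `threshold_ng_ml`.
#' @export
udt_panels <- function() {
  tibble::tribble(
    ~panel_id,                  ~window_lo, ~window_hi, ~threshold_ng_ml,
    "marijuana",                15,         30,         50,
    "opiates",                  2,          4,          2000,
    "methadone",                3,          5,          300,
    "oxycodone",                2,          4,          100,
    "propoxyphene",             1,          2,          300,
    "buprenorphine",            2,          3,          10,
    "methamphetamine",          3,          5,          1000,
    "amphetamine",              2,          4,          1000,
    "cocaine",                  2,          4,          300,
    "benzodiazepines",          3,          7,          300,
    "phencyclidine",            7,          14,         25,
    "barbiturates",             4,          7,          300,
    "tricyclic_antidepressants", 2,         7,          300
  )
}

#' Panel classes for aggregate rows
#'
#' `opioids` = opiates, methadone, oxycodone, propoxyphene,
#' buprenorphine; `stimulants` = methamphetamine, amphetamine, cocaine.
#'
#' @return Named list of panel-id vectors.
#' @export
udt_panel_classes <- function() {
  list(
    opioids = c("opiates", "methadone", "oxycodone", "propoxyphene",
                "buprenorphine"),
    stimulants = c("methamphetamine", "amphetamine", "cocaine")
  )
}

#' Drug-to-panel map for the catalog opioids
#'
#' Heroin reads on the opiates panel; oxycodone-containing brands on
#' the oxycodone panel; buprenorphine and methadone on their own
#' panels. Fentanyl and tramadol are not detected by any of the 13
#' panels and map to `NA` (an explicit never-positive marker).
#'
#' @return Named character vector: drug id to panel id (or `NA`).
#' @export
drug_panel_map <- function() {
  c(heroin = "opiates",
    percocet = "oxycodone", roxicodone = "oxycodone",
    oxycontin = "oxycodone", tylox = "oxycodone",
    norco = "oxycodone", lortab = "oxycodone",
    opana = NA, tramadol = NA, fentanyl = NA,
    buprenorphine_pill = "buprenorphine",
    buprenorphine_strip = "buprenorphine",
    methadone_pill = "methadone", methadone_liquid = "methadone")
}

#' Randomly select the UDT subsample
#'
#' Participants qualify when they completed the screen and reported
#' opioid use in the past 24 hours; a uniform random subset of
#' qualifiers is selected.
#'
#' @param records Record tibble (needs `complete` and
#'   `used_opioid_24h`).
#' @param count Number to select; or use `fraction`.
#' @param fraction Fraction of qualifiers to select (rounded down).
#' @param seed Integer seed.
#' @return The selected rows of `records`.
#' @export
select_udt_subsample <- function(records, count = NULL, fraction = NULL,
                                 seed = 1L) {
  pool <- which(records$complete %in% TRUE &
                records$used_opioid_24h %in% TRUE)
  if (is.null(count)) {
    stopifnot(!is.null(fraction), fraction >= 0, fraction <= 1)
    count <- floor(fraction * length(pool))
  }
  if (count > length(pool)) {
    stop("requested ", count, " but only ", length(pool),
         " qualifying candidates", call. = FALSE)
  }
  sel <- withr::with_seed(seed, sample(pool, count))
  records[sel, , drop = FALSE]
}

#' Simulate one participant's 13-panel result
#'
#' A panel reads positive when any drug mapped to it was last used
#' within its detection window, counting the days between use and
#' specimen collection (`days_since_use + days_elapsed`). The default
#' deterministic model uses the window's upper bound; the stochastic
#' model draws the window length uniformly within the interval. The
#' 2-to-5-hour onset delay is below day resolution and ignored.
#'
#' @param days_since_use Named numeric: per-drug days between last use
#'   and the screening survey.
#' @param days_elapsed Days between survey and specimen (0-3 under
#'   protocol).
#' @param panels Panel tibble from [udt_panels()].
#' @param map Drug-to-panel map from [drug_panel_map()].
#' @param model `"upper"` (default, deterministic) or `"uniform"`.
#' @return One-row tibble: `days_elapsed`, one logical `panel_*` column
#'   per panel, and a `notices` attribute listing unmapped drugs.
#' @export
simulate_udt <- function(days_since_use, days_elapsed = 0,
                         panels = udt_panels(), map = drug_panel_map(),
                         model = c("upper", "uniform")) {
  model <- match.arg(model)
  stopifnot(all(days_since_use >= 0), days_elapsed >= 0)
  notices <- character()
  pos <- stats::setNames(rep(FALSE, nrow(panels)), panels$panel_id)
  for (drug in names(days_since_use)) {
    panel <- if (drug %in% names(map)) map[[drug]] else NA
    if (is.na(panel)) {
      notices <- c(notices, paste0("drug '", drug,
                                   "' not detected by any panel"))
      next
    }
    row <- panels[panels$panel_id == panel, ]
    win <- switch(model,
                  upper = row$window_hi,
                  uniform = stats::runif(1, row$window_lo, row$window_hi))
    if (days_since_use[[drug]] + days_elapsed <= win) {
      pos[[panel]] <- TRUE
    }
  }
  out <- tibble::as_tibble(as.list(stats::setNames(
    pos, paste0("panel_", names(pos)))))
  out <- tibble::add_column(out, days_elapsed = days_elapsed,
                            .before = 1L)
  attr(out, "notices") <- notices
  out
}

#' Any-positive flag over a panel class
#'
#' @param records UDT record tibble with `panel_*` columns.
#' @param class_panels Character vector of member panel ids.
#' @return Logical vector: union of the member panels per record.
#' @export
any_class_positive <- function(records, class_panels) {
  cols <- paste0("panel_", class_panels)
  missing <- setdiff(cols, names(records))
  if (length(missing)) {
    stop("unknown panel(s) in class map: ",
         paste(sub("^panel_", "", missing), collapse = ", "),
         call. = FALSE)
  }
  rowSums(as.matrix(records[cols])) > 0
}

#' Self-report vs UDT concordance table
#'
#' For each reported past-24-hour opioid: the number tested, the count
#' and percentage whose mapped panel read positive, and the mean and
#' range of days between survey and specimen. Reported drugs with no
#' panel mapping are excluded with a notice.
#'
#' @param records UDT record tibble with `reported_opioid_24h`,
#'   `days_elapsed` and `panel_*` columns.
#' @param map Drug-to-panel map.
#' @param digits Rounding for the percentage (default 0, half-up).
#' @return Tibble: one row per reported drug plus attributes `notices`.
#' @export
concordance_summary <- function(records, map = drug_panel_map(),
                                digits = 0) {
  if (nrow(records) == 0L) {
    return(tibble::tibble(reported = character(), n = integer(),
                          n_positive = integer(), pct_positive = numeric(),
                          days_mean = numeric(), days_min = numeric(),
                          days_max = numeric()))
  }
  notices <- character()
  rows <- list()
  for (drug in unique(records$reported_opioid_24h)) {
    panel <- if (drug %in% names(map)) map[[drug]] else NA
    sub <- records[records$reported_opioid_24h == drug, ]
    if (is.na(panel)) {
      notices <- c(notices, paste0("reported drug '", drug,
                                   "' has no mapped panel; excluded"))
      next
    }
    posv <- sub[[paste0("panel_", panel)]]
    rows[[drug]] <- tibble::tibble(
      reported = drug, n = nrow(sub), n_positive = sum(posv),
      pct_positive = round_half_up(100 * sum(posv) / nrow(sub), digits),
      days_mean = mean(sub$days_elapsed),
      days_min = min(sub$days_elapsed), days_max = max(sub$days_elapsed))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$n), , drop = FALSE]
  attr(out, "notices") <- notices
  out
}

#' Build the UDT fixture (34 tested participants)
#'
#' Assembles the tested subsample from four constraint slices: the
#' opioid-panel systems of the three reporter groups (heroin,
#' buprenorphine, Percocet reporters, including the cross-panel
#' overlaps that make the any-opioid union come out right), a stimulant
#' overlay, and a singles overlay (marijuana, benzodiazepines,
#' phencyclidine). Days-to-specimen are fixed values inside each
#' group's printed range.
#'
#' @param seed Integer seed (row permutation within groups).
#' @return UDT record tibble (34 rows, 13 `panel_*` columns).
#' @export
build_udt_fixture <- function(seed = 1L) {
  groups <- list(
    list(slice = "udt_heroin_reporters", reported = "heroin",
         days = c(rep(1, 5), rep(0, 16))),
    list(slice = "udt_bup_reporters", reported = "buprenorphine_pill",
         days = c(3, 1, 1, rep(0, 6))),
    list(slice = "udt_percocet_reporters", reported = "percocet",
         days = c(1, 1, 1, 0))
  )
  op_rows <- lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    fx <- build_fixture(g$slice, seed = seed + i)
    flags <- fx$flags
    tibble::tibble(
      reported_opioid_24h = g$reported,
      days_elapsed = g$days[seq_len(nrow(flags))],
      panel_opiates = flags$opi,
      panel_buprenorphine = flags$bup,
      panel_oxycodone = flags$oxy)
  })
  rec <- do.call(rbind, op_rows)
  n <- nrow(rec)
  rec$respondent_id <- sprintf("udt%02d", seq_len(n))

  stim <- build_fixture("udt_stimulants", seed = seed + 11L)$flags
  rec$panel_methamphetamine <- stim$meth
  rec$panel_amphetamine <- stim$amph
  rec$panel_cocaine <- stim$coc

  other <- build_fixture("udt_other", seed = seed + 12L)$flags
  rec$panel_marijuana <- other$marijuana
  rec$panel_benzodiazepines <- other$benzo
  rec$panel_phencyclidine <- other$pcp

  rec$panel_methadone <- FALSE
  rec$panel_propoxyphene <- FALSE
  rec$panel_barbiturates <- FALSE
  rec$panel_tricyclic_antidepressants <- FALSE
  rec
}
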