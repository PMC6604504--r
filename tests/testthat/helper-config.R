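# Shared configuration and small builders used across the suite.

test_cfg <- default_config()
test_personas <- default_personas(test_cfg$flow)

# A bank of ten 4-option items (guessing probability 1/4 each),
# identical topics to a county bank.
mc4_bank <- function(bank_id = "mc4") {
  cats <- c("largest_town", "smallest_communities", "jail", "walmart",
            "landmark", "grocery", "mascot", "school_colors", "festival",
            "pizza")
  items <- lapply(seq_along(cats), function(i) {
    quiz_item(paste0(bank_id, "_q", i), "multiple_choice",
              paste0("o", 1:4), "o1", cats[i])
  })
  question_bank(bank_id, items)
}

# Configuration whose five county banks are all 4-option banks, so the
# county-quiz guessing probability is the homogeneous binomial value.
mc4_config <- function() {
  cfg <- default_config()
  for (cty in cfg$flow$eligible_counties) {
    bk <- mc4_bank(cty)
    bk$bank_id <- cty
    cfg$banks[[cty]] <- bk
  }
  cfg
}

# Answer source with fully specified deterministic behaviour.
fixed_source <- function(age = 27, county = "amberley",
                         substances = "heroin", most_often = "heroin",
                         correct = TRUE, abandon_at = NULL) {
  list(
    reported_age = age, reported_county = county,
    reported_substances = substances,
    most_often_opioid = if (length(substances)) most_often else NULL,
    used_opioid_24h = FALSE, abandon_at = abandon_at,
    p_correct = function(item) as.numeric(correct),
    answer = function(item) {
      if (!item$scorable) return(item$options[[1L]])
      if (correct) item$correct[[1L]]
      else setdiff(item$options, item$correct)[[1L]]
    }
  )
}

# Brute-force feasibility oracle for small constraint systems: counts
# all compositions of n over the 2^k cells and checks each against the
# constraint counts directly.
brute_force_feasible <- function(fields, preds, counts) {
  cells <- expand.grid(rep(list(c(FALSE, TRUE)), length(fields)),
                       KEEP.OUT.ATTRS = FALSE)
  names(cells) <- fields
  m <- nrow(cells)
  sat <- sapply(preds, function(pr) {
    v <- eval(pr, cells)
    if (length(v) == 1L) v <- rep(v, m)
    as.logical(v)
  })
  sat <- matrix(sat, nrow = m)
  n <- counts[[1L]]  # convention: first constraint is the total
  found <- FALSE
  rec <- function(j, left, acc) {
    if (found) return()
    if (j == m) {
      x <- c(acc, left)
      if (all(as.vector(t(sat) %*% x) == counts)) found <<- TRUE
      return()
    }
    for (v in 0:left) rec(j + 1L, left - v, c(acc, v))
  }
  rec(1L, n, integer())
  found
}
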