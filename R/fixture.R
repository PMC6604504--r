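#' @title Marginal-constraint fixture synthesizer
#'
#' @description The study deposited no microdata, but its Results print
#'   many marginal counts (funnel nodes, per-item accuracies, UDT panel
#'   positives). A constraint slice states those counts as predicates
#'   over binary record flags; the synthesizer finds an exact
#'   nonnegative-integer allocation over the cross-classification cells,
#'   expands it to record level, and materializes records carrying
#'   *responses* (per-item correctness), so that every printed count
#'   re-emerges only when the real scoring rules are re-applied.
#'   Construction is deterministic given (constraints, seed); infeasible
#'   slices are reported with a minimal conflicting subset.
#' @name fixture
NULL

#' Construct a constraint set
#'
#' @param slice Slice name (selects the record materializer).
#' @param fields Character vector of binary flag names.
#' @param constraints List of `list(name, pred, count, where)` where
#'   `pred` is an unevaluated expression over `fields` (and `TRUE` for
#'   the total), `count` the required number of records satisfying it,
#'   and `where` a free-text provenance note.
#' @return A `constraint_set` object.
#' @export
constraint_set <- function(slice, fields, constraints) {
  stopifnot(is.character(fields))
  for (ct in constraints) {
    stopifnot(!is.null(ct$name), !is.null(ct$pred), !is.null(ct$count))
    if (ct$count < 0) stop("constraint '", ct$name, "': negative count",
                           call. = FALSE)
  }
  structure(list(slice = slice, fields = fields, constraints = constraints),
            class = "constraint_set")
}

#' Load a shipped constraint slice
#'
#' Slices are YAML files under `extdata/constraints/`, one per
#' internally consistent group of printed counts (the source's printed
#' counts are mutually inconsistent in places, so one global set would
#' be infeasible by construction).
#'
#' @param slice Slice name (file stem), e.g. `"heroin"`,
#'   `"funnel_reasons"`; see [fixture_slices()].
#' @return A [constraint_set()].
#' @export
load_constraints <- function(slice) {
  path <- system.file("extdata", "constraints", paste0(slice, ".yaml"),
                      package = "quizscreen")
  if (!nzchar(path)) stop("unknown constraint slice '", slice, "'",
                          call. = FALSE)
  doc <- yaml::read_yaml(path)
  cons <- lapply(doc$constraints, function(ct) {
    list(name = ct$name, pred = str2lang(ct$pred),
         count = as.integer(ct$count), where = ct$where %||% "")
  })
  constraint_set(doc$slice, unlist(doc$fields) %||% character(), cons)
}

#' Names of the shipped constraint slices
#' @return Character vector.
#' @export
fixture_slices <- function() {
  dir <- system.file("extdata", "constraints", package = "quizscreen")
  sub("[.]yaml$", "", list.files(dir, pattern = "[.]yaml$"))
}

cell_grid <- function(fields) {
  if (length(fields) == 0L) {
    return(structure(data.frame(row.names = 1L), names = character()))
  }
  g <- expand.grid(rep(list(c(FALSE, TRUE)), length(fields)),
                   KEEP.OUT.ATTRS = FALSE)
  names(g) <- fields
  g
}

sat_matrix <- function(cells, constraints) {
  m <- nrow(cells)
  sat <- matrix(FALSE, m, length(constraints))
  for (i in seq_along(constraints)) {
    v <- eval(constraints[[i]]$pred, cells)
    if (length(v) == 1L) v <- rep(v, m)
    sat[, i] <- as.logical(v)
  }
  sat
}

# Exact deterministic search for nonnegative integer cell counts
# satisfying all equality constraints: most-constrained cell first,
# largest feasible value first, with completability pruning.
solve_cells <- function(cells, sat, counts, budget = 2e5) {
  m <- nrow(cells)
  ncon <- length(counts)
  ntrue <- if (ncol(cells)) rowSums(cells) else rep(0, m)
  coverage <- rowSums(sat)
  nodes <- 0L
  dfs <- function(assign, rem) {
    nodes <<- nodes + 1L
    if (nodes > budget) {
      stop("cell allocation search budget exceeded", call. = FALSE)
    }
    if (any(rem < 0)) return(NULL)
    un <- which(is.na(assign))
    if (!length(un)) return(if (all(rem == 0L)) assign else NULL)
    cap <- vapply(un, function(j) {
      cov <- which(sat[j, ])
      if (!length(cov)) 0 else min(rem[cov])
    }, numeric(1))
    for (i in seq_len(ncon)) {
      if (rem[i] > 0) {
        cov_un <- sat[un, i]
        if (sum(cap[cov_un]) < rem[i]) return(NULL)
      }
    }
    score <- coverage[un] * 1000 - ntrue[un]
    j <- un[which.max(score)]
    jcap <- cap[match(j, un)]
    for (v in seq(jcap, 0, by = -1)) {
      a2 <- assign
      a2[j] <- v
      res <- dfs(a2, rem - v * sat[j, ])
      if (!is.null(res)) return(res)
    }
    NULL
  }
  dfs(rep(NA_integer_, m), counts)
}

#' Find a minimal conflicting subset of an infeasible constraint set
#'
#' Searches subsets of increasing size for the smallest infeasible
#' subsystem; for feasible sets returns `NULL`.
#'
#' @param cs A [constraint_set()].
#' @return Character vector of constraint names, or `NULL`.
#' @export
minimal_conflict <- function(cs) {
  cells <- cell_grid(cs$fields)
  counts <- vapply(cs$constraints, function(ct) as.numeric(ct$count),
                   numeric(1))
  sat <- sat_matrix(cells, cs$constraints)
  nc <- length(counts)
  full <- solve_cells(cells, sat, counts)
  if (!is.null(full)) return(NULL)
  for (size in 2:nc) {
    subs <- utils::combn(nc, size)
    for (ci in seq_len(ncol(subs))) {
      sel <- subs[, ci]
      if (is.null(solve_cells(cells, sat[, sel, drop = FALSE],
                              counts[sel]))) {
        return(vapply(cs$constraints[sel], `[[`, "", "name"))
      }
    }
  }
  vapply(cs$constraints, `[[`, "", "name")
}

#' Build a fixture table from a constraint set
#'
#' Solves for exact cell counts, expands to one row per record, applies
#' the slice's materializer (flags become concrete respondent records:
#' ages, counties, substances, per-item correctness), permutes row
#' order under the seed, and re-verifies every constraint. Infeasible
#' sets raise an error naming a minimal conflicting subset.
#'
#' @param cs A [constraint_set()] (or slice name, loaded via
#'   [load_constraints()]).
#' @param seed Integer seed (row-order permutation only; the allocation
#'   itself is deterministic).
#' @return A `fixture_table`: list with `slice`, `flags` (record-level
#'   flag tibble), `records` (engine-schema tibble or slice-specific
#'   table), `constraints`.
#' @export
build_fixture <- function(cs, seed = 1L) {
  if (is.character(cs)) cs <- load_constraints(cs)
  stopifnot(inherits(cs, "constraint_set"))
  cells <- cell_grid(cs$fields)
  counts <- vapply(cs$constraints, function(ct) as.numeric(ct$count),
                   numeric(1))
  sat <- sat_matrix(cells, cs$constraints)
  sol <- solve_cells(cells, sat, counts)
  if (is.null(sol)) {
    confl <- minimal_conflict(cs)
    detail <- vapply(cs$constraints[match(confl,
      vapply(cs$constraints, `[[`, "", "name"))],
      function(ct) sprintf("%s=%d", ct$name, ct$count), "")
    stop("infeasible constraint set '", cs$slice,
         "'; minimal conflicting subset: {",
         paste(detail, collapse = ", "), "}", call. = FALSE)
  }
  idx <- rep(seq_len(nrow(cells)), sol)
  flags <- tibble::as_tibble(cells[idx, , drop = FALSE])
  perm <- withr::with_seed(seed, sample.int(nrow(flags)))
  flags <- flags[perm, , drop = FALSE]
  mat <- fixture_materializer(cs$slice)
  records <- mat(flags)
  vr <- verify_fixture(flags, cs)
  if (!all(vr$satisfied)) {
    stop("internal error: built fixture violates its constraints",
         call. = FALSE)
  }
  structure(list(slice = cs$slice, flags = flags, records = records,
                 constraints = cs),
            class = "fixture_table")
}

#' Verify a table against a constraint set
#'
#' @param data Flag tibble (or a `fixture_table`, whose flags are used).
#' @param cs A [constraint_set()].
#' @return Tibble with one row per constraint: `name`, `required`,
#'   `observed`, `satisfied`, `where`.
#' @export
verify_fixture <- function(data, cs) {
  if (inherits(data, "fixture_table")) data <- data$flags
  stopifnot(inherits(cs, "constraint_set"))
  rows <- lapply(cs$constraints, function(ct) {
    v <- eval(ct$pred, data)
    if (length(v) == 1L) v <- rep(v, nrow(data))
    obs <- sum(v)
    tibble::tibble(name = ct$name, required = as.integer(ct$count),
                   observed = as.integer(obs),
                   satisfied = obs == ct$count,
                   where = ct$where %||% "")
  })
  do.call(rbind, rows)
}

# --- slice materializers -------------------------------------------------

county_cycle <- function(n, counties) counties[(seq_len(n) - 1L) %% 5L + 1L]

all_correct_county <- function(rec, rows = seq_len(nrow(rec))) {
  for (j in 1:5) rec[[paste0("county_item", j)]][rows] <- TRUE
  rec
}

materialize_drug_slice <- function(drug_for_row, comp_cols) {
  function(flags) {
    n <- nrow(flags)
    rec <- empty_record(n)
    rec$respondent_id <- sprintf("fx%04d", seq_len(n))
    rec$age <- 27L
    counties <- c("amberley", "beechfork", "cartwright", "dunmore",
                  "eldridge")
    rec$reported_county <- county_cycle(n, counties)
    rec <- all_correct_county(rec)
    drug <- drug_for_row(flags)
    rec$reported_substances <- drug
    rec$most_often_opioid <- drug
    for (cmp in names(comp_cols)) {
      rec[[paste0("comp_", cmp)]] <- flags[[comp_cols[[cmp]]]]
    }
    rec
  }
}

materialize_funnel <- function(flags) {
  n <- nrow(flags)
  rec <- empty_record(n)
  rec$respondent_id <- sprintf("fx%04d", seq_len(n))
  counties <- c("amberley", "beechfork", "cartwright", "dunmore",
                "eldridge")
  rec$complete <- flags$complete
  done <- which(flags$complete)
  rec$age[done] <- ifelse(flags$age_bad[done], 41L, 27L)
  rec$reported_county[done] <- ifelse(flags$outside[done], "out_of_area",
                                      county_cycle(n, counties)[done])
  rec$reported_substances[done] <- ifelse(flags$no_substance[done], "",
                                          "heroin")
  rec$most_often_opioid[done] <- ifelse(flags$no_substance[done],
                                        NA_character_, "heroin")
  in_area <- done[!flags$outside[done]]
  # county quiz: failers score 2 of 5, everyone else full marks
  for (j in 1:5) {
    rec[[paste0("county_item", j)]][in_area] <-
      !flags$county_fail[in_area] | j <= 2L
  }
  quizzed <- done[!flags$no_substance[done]]
  rec$comp_cap_size[quizzed] <- !flags$drug_fail[quizzed]
  rec$comp_price[quizzed] <- !flags$drug_fail[quizzed]
  rec$comp_image[quizzed] <- TRUE
  rec
}

materialize_county <- function(flags) {
  n <- nrow(flags)
  rec <- empty_record(n)
  rec$respondent_id <- sprintf("fx%04d", seq_len(n))
  rec$age <- 27L
  counties <- c("amberley", "beechfork", "cartwright", "dunmore",
                "eldridge")
  rec$reported_county <- county_cycle(n, counties)
  for (j in 1:5) rec[[paste0("county_item", j)]] <- flags[[paste0("i", j)]]
  rec$reported_substances <- "heroin"
  rec$most_often_opioid <- "heroin"
  rec$comp_cap_size <- TRUE
  rec$comp_price <- TRUE
  rec$comp_image <- TRUE
  rec
}

fixture_materializer <- function(slice) {
  switch(slice,
    heroin = materialize_drug_slice(
      function(flags) rep("heroin", nrow(flags)),
      c(cap_size = "cap", price = "price", image = "image")),
    prescription = materialize_drug_slice(
      function(flags) {
        ifelse(flags$percocet, "percocet",
               ifelse(flags$norco, "norco",
                      ifelse(flags$tylox, "tylox", "lortab")))
      },
      c(dose = "dose", image = "image")),
    bup_pills = ,
    bup_pills_printed = materialize_drug_slice(
      function(flags) rep("buprenorphine_pill", nrow(flags)),
      c(dose = "dose", image = "image")),
    bup_strips = materialize_drug_slice(
      function(flags) rep("buprenorphine_strip", nrow(flags)),
      c(dose = "dose", image = "image")),
    methadone = materialize_drug_slice(
      function(flags) rep("methadone_pill", nrow(flags)),
      c(dose = "dose", image = "image")),
    synthetic = materialize_drug_slice(
      function(flags) rep("fentanyl", nrow(flags)), character()),
    funnel_fig2 = ,
    funnel_reasons = materialize_funnel,
    county = materialize_county,
    function(flags) flags  # UDT overlays and unknown slices: flags as-is
  )
}

#' Build the combined drug-quiz fixture
#'
#' Concatenates the per-drug slices (heroin, prescription opioids,
#' buprenorphine pills and strips, methadone, synthetic auto-pass) into
#' the full population of drug-quizzed respondents.
#'
#' @param seed Integer seed.
#' @return Record tibble.
#' @export
build_drug_quiz_fixture <- function(seed = 1L) {
  slices <- c("heroin", "prescription", "bup_pills", "bup_strips",
              "methadone", "synthetic")
  recs <- lapply(seq_along(slices), function(i) {
    build_fixture(slices[i], seed = seed + i)$records
  })
  out <- do.call(rbind, recs)
  out$respondent_id <- sprintf("dq%04d", seq_len(nrow(out)))
  out
}
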