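#' @title Exact pass-probability oracle
#'
#' @description The number of correct answers on a quiz with independent
#'   per-item success probabilities follows a Poisson-binomial
#'   distribution; the county quiz adds a layer of averaging over the
#'   `choose(10, 5)` equally likely bank draws. These closed forms give
#'   exact pass probabilities and screen operating characteristics, and
#'   serve as the oracle the Monte-Carlo simulator is checked against.
#' @name oracle
NULL

#' Poisson-binomial upper tail
#'
#' `P(#successes >= k)` for independent Bernoulli trials with
#' probabilities `probs`, by exact dynamic-programming convolution.
#'
#' @param probs Numeric vector of success probabilities.
#' @param k Nonnegative count.
#' @return Probability.
#' @export
poisson_binomial_tail <- function(probs, k) {
  stopifnot(length(probs) >= 1L, k >= 0)
  if (any(probs < 0 | probs > 1)) {
    stop("success probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (k == 0) return(1)
  if (k > length(probs)) return(0)
  # f[j+1] = P(j successes among trials processed so far)
  f <- c(1, rep(0, length(probs)))
  for (p in probs) {
    f <- c(f[1] * (1 - p), f[-1] * (1 - p) + f[-length(f)] * p)
  }
  sum(f[(k + 1L):length(f)])
}

#' Poisson-binomial upper tail by full enumeration
#'
#' Brute-force sum over all `2^n` outcome vectors. Intended as an
#' independent oracle for [poisson_binomial_tail()] at small `n`; with
#' dyadic-rational probabilities (multiples of `1/2^b`) every product is
#' exactly representable in double precision, so the comparison is
#' exact.
#'
#' @inheritParams poisson_binomial_tail
#' @return Probability.
#' @export
enumerate_tail <- function(probs, k) {
  n <- length(probs)
  stopifnot(n >= 1L, n <= 20L, k >= 0)
  total <- 0
  for (mask in 0:(2^n - 1)) {
    bits <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    if (sum(bits) >= k) {
      total <- total + prod(ifelse(bits, probs, 1 - probs))
    }
  }
  total
}

#' Exact county-quiz pass probability
#'
#' Averages the Poisson-binomial tail over every without-replacement
#' draw of `spec$draw_size` items from the bank (all
#' `choose(n, draw_size)` draws equally likely). With a homogeneous
#' success probability this reduces to the binomial tail, independent of
#' the draw.
#'
#' @param profile Numeric vector: per-bank-item success probability
#'   (from a knowledge model, or `|correct|/|options|` for a pure
#'   guesser).
#' @param spec A [county_quiz_spec()].
#' @return Probability of scoring at least `pass_threshold`.
#' @export
county_pass_probability <- function(profile, spec = county_quiz_spec()) {
  n <- length(profile)
  if (n < spec$draw_size) {
    stop("bank size ", n, " smaller than draw size ", spec$draw_size,
         call. = FALSE)
  }
  draws <- utils::combn(n, spec$draw_size)
  mean(apply(draws, 2, function(idx) {
    poisson_binomial_tail(profile[idx], spec$pass_threshold)
  }))
}

#' Exact drug-quiz pass probability
#'
#' `P(at least one scored component correct) = 1 - prod(1 - p)` under
#' component independence; auto-pass specs (synthetic opioids) return 1
#' and not-applicable specs (nonopioid masking quizzes) return `NA`.
#'
#' @param spec A [drug_quiz_spec()].
#' @param profile Named numeric vector of per-component success
#'   probabilities covering all scored components; defaults to the pure
#'   guessing profile derived from the item structure.
#' @return Probability (or `NA` for masking quizzes).
#' @export
drug_pass_probability <- function(spec, profile = drug_guess_profile(spec)) {
  stopifnot(inherits(spec, "drug_quiz_spec"))
  if (spec$auto_pass) return(1)
  if (!spec$applicable) return(NA_real_)
  missing <- setdiff(spec$scored, names(profile))
  if (length(missing)) {
    stop("profile missing scored component(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  p <- profile[spec$scored]
  if (any(p < 0 | p > 1)) {
    stop("component probabilities must lie in [0, 1]", call. = FALSE)
  }
  1 - prod(1 - p)
}

#' Per-item success profile for a persona on a bank
#'
#' Each item's success probability is the persona's knowledge
#' probability for the item's category when one is given, otherwise the
#' structural guessing probability `|correct|/|options|`.
#'
#' @param knowledge Named numeric vector of per-category correctness
#'   probabilities (may be empty: pure guesser).
#' @param bank A [question_bank()].
#' @return Numeric vector of length `length(bank$items)`.
#' @export
knowledge_success_profile <- function(knowledge, bank) {
  vapply(bank$items, function(it) {
    if (it$category %in% names(knowledge)) {
      p <- knowledge[[it$category]]
      stopifnot(p >= 0, p <= 1)
      p
    } else {
      item_guess_prob(it)
    }
  }, numeric(1))
}

#' Exact probability a persona is classified eligible
#'
#' Composes the flow's AND-logic analytically: age in range, an
#' eligible county reported, county-quiz pass for the claimed county,
#' an opioid reported, and the drug-quiz pass for the most-often opioid
#' (mixture over the persona's most-often distribution), conditional on
#' a complete entry.
#'
#' @param persona A [persona()].
#' @param flow A [screening_flow_spec()].
#' @param banks Named list of banks.
#' @param catalog A [drug_catalog()].
#' @return Probability in \[0, 1\].
#' @export
persona_pass_probability <- function(persona, flow, banks, catalog) {
  p_age <- sum(persona$age_weights[persona$age_values >= flow$age_range[1] &
                                   persona$age_values <= flow$age_range[2]])
  cty_w <- persona$county_weights
  elig_cty <- intersect(names(cty_w), flow$eligible_counties)
  p_county_and_quiz <- sum(vapply(elig_cty, function(cty) {
    prof <- knowledge_success_profile(persona$knowledge, banks[[cty]])
    cty_w[[cty]] * county_pass_probability(prof, flow$county_quiz)
  }, numeric(1)))
  p_sub_and_drug <- sum(vapply(seq_along(persona$substance_sets),
                               function(i) {
    set <- persona$substance_sets[[i]]
    w <- persona$substance_weights[[i]]
    opioids <- set$drugs[vapply(set$drugs, function(d) is_opioid(catalog, d),
                                TRUE)]
    if (length(opioids) == 0L) return(0)
    mo_w <- set$most_often_weights %||%
      stats::setNames(rep(1 / length(opioids), length(opioids)), opioids)
    w * sum(vapply(names(mo_w), function(d) {
      spec <- drug_quiz_spec(catalog, d)
      prof <- persona$knowledge[intersect(names(persona$knowledge),
                                          DRUG_COMPONENTS)]
      full <- drug_guess_profile(spec)
      full[intersect(names(full), names(prof))] <-
        prof[intersect(names(full), names(prof))]
      mo_w[[d]] * drug_pass_probability(spec, full)
    }, numeric(1)))
  }, numeric(1)))
  p_age * p_county_and_quiz * p_sub_and_drug
}

#' Operating characteristics of the whole screen over a persona mix
#'
#' Sensitivity is the probability a truly eligible persona is classified
#' eligible; specificity the probability a truly ineligible persona is
#' classified ineligible; the positive predictive value follows from
#' Bayes' rule on the mix weights.
#'
#' @param personas List of [persona()]s (each carries `truly_eligible`).
#' @param weights Mix weights (normalized internally).
#' @param flow,banks,catalog Screen configuration.
#' @return A list with `sensitivity`, `specificity`, `ppv`, and the
#'   per-persona classification probabilities.
#' @export
screen_operating_characteristics <- function(personas, weights, flow,
                                             banks, catalog) {
  stopifnot(length(personas) == length(weights), all(weights >= 0))
  w <- weights / sum(weights)
  p_class <- vapply(personas, persona_pass_probability, numeric(1),
                    flow = flow, banks = banks, catalog = catalog)
  truth <- vapply(personas, `[[`, TRUE, "truly_eligible")
  sens <- if (any(truth)) sum(w[truth] * p_class[truth]) / sum(w[truth])
          else NA_real_
  spec <- if (any(!truth)) {
    sum(w[!truth] * (1 - p_class[!truth])) / sum(w[!truth])
  } else NA_real_
  denom <- sum(w * p_class)
  ppv <- if (denom > 0) sum(w[truth] * p_class[truth]) / denom else NA_real_
  list(sensitivity = sens, specificity = spec, ppv = ppv,
       p_classified_eligible = stats::setNames(
         p_class, vapply(personas, `[[`, "", "persona_id")))
}
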