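#!/usr/bin/env Rscript
# Loads the screening configuration and summarizes the quiz structure:
# county banks (10 items, 6 parallel topics), the drug catalog, and an
# example 50/50 dose/image quiz construction for Roxicodone.

suppressMessages({
  library(quizscreen)
  library(tibble)
})
dir.create("results", showWarnings = FALSE)

cfg <- load_config(example_config_path())
cat("Eligible counties:", paste(cfg$flow$eligible_counties, collapse = ", "),
    "\nAge range:", paste(cfg$flow$age_range, collapse = "-"),
    "(inclusive)\n\n")

bank_rows <- lapply(names(cfg$banks), function(b) {
  items <- cfg$banks[[b]]$items
  tibble(bank = b, n_items = length(items),
         scorable = sum(vapply(items, `[[`, TRUE, "scorable")),
         mean_guess_prob = round(mean(vapply(items, function(it) {
           p <- item_guess_prob(it)
           if (is.na(p)) 1 / length(it$options) else p
         }, 1)), 3))
})
banks <- do.call(rbind, bank_rows)
print(banks)
write.csv(banks, "results/bank_structure.csv", row.names = FALSE)

cat("\nExample: Roxicodone dose question (5/15/30 mg -> 6 options):\n")
rox <- build_dose_item("roxicodone", c(5, 15, 30), c(10, 20, 40), seed = 1)
cat("  options:", paste(rox$options, collapse = " "), "\n")
cat("  correct:", paste(rox$correct, collapse = " "), "\n")

drug_rows <- lapply(names(cfg$catalog), function(d) {
  spec <- drug_quiz_spec(cfg$catalog, d, seed = 1)
  gp <- drug_guess_profile(spec)
  tibble(drug = d, class = spec$drug_class,
         scored = paste(spec$scored, collapse = "+"),
         auto_pass = spec$auto_pass,
         guess_pass_prob = round(drug_pass_probability(spec), 4))
})
drugs <- do.call(rbind, drug_rows)
print(drugs, n = 20)
write.csv(drugs, "results/drug_quiz_structure.csv", row.names = FALSE)
cat("\nWrote results/bank_structure.csv and results/drug_quiz_structure.csv\n")
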