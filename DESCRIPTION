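Package: quizscreen
Title: Knowledge-Quiz Eligibility Screening for Web-Based Studies of
    People Who Use Drugs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a web-style eligibility screening pipeline for
    hidden-population surveys of people who use drugs: county-residence
    knowledge quizzes drawn at random from 10-item banks (pass = 3 of 5),
    drug-knowledge quizzes on dose, appearance and street price with a
    50/50 correct-option construction rule, a branching screening engine
    with masking quizzes for ineligible-by-report respondents, an exact
    Poisson-binomial guessing oracle for the screen's operating
    characteristics, a persona-based synthetic respondent simulator, a
    marginal-constraint fixture synthesizer, and a 13-panel urine drug
    test concordance stage with nonparametric reporting statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
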