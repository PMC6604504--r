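test_that("dose items follow the 50/50 option-construction rule", {
  # three manufactured doses -> 6 options, 3 correct
  it <- build_dose_item("roxicodone", c(5, 15, 30), c(10, 20, 40), seed = 1)
  expect_length(it$options, 6L)
  expect_length(it$correct, 3L)
  expect_setequal(it$correct, c("5mg", "15mg", "30mg"))
  # degenerate single-dose drug -> 2 options, 1 correct
  it1 <- build_dose_item("tylox", 50, 25, seed = 1)
  expect_length(it1$options, 2L)
  expect_identical(it1$correct, "50mg")
  # preconditions
  expect_error(build_dose_item("x", c(5, 15), 5, seed = 1), "insufficient")
  expect_error(build_dose_item("x", c(5, 15), c(5, 20), seed = 1),
               "overlap")
})

test_that("every constructed dose/image item has exactly half correct", {
  cfg <- test_cfg
  for (did in names(cfg$catalog)) {
    d <- cfg$catalog[[did]]
    if (length(d$true_doses) == 0) next
    dose <- build_dose_item(did, d$true_doses, d$decoy_doses, seed = 3)
    expect_identical(length(dose$correct) * 2L, length(dose$options))
    img <- build_image_item(d, "all", seed = 3)
    expect_identical(length(img$correct) * 2L, length(img$options))
  }
})

test_that("image items respect dose context and branching", {
  rox <- test_cfg$catalog[["roxicodone"]]
  one <- build_image_item(rox, 15, seed = 2)
  expect_identical(length(one$correct) * 2L, length(one$options))
  all_d <- build_image_item(rox, "all", seed = 2)
  expect_setequal(all_d$correct,
                  paste0("img_roxicodone_", c(5, 15, 30), "mg"))
  expect_error(build_image_item(rox, 99), "unknown dose")
})

test_that("the heroin image item offers 10 images with 5 correct", {
  it <- build_heroin_image_item(seed = 5)
  expect_length(it$options, 10L)
  expect_length(it$correct, 5L)
})

test_that("item and bank invariants are enforced", {
  expect_error(quiz_item("a", "yes_no", c("y", "n", "maybe"), "y", "jail"),
               "exactly 2 options")
  expect_error(quiz_item("a", "multiple_choice", paste0("o", 1:4),
                         paste0("o", 1:4), "towns"),
               "strict subset")
  # a 9-item bank violates the bank invariant and names the bank
  bk <- test_cfg$banks[["amberley"]]
  expect_error(question_bank("amberley", bk$items[1:9]),
               "amberley.*exactly 10 items")
  # generic bank must be unscorable
  expect_error(question_bank("generic", bk$items), "unscorable")
})

test_that("county banks split 6 parallel and 4 county-specific topics", {
  for (cty in test_cfg$flow$eligible_counties) {
    cats <- vapply(test_cfg$banks[[cty]]$items, `[[`, "", "category")
    parallel <- c("largest_town", "smallest_communities", "jail",
                  "walmart", "landmark", "grocery")
    expect_identical(sum(cats %in% parallel), 6L)
    expect_identical(sum(!cats %in% parallel), 4L)
  }
})

test_that("configuration round-trips through YAML unchanged", {
  cfg <- test_cfg
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  cfg2 <- load_config(path)
  expect_identical(cfg2$flow, cfg$flow)
  expect_identical(cfg2$banks, cfg$banks)
  expect_identical(cfg2$catalog, cfg$catalog)
})

test_that("the shipped config loads and exposes catalog facts", {
  cfg <- load_config(example_config_path())
  expect_length(cfg$flow$eligible_counties, 5L)
  expect_identical(cfg$flow$age_range, c(18L, 35L))
  for (cty in cfg$flow$eligible_counties) {
    expect_length(cfg$banks[[cty]]$items, 10L)
  }
  # Roxicodone is manufactured as 5, 15 and 30 mg pills
  expect_identical(cfg$catalog[["roxicodone"]]$true_doses, c(5, 15, 30))
  expect_identical(cfg$catalog[["heroin"]]$cap_size_answer_g, 0.1)
  # correct street-price bracket is $10-$50
  hb <- cfg$catalog[["heroin"]]
  expect_identical(hb$price_brackets_cents[[hb$price_correct]],
                   c(1000, 5000))
})

test_that("schema violations are reported with item-level paths", {
  cfg <- test_cfg
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  doc <- yaml::read_yaml(path)
  doc$banks$amberley <- doc$banks$amberley[1:9]
  yaml::write_yaml(doc, path)
  expect_error(load_config(path), "banks/amberley")
})

test_that("drug quiz specs implement the class-specific scoring sets", {
  heroin <- drug_quiz_spec(test_cfg$catalog, "heroin", seed = 1)
  expect_setequal(heroin$scored, c("cap_size", "price"))
  expect_false("image" %in% heroin$scored)
  rox <- drug_quiz_spec(test_cfg$catalog, "roxicodone", seed = 1)
  expect_setequal(rox$scored, c("dose", "image"))
  fent <- drug_quiz_spec(test_cfg$catalog, "fentanyl", seed = 1)
  expect_true(fent$auto_pass)
  expect_length(fent$scored, 0L)
  meth <- drug_quiz_spec(test_cfg$catalog, "methamphetamine", seed = 1)
  expect_false(meth$applicable)
  expect_length(meth$scored, 0L)
})
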