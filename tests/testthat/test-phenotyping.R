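test_that("normalized scores are percent of the sample mean", {
  intake <- make_intake(c("a", "b", "c"), alcohol_gkg = c(2, 4, 6),
                        quinine_gkg = c(1, 1, 1))
  scores <- normalize_scores(intake)
  expect_equal(scores$alcohol_pct, c(50, 100, 150))
  expect_equal(scores$quinine_pct, c(100, 100, 100))
})

test_that("identical subjects all score exactly 100", {
  intake <- make_intake(letters[1:5], rep(2.5, 5), rep(1.2, 5))
  scores <- normalize_scores(intake)
  expect_equal(scores$alcohol_pct, rep(100, 5))
  expect_equal(scores$quinine_pct, rep(100, 5))
})

test_that("score means are conserved at 100 on random cohorts", {
  set.seed(13)
  for (i in 1:20) {
    scores <- normalize_scores(random_intake_table(sample(2:40, 1)))
    expect_equal(mean(scores$alcohol_pct), 100, tolerance = 1e-9)
    expect_equal(mean(scores$quinine_pct), 100, tolerance = 1e-9)
  }
})

test_that("degenerate cohorts are refused", {
  expect_error(normalize_scores(make_intake("a", 2, 1)),
               class = "starpheno_degenerate_cohort_error")
  expect_error(normalize_scores(make_intake(c("a", "b"), c(0, 0), c(1, 1))),
               class = "starpheno_degenerate_cohort_error")
})

test_that("classification follows the published rules with precedence", {
  expect_equal(as.character(classify_subject(80, 70)), "Low")
  expect_equal(as.character(classify_subject(120, 70)), "High")
  # above-average punished intake overrides a low alcohol score
  expect_equal(as.character(classify_subject(60, 130)), "Compulsive")
  # exact 100 resolves to the less severe label
  expect_equal(as.character(classify_subject(100, 100)), "Low")
  expect_equal(as.character(classify_subject(150, 100)), "High")
  expect_error(classify_subject(Inf, 50), class = "starpheno_domain_error")
})

test_that("cohort phenotyping labels every subject exactly once", {
  set.seed(29)
  intake <- random_intake_table(20)
  ph <- phenotype_cohort(intake)
  expect_equal(nrow(ph), 20)
  expect_false(anyNA(ph$label))
  expect_setequal(levels(ph$label), c("Low", "High", "Compulsive"))
  # dominant quinine drinker must be Compulsive
  intake2 <- make_intake(letters[1:4], c(1, 1, 1, 1), c(1, 1, 1, 10))
  ph2 <- suppressWarnings(phenotype_cohort(intake2))
  expect_equal(as.character(ph2$label[ph2$subject == "d"]), "Compulsive")
})

test_that("small cohorts trigger the minimum-sample warning", {
  set.seed(30)
  intake <- random_intake_table(8)
  expect_warning(phenotype_cohort(intake), "unstable below 15")
  expect_silent(phenotype_cohort(intake, min_n = 5))
})

test_that("scores and labels are invariant to uniform intake scaling", {
  set.seed(31)
  intake <- random_intake_table(15)
  ph <- phenotype_cohort(intake)
  for (c_scale in c(0.2, 3, 17)) {
    scaled <- dplyr::mutate(intake, intake_gkg = intake_gkg * c_scale)
    ph2 <- phenotype_cohort(scaled)
    expect_equal(ph2$alcohol_pct, ph$alcohol_pct)
    expect_equal(ph2$quinine_pct, ph$quinine_pct)
    expect_equal(ph2$label, ph$label)
  }
})

test_that("reordering subjects permutes results identically", {
  set.seed(32)
  intake <- random_intake_table(15)
  ph <- phenotype_cohort(intake)
  perm <- intake[sample(nrow(intake)), ]
  ph2 <- phenotype_cohort(perm)
  ph2 <- ph2[match(ph$subject, ph2$subject), ]
  expect_equal(ph2$alcohol_pct, ph$alcohol_pct)
  expect_equal(as.character(ph2$label), as.character(ph$label))
})

test_that("raising a subject's punished intake never demotes it from Compulsive", {
  set.seed(33)
  intake <- random_intake_table(15)
  ph <- phenotype_cohort(intake)
  target <- ph$subject[which(ph$label == "Compulsive")[1]]
  skip_if(is.na(target))
  for (bump in c(1.2, 2, 5)) {
    bumped <- dplyr::mutate(
      intake,
      intake_gkg = ifelse(subject == target & condition == "alcohol_quinine",
                          intake_gkg * bump, intake_gkg))
    ph2 <- phenotype_cohort(bumped)
    expect_equal(as.character(ph2$label[ph2$subject == target]),
                 "Compulsive")
  }
})

test_that("missing sessions fall back to the mean of available sessions", {
  set.seed(34)
  intake <- random_intake_table(10)
  # dropping one quinine session only changes that subject's quinine mean
  drop_row <- which(intake$subject == "s001" &
                      intake$condition == "alcohol_quinine")[1]
  reduced <- intake[-drop_row, ]
  s1 <- normalize_scores(reduced)
  manual <- mean(reduced$intake_gkg[reduced$subject == "s001" &
                                      reduced$condition == "alcohol_quinine"])
  expect_equal(s1$quinine_gkg[s1$subject == "s001"], manual)
  # a subject with zero sessions in one condition is dropped with a warning
  gone <- intake[!(intake$subject == "s002" &
                     intake$condition == "alcohol_quinine"), ]
  expect_warning(out <- normalize_scores(gone), "s002")
  expect_false("s002" %in% out$subject)
})
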