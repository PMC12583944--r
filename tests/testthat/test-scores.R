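mk_score_table <- function(session = 1, profession, topic_scores_r1,
                           topic_scores_r2) {
  topics <- teamstepps_topics()
  rbind(
    data.frame(session = session, profession = profession, rater = 1,
               topic = topics, score = topic_scores_r1),
    data.frame(session = session, profession = profession, rater = 2,
               topic = topics, score = topic_scores_r2))
}

test_that("min-max scaling anchors the declared ranges", {
  tab <- mk_score_table(1, "radiological technologist",
                        c(6, 4, 5, 5, 4), c(6, 4, 5, 5, 4))
  sc <- scale_scores(tab)
  # team structure range 2-10, both raters 6 -> 0.5
  expect_equal(sc$scaled[sc$topic == "team structure"], 0.5)
  # raters at the range minimum -> 0
  expect_equal(sc$scaled[sc$topic == "communication"], 0)
  # medical doctor overall: raters' overalls 69 and 77, range 23-115
  md <- mk_score_table(1, "medical doctor",
                       c(12, 13, 17, 17, 10), c(14, 14, 21, 17, 11))
  scmd <- scale_scores(md)
  expect_equal(scmd$scaled[scmd$topic == "overall"], (73 - 23) / 92)
  # out-of-range score is refused with the record named
  bad <- tab; bad$score[1] <- 11
  expect_error(scale_scores(bad), "outside")
})

test_that("scaling is invariant to a common shift of scores and bounds", {
  tab <- mk_score_table(1, "medical doctor",
                        c(10, 12, 20, 15, 9), c(12, 11, 22, 14, 10))
  rng <- default_topic_ranges()
  sc1 <- scale_scores(tab, rng)
  shift <- 3
  tab2 <- tab; tab2$score <- tab2$score + shift
  rng2 <- rng
  md_topics <- rng2$profession == "medical doctor" & rng2$topic != "overall"
  rng2$min[md_topics] <- rng2$min[md_topics] + shift
  rng2$max[md_topics] <- rng2$max[md_topics] + shift
  ov <- rng2$profession == "medical doctor" & rng2$topic == "overall"
  rng2$min[ov] <- rng2$min[ov] + 5 * shift
  rng2$max[ov] <- rng2$max[ov] + 5 * shift
  sc2 <- scale_scores(tab2, rng2)
  expect_equal(sc2$scaled, sc1$scaled)
})

test_that("group score needs all six professions and is order-invariant", {
  profs <- unique(default_topic_ranges()$profession)
  vals <- c(0.3, 0.4, 0.55, 0.54, 0.37, 0.52)
  sc <- data.frame(session = 1, profession = profs, topic = "overall",
                   scaled = vals)
  g <- group_score(sc, roster = profs)
  expect_equal(g$value, mean(vals))
  expect_true(g$complete)
  g2 <- group_score(sc[sample(6), ], roster = profs)
  expect_equal(g2$value, g$value)
  g3 <- group_score(sc[-2, ], roster = profs)
  expect_true(is.na(g3$value))
  expect_false(g3$complete)
})

test_that("ICC(2,1) matches the ANOVA oracle and its known cases", {
  m <- cbind(1:6, 2:7)
  expect_lt(abs(icc21(m) - oracle_icc21(m)), 1e-9)
  for (i in 1:5) {
    set.seed(600 + i)
    mm <- matrix(rnorm(24, 10, 2), 12, 2)
    expect_lt(abs(icc21(mm) - oracle_icc21(mm)), 1e-9)
  }
  # identical raters agree perfectly
  expect_equal(as.numeric(icc21(cbind(1:8, 1:8))), 1)
  # a constant offset breaks absolute agreement
  expect_lt(as.numeric(icc21(cbind(1:8, (1:8) + 2))), 1)
  # independently drawn columns: near zero at large n
  set.seed(601)
  m0 <- cbind(rnorm(500), rnorm(500))
  expect_lt(abs(as.numeric(icc21(m0))), 0.1)
  expect_error(icc21(matrix(1:4, 2, 2)), "at least 3")
})

test_that("ICC labels follow the published bands", {
  expect_equal(icc_interpret(0.73)[["cicchetti"]], "good")
  expect_equal(icc_interpret(0.75)[["cicchetti"]], "excellent")
  expect_equal(icc_interpret(0.32)[["cicchetti"]], "poor")
  expect_equal(icc_interpret(0.45)[["cicchetti"]], "fair")
  expect_equal(icc_interpret(0.45)[["koo_li"]], "poor")
  expect_equal(icc_interpret(0.6)[["koo_li"]], "moderate")
  expect_equal(icc_interpret(0.8)[["koo_li"]], "good")
  expect_equal(icc_interpret(0.95)[["koo_li"]], "excellent")
  expect_error(icc_interpret(1.2), "exceed")
})
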