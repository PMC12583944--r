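test_that("MCD flags a planted gross outlier and spares clean data", {
  set.seed(41)
  X <- rbind(matrix(rnorm(200), 100, 2), c(50, 50))
  fl <- mcd_outliers(X, seed = 1)
  expect_true(fl[101])
  # clean bivariate normal: flagged fraction small at alpha = .001
  set.seed(42)
  X2 <- matrix(rnorm(400), 200, 2)
  expect_lte(mean(mcd_outliers(X2, seed = 2)), 0.03)
  expect_error(mcd_outliers(matrix(rnorm(10), 5, 2)), "at least 10")
  expect_error(mcd_outliers(cbind(1:20, 1:20)), "rank-deficient")
})

test_that("MCD flags are invariant under affine maps of the cloud", {
  set.seed(43)
  X <- rbind(matrix(rnorm(300), 150, 2), matrix(c(8, -7, 9, 8), 2, 2))
  th <- 0.7
  A <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2) %*% diag(c(3, 0.5))
  f1 <- mcd_outliers(X, seed = 7)
  f2 <- mcd_outliers(X %*% t(A) + 5, seed = 7)
  expect_equal(as.logical(f1), as.logical(f2))
})

test_that("Pearson correlation matches hand computation and the t test", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson_r(1:10, -(1:10))$r, -1)
  pr <- pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(pr$r, 0.8)
  expect_error(pearson_r(1:5, rep(2, 5)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("BH adjustment matches the brute-force definition", {
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(44)
  for (i in 1:200) {
    m <- sample(3:30, 1)
    p <- runif(m)^sample(c(1, 3), 1)
    adj <- bh_adjust(p)
    or <- oracle_bh(p, m)
    expect_equal(adj, or$adjusted, tolerance = 1e-12)
    expect_equal(adj < 0.05, or$rejected)
  }
})

test_that("minimum detectable r reproduces the closed form and a power
          simulation", {
  expect_equal(round(min_detectable_r(30), 2), 0.49)
  expect_lt(min_detectable_r(1e6), 0.005)
  r50 <- min_detectable_r(50)
  expect_equal(r50, tanh((qnorm(0.975) + qnorm(0.8)) / sqrt(47)))
  # Monte-Carlo power at the detectable effect is close to the target
  set.seed(45)
  nrep <- 4000
  hits <- replicate(nrep, {
    x <- rnorm(50)
    y <- r50 * x + sqrt(1 - r50^2) * rnorm(50)
    cor.test(x, y)$p.value < 0.05
  })
  expect_lt(abs(mean(hits) - 0.8), 0.04)
  expect_error(min_detectable_r(3), "exceed 3")
})

mk_grid_inputs <- function(n_sessions, link = 0, seed = 1, level = "group") {
  set.seed(seed)
  regions <- c("anterior", "central", "posterior")
  bands <- c("all", "alpha")
  coh <- runif(n_sessions)
  ti <- expand.grid(session = seq_len(n_sessions), region = regions,
                    band = bands, stringsAsFactors = FALSE)
  ti$value <- rnorm(nrow(ti), 0, 0.3) +
    ifelse(ti$region == "anterior" & ti$band == "alpha",
           2 * coh[ti$session], 0)
  sc <- expand.grid(session = seq_len(n_sessions),
                    topic = c(teamstepps_topics(), "overall"),
                    stringsAsFactors = FALSE)
  sc$scaled <- link * coh[sc$session] + rnorm(nrow(sc), 0.5, 0.05)
  list(ti = ti, scores = sc)
}

test_that("the grid always has 36 cases and handles degeneracies", {
  gi <- mk_grid_inputs(12, seed = 46)
  g <- correlation_grid(gi$ti, gi$scores, level = "group")
  expect_equal(nrow(g), 36L)
  expect_equal(attr(g, "m"), 36L)
  expect_equal(unique(table(g$score)), 6L)
  expect_true(all(g$n_after_outliers <= g$n_total))
  expect_true(all(g$p_adjusted >= g$p_raw, na.rm = TRUE))
  # identical scores for every session: zero variance, all undefined
  gi2 <- gi; gi2$scores$scaled <- 0.5
  g2 <- correlation_grid(gi2$ti, gi2$scores, level = "group")
  expect_equal(nrow(g2), 36L)
  expect_true(all(is.na(g2$r)))
})

test_that("a planted negative link is recovered in the right cell only", {
  gi <- mk_grid_inputs(15, link = -0.4, seed = 47)
  g <- correlation_grid(gi$ti, gi$scores, level = "group")
  hit <- g[g$region == "anterior" & g$band == "alpha" &
             g$score == "overall", ]
  expect_lt(hit$r, -0.7)
  expect_true(hit$significant)
  # central cells carry no planted signal
  expect_true(all(!g$significant[g$region == "central"]))
})

test_that("sign recovery and null behaviour across seeded replicates", {
  signs <- sapply(1:50, function(r) {
    gi <- mk_grid_inputs(15, link = -0.4, seed = 1000 + r)
    g <- correlation_grid(gi$ti, gi$scores, level = "group", seed = r)
    g$r[g$region == "anterior" & g$band == "alpha" & g$score == "overall"]
  })
  expect_gte(mean(signs < 0), 0.95)
  any_sig <- sapply(1:40, function(r) {
    gi <- mk_grid_inputs(15, link = 0, seed = 2000 + r)
    g <- correlation_grid(gi$ti, gi$scores, level = "group", seed = r)
    any(g$significant)
  })
  expect_lte(mean(any_sig), 0.10)
})
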