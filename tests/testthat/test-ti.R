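test_that("self-coherence is exactly 1 and degenerate K is refused", {
  set.seed(1)
  x <- matrix(rnorm(10 * 125), 10, 125)
  C <- coherence_epochs(x, x)
  expect_true(all(abs(C$coh - 1) < 1e-12))
  expect_error(coherence_epochs(x[1, , drop = FALSE], x[1, , drop = FALSE]),
               "K=1")
})

test_that("independent signals show only the 1/K coherence bias", {
  set.seed(7)
  K <- 60
  x <- matrix(rnorm(K * 125), K, 125)
  y <- matrix(rnorm(K * 125), K, 125)
  C <- coherence_epochs(x, y)
  expect_lte(mean(C$coh[1:20]), 0.05)
})

test_that("signal-plus-noise coherence matches the closed form s/(1+s)", {
  # y = x + independent noise with per-bin SNR s  =>  C = s/(1+s)
  for (snr in c(0.5, 2)) {
    set.seed(100 + round(10 * snr))
    K <- 200
    x <- matrix(rnorm(K * 125), K, 125)
    y <- x + matrix(rnorm(K * 125, sd = sqrt(1 / snr)), K, 125)
    C <- coherence_epochs(x, y)
    expect_lt(abs(mean(C$coh[2:40]) - snr / (1 + snr)), 0.05)
  }
})

test_that("band TI closed forms and additivity hold", {
  expect_equal(band_ti(rep(0, 30), band_spec("all")), 0)
  coh <- rep(0, 30); coh[8:12] <- 0.5
  expect_equal(band_ti(coh, band_spec("alpha")), 5 * log(2))
  set.seed(3)
  coh2 <- runif(30)
  expect_equal(band_ti(coh2, band_spec("all")),
               band_ti(coh2, band_spec("custom", c(1, 7))) +
                 band_ti(coh2, band_spec("alpha")) +
                 band_ti(coh2, band_spec("custom", c(13, 20))))
  expect_error(band_ti(runif(10), band_spec("all")), "beyond")
})

test_that("band TI and coherence match an independent brute-force oracle", {
  for (i in 1:20) {
    set.seed(500 + i)
    K <- 6; n <- 64
    x <- matrix(rnorm(K * n), K, n)
    y <- matrix(rnorm(K * n), K, n) + 0.5 * x
    C <- coherence_epochs(x, y)
    oc <- oracle_coherence(x, y)
    expect_lt(max(abs(C$coh - oc)), 1e-9)
    bd <- band_spec("custom", c(2, 9))
    expect_lt(abs(band_ti(C, bd) - oracle_band_ti(oc, 2:9)), 1e-9)
  }
})

test_that("permutation null is calibrated and validated", {
  set.seed(11)
  K <- 30
  x <- matrix(rnorm(K * 125), K, 125)
  y <- matrix(rnorm(K * 125), K, 125)
  raw <- band_ti(coherence_epochs(x, y), band_spec("all"))
  null <- permutation_null(x, y, band_spec("all"), n_perm = 400, seed = 2)
  expect_gt(raw, quantile(null$values, 0.005))
  expect_lt(raw, quantile(null$values, 0.995))
  expect_error(permutation_null(x, y, n_perm = 50), "at least 100")
  expect_error(permutation_null(x[1:5, ], y[1:5, ], n_perm = 100), "epochs")
  # identical epoch lists: misalignment destroys coherence
  null2 <- permutation_null(x, x, band_spec("all"), n_perm = 300, seed = 3)
  raw2 <- band_ti(coherence_epochs(x, x), band_spec("all"))
  expect_gte(mean(null2$values < raw2), 0.99)
})

test_that("normalization arithmetic and z calibration are correct", {
  null <- structure(list(values = rnorm(200, 5, 1), mean = 5, sd = 2,
                         n_perm = 200), class = "ti_null")
  expect_equal(normalize_ti(5, null)$z, 0)
  expect_equal(normalize_ti(9, null)$z, 2)
})

test_that("normalized TI is duration-invariant under the null", {
  med_z <- sapply(c(30, 120), function(K) {
    z <- sapply(1:200, function(r) {
      set.seed(900 + 7 * K + r)
      x <- matrix(rnorm(K * 125), K, 125)
      y <- matrix(rnorm(K * 125), K, 125)
      ti_estimate(x, y, band_spec("all"), n_perm = 120, seed = r)$z
    })
    median(z)
  })
  expect_lt(abs(med_z[1] - med_z[2]), 0.25)
})

test_that("median alpha z increases strictly with the shared weight", {
  med <- sapply(c(0, 0.3, 0.6), function(w) {
    z <- sapply(1:20, function(r) {
      pr <- make_band_coh_pair(40, 125, w^2, 8:12, seed = 2000 + 100 * w + r)
      ti_estimate(pr$x, pr$y, band_spec("alpha"), n_perm = 150,
                  seed = r)$z
    })
    median(z)
  })
  expect_true(all(diff(med) > 0))
})
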