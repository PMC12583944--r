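# Independent brute-force oracles: literal-definition implementations that
# share no code with the package internals.

# DFT by explicit summation
oracle_dft <- function(x, f) {
  n <- length(x)
  t <- 0:(n - 1)
  sum(x * exp(-2i * pi * f * t / n))
}

# Welch-style magnitude-squared coherence at integer bins 1..b_max,
# per-epoch linear detrend (explicit least squares) + Hann window,
# everything by loops and explicit sums.
oracle_coherence <- function(x_epochs, y_epochs) {
  K <- nrow(x_epochs); n <- ncol(x_epochs)
  t <- seq_len(n)
  hann <- 0.5 * (1 - cos(2 * pi * (t - 1) / (n - 1)))
  detrend <- function(v) {
    b <- sum((t - mean(t)) * (v - mean(v))) / sum((t - mean(t))^2)
    a <- mean(v) - b * mean(t)
    v - a - b * t
  }
  b_max <- (n - 1) %/% 2
  sxy <- sxx <- syy <- numeric(b_max)
  for (k in seq_len(K)) {
    xv <- detrend(x_epochs[k, ]) * hann
    yv <- detrend(y_epochs[k, ]) * hann
    for (f in seq_len(b_max)) {
      X <- oracle_dft(xv, f); Y <- oracle_dft(yv, f)
      sxy[f] <- sxy[f] + X * Conj(Y) / K
      sxx[f] <- sxx[f] + Mod(X)^2 / K
      syy[f] <- syy[f] + Mod(Y)^2 / K
    }
  }
  Mod(sxy)^2 / (sxx * syy)
}

oracle_band_ti <- function(coh, bins, clip = 1 - 1e-10) {
  tot <- 0
  for (b in bins) tot <- tot - log(1 - min(coh[b], clip))
  tot
}

# ICC(2,1) through R's own two-way ANOVA decomposition
oracle_icc21 <- function(mat) {
  df <- data.frame(y = as.vector(mat),
                   subj = factor(rep(seq_len(nrow(mat)), ncol(mat))),
                   rater = factor(rep(seq_len(ncol(mat)), each = nrow(mat))))
  tab <- suppressWarnings(anova(lm(y ~ subj + rater, data = df)))
  msr <- tab["subj", "Mean Sq"]; msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  k <- ncol(mat); n <- nrow(mat)
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

# Benjamini-Hochberg by definition: adjusted value and step-up rejection set
oracle_bh <- function(p, m = length(p), alpha = 0.05) {
  o <- order(p)
  ps <- p[o]
  adj <- numeric(length(p))
  for (i in seq_along(ps))
    adj[i] <- min(1, min(ps[i:length(ps)] * m / (i:length(ps))))
  rej_i <- which(ps <= seq_along(ps) * alpha / m)
  k <- if (length(rej_i)) max(rej_i) else 0
  rejected <- rep(FALSE, length(p))
  if (k > 0) rejected[o[seq_len(k)]] <- TRUE
  out <- numeric(length(p)); out[o] <- adj
  list(adjusted = out, rejected = rejected)
}

# Epoch pair with a flat target magnitude-squared coherence: y shares
# sqrt(C) amplitude correlation with x at every bin.
make_flat_coh_pair <- function(K, n, C, seed = 1) {
  set.seed(seed)
  a <- sqrt(sqrt(C)); b <- sqrt(1 - sqrt(C))
  x <- matrix(rnorm(K * n), K, n)
  y <- a * x + b * matrix(rnorm(K * n), K, n)
  list(x = x, y = y)
}

# Epoch pair coherent only inside a set of integer-Hz bins, built in the
# frequency domain per epoch.
make_band_coh_pair <- function(K, n, C, bins, seed = 1) {
  set.seed(seed)
  a <- sqrt(sqrt(C)); b <- sqrt(1 - sqrt(C))
  half <- (n - 1) %/% 2
  synth <- function(Z) {
    full <- complex(length.out = n)
    full[1 + seq_len(half)] <- Z
    full[n + 1 - seq_len(half)] <- Conj(Z)
    Re(fft(full, inverse = TRUE)) / sqrt(n)
  }
  x <- y <- matrix(0, K, n)
  for (k in seq_len(K)) {
    Zx <- complex(real = rnorm(half), imaginary = rnorm(half))
    Zn <- complex(real = rnorm(half), imaginary = rnorm(half))
    Zy <- Zn
    Zy[bins] <- a * Zx[bins] + b * Zn[bins]
    x[k, ] <- synth(Zx)
    y[k, ] <- synth(Zy)
  }
  list(x = x, y = y)
}
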