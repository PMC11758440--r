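test_that("response size sums the half-open window", {
  # all-ones epoch at 2-s bins: a 22-s window holds 11 bins
  ep <- rep(1, 35)
  expect_equal(response_size(ep, fs = 0.5, window = c(0, 22),
                             rel_t0 = -28), 11)
  expect_equal(response_size(ep, fs = 0.5, window = c(0, 4),
                             rel_t0 = -28), 2)
  expect_equal(response_size(rep(0, 35), 0.5, c(0, 22), -28), 0)
  # ramp: closed-form partial sum
  ramp <- seq_len(35)
  idx <- which(seq(-28, by = 2, length.out = 35) >= 0)[1:2]
  expect_equal(response_size(ramp, 0.5, c(0, 4), -28), sum(ramp[idx]))
  expect_error(response_size(ep, 0.5, c(40, 60), -28), "outside")
})

test_that("within-experiment z-scoring has exact two-point and affine behaviour", {
  rec <- data.frame(experiment = "e1", subject = "s1",
                    modality = "electrical", frequency_hz = c(7, 7),
                    trial = 1:2, fmri_size = c(1, 3),
                    neural_size = c(10, 30))
  z <- standardize_within_experiment(rec)
  expect_equal(z$fmri_size, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(z$neural_size, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  # affine invariance: shifted/scaled copies give identical z-scores
  rec2 <- rec
  rec2$fmri_size <- 5 * rec$fmri_size - 2
  z2 <- standardize_within_experiment(rec2)
  expect_equal(z2$fmri_size, z$fmri_size, tolerance = 1e-12)
  # idempotence
  expect_equal(standardize_within_experiment(z)$fmri_size, z$fmri_size,
               tolerance = 1e-12)
  # degenerate variance
  rec3 <- rec; rec3$fmri_size <- c(2, 2)
  expect_error(standardize_within_experiment(rec3), "zero variance")
})

test_that("z-scores have machine-precision mean 0 and sd 1 per experiment", {
  set.seed(8)
  rec <- data.frame(experiment = rep(c("a", "b"), each = 28),
                    subject = "s1", modality = "electrical",
                    frequency_hz = 7, trial = 1:56,
                    fmri_size = rnorm(56), neural_size = rnorm(56))
  z <- standardize_within_experiment(rec)
  for (e in c("a", "b")) {
    v <- z$fmri_size[z$experiment == e]
    expect_lt(abs(mean(v)), 1e-12)
    expect_equal(sd(v), 1, tolerance = 1e-12)
  }
})

test_that("subject-frequency aggregation recovers planted means", {
  freqs <- c(1, 3, 5, 7, 9, 13, 17)
  plant <- outer(1:3, seq_along(freqs))   # subject x frequency means
  rec <- do.call(rbind, lapply(1:3, function(s)
    do.call(rbind, lapply(seq_along(freqs), function(fi)
      data.frame(experiment = paste0("e", s), subject = paste0("s", s),
                 modality = "electrical", frequency_hz = freqs[fi],
                 trial = 1:4, fmri_size = plant[s, fi],
                 neural_size = plant[s, fi])))))
  agg <- aggregate_subject_frequency(rec)
  expect_equal(nrow(agg), 21L)            # 3 subjects x 7 frequencies
  expect_true(all(agg$n_trials == 4L))
  got <- matrix(agg$fmri_size[order(agg$subject, agg$frequency_hz)],
                nrow = 3, byrow = TRUE)
  expect_equal(got, plant, ignore_attr = TRUE)
})

test_that("linear fit agrees with normal equations and exact lines", {
  f <- linear_fit(c(0, 1, 2), c(1, 3, 5))
  expect_equal(f$beta1, 2)
  expect_equal(f$beta0, 1)
  expect_equal(f$r2, 1)
  expect_equal(f$mse, 0)
  g <- linear_fit(1:4, 2 * (1:4), with_intercept = FALSE)
  expect_equal(g$beta1, 2)
  expect_true(is.na(g$beta0))
  expect_equal(g$r2, 1)
  # 50-point random set vs closed-form OLS
  set.seed(11)
  x <- rnorm(50); y <- 1.3 * x + 0.4 + rnorm(50)
  h <- linear_fit(x, y)
  X <- cbind(1, x)
  bet <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(h$beta0, bet[1], tolerance = 1e-10)
  expect_equal(h$beta1, bet[2], tolerance = 1e-10)
  h0 <- linear_fit(x, y, with_intercept = FALSE)
  expect_equal(h0$beta1, sum(x * y) / sum(x^2), tolerance = 1e-10)
  expect_error(linear_fit(c(1, 1, 1), 1:3), "singular")
  expect_error(linear_fit(c(0, 0), 1:2, with_intercept = FALSE),
               "singular")
})

test_that("with-intercept R^2 is invariant under affine transforms", {
  set.seed(12)
  x <- rnorm(40); y <- 0.8 * x + rnorm(40, sd = 0.5)
  r <- linear_fit(x, y)$r2
  expect_equal(linear_fit(3 * x - 1, -2 * y + 7)$r2, r,
               tolerance = 1e-12)
})

test_that("frequency-wise fits recover planted gains", {
  freqs <- c(1, 3, 5, 7)
  t0 <- -28
  base <- lapply(freqs, function(f) {
    v <- rep(0, 35); v[15:25] <- f   # some response
    zte_ts(v, fs = 0.5, t0 = t0)
  })
  names(base) <- freqs
  # constant 1.5 gain
  fm <- lapply(base, function(b) { b$values <- 1.5 * b$values; b })
  ft <- frequency_wise_timecourse_fit(fm, base)
  expect_equal(ft$beta1, rep(1.5, 4), tolerance = 1e-12)
  # gain increasing with frequency
  fm2 <- lapply(seq_along(base), function(i) {
    b <- base[[i]]; b$values <- (1 + 0.2 * i) * b$values; b
  })
  names(fm2) <- freqs
  ft2 <- frequency_wise_timecourse_fit(fm2, base)
  expect_true(all(diff(ft2$beta1) > 0))
  # zero fMRI: beta1 = 0, mse = 0
  fm0 <- lapply(base, function(b) { b$values <- 0 * b$values; b })
  ft0 <- frequency_wise_timecourse_fit(fm0, base)
  expect_equal(ft0$beta1, rep(0, 4))
  expect_equal(ft0$mse, rep(0, 4))
})

test_that("fixed reference scaling yields near-zero residuals for a global gain", {
  freqs <- c(1, 3, 5, 7)
  t <- seq(-28, 40, by = 2)
  conv <- lapply(freqs, function(f)
    zte_ts(ifelse(t >= 0, f * exp(-t / 10), 0), fs = 0.5, t0 = -28))
  names(conv) <- freqs
  fm <- lapply(conv, function(b) { b$values <- 2.5 * b$values; b })
  fx <- fixed_scaling_residuals(fm, conv, ref_frequency = 7,
                                ref_window = c(0, 4))
  expect_equal(fx$beta1, 2.5, tolerance = 1e-12)
  for (f in names(fx$residuals))
    expect_lt(max(abs(fx$residuals[[f]]$values)), 1e-10)
  # frequency-dependent gains leave residuals off-reference only
  fm2 <- lapply(seq_along(conv), function(i) {
    b <- conv[[i]]; b$values <- (2 + 0.3 * i) * b$values; b
  })
  names(fm2) <- freqs
  fx2 <- fixed_scaling_residuals(fm2, conv, 7, c(0, 4))
  tsel <- t >= 0 & t < 4
  expect_lt(max(abs(fx2$residuals[["7"]]$values[tsel])), 1e-10)
  expect_gt(max(abs(fx2$residuals[["1"]]$values)), 0.1)
  # least-squares orthogonality of the reference residual
  r7 <- fx2$residuals[["7"]]$values[tsel]
  x7 <- conv[["7"]]$values[tsel]
  expect_lt(abs(sum(r7 * x7)), 1e-9)
  expect_error(fixed_scaling_residuals(fm, conv, ref_frequency = 99),
               "not present")
})

test_that("mean of means weighs subjects, not trials", {
  # subject A: trials {0, 0}; subject B: trial {2} -> grand mean 1
  out <- mean_of_means(list(A = matrix(c(0, 0), nrow = 2),
                            B = matrix(2, nrow = 1)))
  expect_equal(out, 1)
  # single subject: its trial mean
  expect_equal(mean_of_means(list(matrix(c(1, 3), nrow = 2))), 2)
  # balanced design: equals the pooled mean
  set.seed(5)
  m1 <- matrix(rnorm(12), nrow = 3)
  m2 <- matrix(rnorm(12), nrow = 3)
  expect_equal(mean_of_means(list(m1, m2)),
               colMeans(rbind(m1, m2)), tolerance = 1e-12)
})
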