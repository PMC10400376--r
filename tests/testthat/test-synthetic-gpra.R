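test_that("zero motif effects give a constant oracle", {
  cfg <- simulator_config(n_sequences = 10, motif_effects = rep(0, 5),
                          seed = 3)
  e <- oracle_expression(random_insert(20), cfg)
  expect_equal(length(unique(e)), 1L)
  expect_equal(unique(e), 8.5)  # affine(0) at the calibration center
})

test_that("embedding an activating consensus raises oracle expression", {
  cfg <- small_sim()$cfg
  j <- which(cfg$motif_effects > 0)[1]
  pwm <- cfg$motifs[[j]]
  consensus <- paste(c("A", "C", "G", "T")[apply(pwm, 2, which.max)],
                     collapse = "")
  set.seed(21)
  deltas <- replicate(100, {
    base <- random_insert(1)
    pos <- sample(80 - nchar(consensus), 1)
    planted <- paste0(substr(base, 1, pos), consensus,
                      substr(base, pos + nchar(consensus) + 1, 80))
    oracle_expression(planted, cfg) - oracle_expression(base, cfg)
  })
  expect_gt(median(deltas), 0)
})

test_that("forward-only scoring is strand asymmetric", {
  cfg <- small_sim()$cfg
  expect_equal(cfg$strand_policy, "forward_only")
  set.seed(5)
  seqs <- random_insert(50)
  fwd <- oracle_expression(seqs, cfg)
  rev <- oracle_expression(vapply(seqs, reverse_complement, ""), cfg)
  expect_gt(mean(abs(fwd - rev) > 1e-9), 0.9)
})

test_that("measurement model reproduces the singleton structure", {
  cfg <- simulator_config(n_sequences = 10, seed = 2)
  set.seed(31)
  m <- simulate_measurement(runif(1e5, 0, 17), cfg)
  expect_true(all(m$measured >= 0 & m$measured <= 17))
  expect_true(all(m$is_singleton == (m$cells == 1L)))
  expect_true(all(abs(m$measured[m$is_singleton] -
                        round(m$measured[m$is_singleton])) < 1e-9))
  # singleton fraction = P(Poisson(1.5) = 0) = exp(-1.5), within 0.01
  expect_equal(mean(m$is_singleton), exp(-1.5), tolerance = 0.01 / exp(-1.5))
  # noiseless sorter: every cell lands in round(e_true)
  cfg0 <- simulator_config(n_sequences = 10, sort_noise_sd = 0, seed = 2)
  e <- runif(500, 0, 17)
  m0 <- simulate_measurement(e, cfg0)
  expect_equal(m0$measured, round(e))
})

test_that("simulated datasets are reproducible and properly split", {
  cfg <- simulator_config(n_sequences = 500, n_test = 100, seed = 9)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a, b)
  expect_length(intersect(a$train$insert, a$test$insert), 0L)
  expect_equal(nrow(a$train), 500L)
  expect_true(all(a$train$expression >= 0 & a$train$expression <= 17))
  expect_true(all(abs(a$train$expression[a$train$is_singleton] -
                        round(a$train$expression[a$train$is_singleton]))
                  < 1e-9))
})

test_that("high-replication test measurements track the oracle better", {
  cfg <- simulator_config(n_sequences = 10000, n_test = 10000, seed = 13)
  d <- simulate_dataset(cfg)
  tr_truth <- d$truth[d$truth$split == "train", ]
  te_truth <- d$truth[d$truth$split == "test", ]
  r_train <- cor(d$train$expression, tr_truth$oracle)
  r_test <- cor(d$test$expression, te_truth$oracle)
  expect_gt(r_test, r_train)
  expect_gt(r_test, 0.98)
})
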