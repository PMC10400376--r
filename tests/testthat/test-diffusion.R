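test_that("memoryless mutation preserves length and alphabet", {
  s <- random_insert(1)
  set.seed(1)
  expect_equal(mutate_sequence(s, 0), s)
  m1 <- mutate_sequence(s, 1)
  expect_equal(sum(strsplit(m1, "")[[1]] != strsplit(s, "")[[1]]), 1L)
  m300 <- mutate_sequence(s, 300)
  expect_equal(nchar(m300), 80L)
  expect_false(grepl("[^ACGT]", m300))
  expect_error(mutate_sequence(s, -1), "non-negative")
})

test_that("mutation process follows the per-position Markov law", {
  # fraction of changed positions after k events on an 80-mer:
  # (3/4) * (1 - (1 - 1/60)^k); Monte Carlo over 10 000 sequences
  ns <- asNamespace("seq2expr")
  set.seed(2)
  codes <- ns$random_code_matrix(10000, 80)
  for (k in c(30, 300)) {
    mut <- ns$mutate_codes(codes, k)
    frac <- mean(mut != codes)
    expected <- 3 / 4 * (1 - (1 - 1 / 60)^k)
    expect_equal(frac, expected, tolerance = 0.01 / expected)
  }
})

test_that("diffusion configuration enforces its invariants", {
  cfg <- diffusion_config()
  expect_equal(cfg$max_mutations, 300L)
  expect_equal(cfg$iterations, 100L)
  expect_equal(cfg$shift, 30L)
  expect_error(diffusion_config(shift = 100, iterations = 100), "shift")
  expect_error(diffusion_config(iterations = 400), "max_mutations")
})

test_that("generator conditioning enters as two broadcast channels", {
  cfg <- diffusion_config()
  s <- random_insert(1)
  m0 <- encode_generator_input(s, 0, 8, cfg)
  expect_equal(dim(m0), c(6L, 80L))
  expect_equal(unique(m0["n_mutations", ]), 0)
  mfull <- encode_generator_input(s, cfg$max_mutations, 8, cfg)
  expect_equal(unique(mfull["n_mutations", ]), 1)
  m_lo <- encode_generator_input(s, 10, 2, cfg)
  m_hi <- encode_generator_input(s, 10, 16, cfg)
  diff_rows <- which(rowSums(m_lo != m_hi) > 0)
  expect_equal(rownames(m_lo)[diff_rows], "expression")
  expect_error(encode_generator_input(s, 400, 8, cfg), "declared")
  expect_error(encode_generator_input(s, 10, 30, cfg), "expression")
})

test_that("generation is reproducible and emits valid sequences", {
  gen <- build_legnet(micro_config(head_type = "per_position"), seed = 8)
  cfg <- diffusion_config(max_mutations = 100L, iterations = 100L,
                          shift = 30L)
  a <- generate_promoters(gen, c(3, 8, 14), cfg, seed = 5)
  b <- generate_promoters(gen, c(3, 8, 14), cfg, seed = 5)
  expect_identical(as.character(a), as.character(b))
  c <- generate_promoters(gen, c(3, 8, 14), cfg, seed = 6)
  expect_false(identical(as.character(a), as.character(c)))
  expect_true(all(nchar(a) == 80L))
  expect_false(any(grepl("[^ACGT]", a)))
  # the declared count stays `shift` above the applied corruption
  trace <- attr(a, "trace")
  pos <- trace[trace[, "corrupted"] > 0, , drop = FALSE]
  expect_true(all(pos[, "declared"] - pos[, "corrupted"] == cfg$shift))
  # degenerate loop: one iteration, no shift -> a single denoising pass
  one <- generate_promoters(gen, 8, diffusion_config(iterations = 1L,
                                                     shift = 0L), seed = 2)
  expect_equal(nchar(one), 80L)
  expect_null(attr(one, "trace"))
})

test_that("design scoring reports correlations and handles degeneracy", {
  m <- build_legnet(tiny_config(), seed = 5)
  seqs <- random_insert(10)
  p <- predict_with_tta(m, seqs, desk_flank())$expression
  sc <- score_designs(m, seqs, p, desk_flank())
  expect_equal(sc$pearson, 1, tolerance = 1e-9)
  expect_equal(sc$spearman, 1, tolerance = 1e-9)
  expect_true(all(sc$predicted >= 0 & sc$predicted <= 17))
  const <- score_designs(m, seqs, rep(8, 10), desk_flank())
  expect_true(is.na(const$pearson))
  expect_match(const$note, "constant")
})

test_that("generator training is seed-deterministic and validated", {
  recs <- small_sim()$data$train[1:400, ]
  dcfg <- diffusion_config(max_mutations = 100L)
  gcfg <- generator_train_config(epochs = 1L, batch_size = 64L,
                                 batches_per_epoch = 3L, seed = 2L)
  arch <- micro_config(head_type = "per_position")
  a <- train_generator(recs, dcfg, gcfg, arch)
  b <- train_generator(recs, dcfg, gcfg, arch)
  expect_identical(a$log$train_loss, b$log$train_loss)
  expect_true(all(is.finite(a$log$val_loss)))
  expect_error(train_generator(recs, dcfg, gcfg, micro_config()),
               "per_position")
})

test_that("mutation ceiling calibration tracks expression decay", {
  cfg <- small_sim()$cfg
  cal <- mutations_to_randomness(cfg, k_grid = c(10, 75, 300),
                                 n_sequences = 500, seed = 4)
  expect_equal(nrow(cal), 3L)
  # correlation decays with mutation load and is near zero at saturation
  expect_gt(cal$correlation[1], cal$correlation[3])
  expect_lt(abs(cal$correlation[3]), 0.15)
  expect_identical(mutations_to_randomness(cfg, k_grid = c(10, 75, 300),
                                           n_sequences = 500, seed = 4),
                   cal)
})
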