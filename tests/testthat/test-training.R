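test_that("one-cycle schedule has the documented endpoints and shape", {
  cfg <- train_config()
  total <- 1000L
  lr <- one_cycle_lr(0:(total - 1), total, cfg)
  expect_equal(lr[1], 0.005 / 25)
  expect_equal(max(lr), 0.005)  # peak equals max_lr exactly
  ws <- max(1, round(cfg$warmup_fraction * (total - 1)))
  expect_equal(lr[ws + 1], 0.005)  # end of phase 1
  expect_equal(lr[total], 0.005 / 1e4)
  # unimodal: nondecreasing then nonincreasing
  expect_true(all(diff(lr[1:(ws + 1)]) >= 0))
  expect_true(all(diff(lr[(ws + 1):total]) <= 0))
  expect_error(one_cycle_lr(total, total, cfg), "step")
})

test_that("optimizers implement their published contracts", {
  cfg_a <- train_config(optimizer = "adamw", max_lr = 0.005)
  cfg_l <- train_config(optimizer = "lion", max_lr = 0.005)
  p <- list(w = 5)
  oa <- make_optimizer(cfg_a, p)
  ol <- make_optimizer(cfg_l, p)
  expect_equal(oa$lr_scale * 0.005, 0.005)
  expect_equal(oa$wd, 0.01)
  expect_equal(ol$lr_scale * 0.005, 0.0005)  # 10-fold reduced lr
  expect_equal(ol$wd, 0.1)                   # 10-fold increased decay
  # descent sanity on a quadratic: loss (w - 2)^2 decreases
  for (opt0 in list(oa, ol)) {
    params <- list(w = 5)
    opt <- opt0
    losses <- numeric(50)
    for (i in 1:50) {
      g <- list(w = 2 * (params$w - 2))
      st <- optimizer_step(opt, params, g, lr = 0.05)
      params <- st$params; opt <- st$opt
      losses[i] <- (params$w - 2)^2
    }
    expect_lt(losses[50], losses[1])
  }
})

test_that("plateau scheduler only ever reduces the rate", {
  s <- plateau_scheduler(0.1, factor = 0.5, patience = 2)
  rates <- numeric(10)
  losses <- c(1, 0.9, 0.9, 0.9, 0.9, 0.8, 0.8, 0.8, 0.8, 0.8)
  for (i in seq_along(losses)) {
    s <- plateau_update(s, losses[i])
    rates[i] <- s$lr
  }
  expect_true(all(diff(rates) <= 0))
  expect_lt(rates[10], 0.1)
})

test_that("k-fold splits are disjoint, covering and deterministic", {
  recs <- small_sim()$data$train[1:100, ]
  sp <- kfold_validation(recs, k = 10, fold_index = 0, seed = 4)
  expect_equal(nrow(sp$validation), 10L)
  expect_equal(nrow(sp$train), 90L)
  expect_equal(sort(c(sp$train$insert, sp$validation$insert)),
               sort(recs$insert))
  sp2 <- kfold_validation(recs, k = 10, fold_index = 0, seed = 4)
  expect_identical(sp, sp2)
  expect_error(kfold_validation(recs[1:5, ], 10, 0), "fewer")
  expect_error(kfold_validation(recs, 10, 10), "fold_index")
})

test_that("training reduces the loss and is seed-deterministic", {
  recs <- small_sim()$data$train[1:1000, ]
  tc <- train_config(batch_size = 64L, batches_per_epoch = NULL,
                     epochs = 2L, seed = 3L)
  r1 <- train_predictor(recs, tc, tiny_config(), desk_flank())
  expect_lt(r1$log$mean_loss[2], r1$log$mean_loss[1])
  r2 <- train_predictor(recs, tc, tiny_config(), desk_flank())
  expect_identical(r1$log$mean_loss, r2$log$mean_loss)
})

test_that("regression loss and reference-path variants train end to end", {
  recs <- small_sim()$data$train[1:200, ]
  tc <- train_config(batch_size = 50L, batches_per_epoch = 2L,
                     epochs = 1L, seed = 5L, loss = "mse_regression")
  r <- train_predictor(recs, tc, micro_config(), desk_flank())
  expect_true(is.finite(r$log$mean_loss))
  # CP-SE configuration exercises the double-precision reference path
  tc2 <- train_config(batch_size = 50L, batches_per_epoch = 2L,
                      epochs = 1L, seed = 5L)
  r2 <- train_predictor(recs, tc2,
                        micro_config(se_variant = "custom_lowrank",
                                     cp_rank = 2L),
                        desk_flank())
  expect_true(is.finite(r2$log$mean_loss))
  # reduce-on-plateau scheduler variant runs
  tc3 <- train_config(batch_size = 50L, batches_per_epoch = 2L,
                      epochs = 2L, seed = 5L,
                      scheduler = "reduce_on_plateau")
  r3 <- train_predictor(recs, tc3, micro_config(), desk_flank())
  expect_equal(nrow(r3$log), 2L)
  # strict orientation doubling mode runs
  tc4 <- train_config(batch_size = 50L, batches_per_epoch = 1L,
                      epochs = 1L, seed = 5L, augment = "double")
  r4 <- train_predictor(recs, tc4, micro_config(), desk_flank())
  expect_true(is.finite(r4$log$mean_loss))
})

test_that("test-time augmentation averages the two orientations", {
  m <- build_legnet(tiny_config(), seed = 6)
  seqs <- random_insert(8)
  p <- predict_with_tta(m, seqs, desk_flank())
  expect_equal(nrow(p), 8L)
  expect_true(all(p$expression >= 0 & p$expression <= 17))
  p_f <- predict_with_tta(m, seqs, desk_flank(), tta = FALSE)
  expect_false(isTRUE(all.equal(p$expression, p_f$expression)))
  # a model blind to the orientation channel gives predictions invariant
  # to reverse-complementing the input (empty flank)
  blind <- m
  blind$stem$conv$W[, 6, ] <- 0
  pb <- predict_with_tta(blind, seqs, desk_flank())
  pr <- predict_with_tta(blind, vapply(seqs, reverse_complement, ""),
                         desk_flank())
  expect_equal(pb$expression, pr$expression, tolerance = 1e-5)
})

test_that("invalid sequences are skipped with a warning", {
  m <- build_legnet(micro_config(), seed = 2)
  seqs <- c(ok = random_insert(1, 40), bad = "ACGTN")
  expect_warning(p <- predict_with_tta(m, seqs, desk_flank()), "skipped")
  expect_equal(p$id, "ok")
  expect_equal(attr(p, "skipped"), "bad")
})

test_that("ensembling averages member predictions", {
  m1 <- build_legnet(tiny_config(), seed = 1)
  m2 <- build_legnet(tiny_config(), seed = 2)
  seqs <- random_insert(5)
  single <- predict_with_tta(m1, seqs, desk_flank())
  e1 <- ensemble_predict(list(m1), seqs, desk_flank())
  expect_equal(e1$expression, single$expression)
  edup <- ensemble_predict(list(m1, m1, m1), seqs, desk_flank())
  expect_equal(edup$expression, single$expression)
  e2 <- ensemble_predict(list(m1, m2), seqs, desk_flank())
  p2 <- predict_with_tta(m2, seqs, desk_flank())
  expect_equal(e2$expression, (single$expression + p2$expression) / 2)
  expect_error(ensemble_predict(list(), seqs), "at least one")
})
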