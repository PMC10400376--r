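test_that("published configurations reproduce the printed totals", {
  orig <- original_config()
  expect_equal(count_parameters(build_legnet(orig)), 1852846L)
  expect_equal(receptive_field(orig), 79L)
  opt <- optimized_config()
  expect_equal(round(count_parameters(build_legnet(opt)) / 1e5), 21)
  expect_equal(receptive_field(opt), 79L)
  expect_equal(orig$block_channels, c(128L, 128L, 64L, 64L, 64L, 64L))
  expect_equal(opt$conv_mode, "depthwise")
  expect_equal(orig$n_bins, 18L)
})

test_that("receptive field follows the stride-1 kernel arithmetic", {
  one <- micro_config(block_channels = 8L, kernel_size = 7L,
                      group_size = 8L)
  # stem k7 (6) + one block: spatial (6) + resize (6) -> 19
  expect_equal(receptive_field(one), 19L)
  add <- micro_config(block_channels = 8L, kernel_size = 7L,
                      group_size = 8L, residual_variant = "add")
  expect_equal(receptive_field(add), 13L)  # no resize conv
  # two kernel-3 blocks: 1 + 2 + 2 * (2 + 2)
  expect_equal(receptive_field(micro_config(kernel_size = 3L)), 11L)
})

test_that("forward pass emits normalized bin distributions", {
  m <- build_legnet(original_config(), seed = 2)
  set.seed(1)
  x <- array(runif(6 * 150 * 2), c(6, 150, 2))
  fw <- seq2expr:::forward_legnet(m, x)
  expect_equal(dim(fw$probs), c(18L, 2L))
  expect_true(all(abs(colSums(fw$probs) - 1) < 1e-6))
  # batch-order equivariance
  fw2 <- seq2expr:::forward_legnet(m, x[, , 2:1, drop = FALSE])
  expect_equal(fw$probs, fw2$probs[, 2:1], tolerance = 1e-10)
})

test_that("seeded construction is reproducible bit for bit", {
  a <- build_legnet(tiny_config(), seed = 11)
  b <- build_legnet(tiny_config(), seed = 11)
  expect_identical(seq2expr:::collect_params(a),
                   seq2expr:::collect_params(b))
  c <- build_legnet(tiny_config(), seed = 12)
  expect_false(identical(seq2expr:::collect_params(a),
                         seq2expr:::collect_params(c)))
})

test_that("every ablation axis is reachable through the configuration", {
  variants <- list(
    micro_config(final_activation_before_pool = FALSE),
    micro_config(se_variant = "custom_lowrank", cp_rank = 3L),
    micro_config(residual_variant = "add"),
    micro_config(group_size = 8L),
    micro_config(conv_mode = "depthwise"),
    micro_config(expansion_policy = "efficientnetv2", expansion_ratio = 2),
    micro_config(block_channels = c(8L, 8L, 8L, 8L))
  )
  set.seed(3)
  x <- array(runif(6 * 40 * 2), c(6, 40, 2))
  for (cfg in variants) {
    m <- build_legnet(cfg, seed = 1)
    fw <- seq2expr:::forward_legnet(m, x)
    expect_true(all(abs(colSums(fw$probs) - 1) < 1e-6))
  }
})

test_that("configuration validation rejects inconsistent settings", {
  expect_error(micro_config(kernel_size = 6L), "odd")
  expect_error(micro_config(se_variant = "custom_lowrank", cp_rank = 0L),
               "cp_rank")
  expect_error(micro_config(group_size = 3L), "divide")
  expect_error(legnet_config(block_channels = integer()), "one block")
})

test_that("network summary reflects the concat channel contract", {
  m <- build_legnet(tiny_config())
  tab <- network_summary(m)
  rs <- tab[grepl("resize", tab$layer), ]
  blocks <- tiny_config()$block_channels
  c_in <- c(tiny_config()$stem_channels, head(blocks, -1))
  expect_equal(rs$c_in, c_in + blocks)
  expect_equal(rs$c_out, blocks)
  expect_equal(attr(tab, "parameter_count"), count_parameters(m))
  expect_equal(attr(tab, "receptive_field"), receptive_field(m$config))
})

test_that("SE gating behaves as channel attention", {
  ns <- asNamespace("seq2expr")
  set.seed(4)
  x <- array(rnorm(8 * 10 * 3), c(8, 10, 3))
  se <- ns$nn_se_std(8L, 4L)
  # force the gate to one: identity on the input
  se$W2[] <- 0; se$b2[] <- 1e4
  expect_equal(ns$se_fw(se, x)$y, x, tolerance = 1e-10)
  # squeeze of a constant-along-positions input is that constant
  xc <- array(rep(rnorm(8), times = 30), c(8, 10, 3))
  expect_equal(ns$se_fw(se, xc)$cache$s, matrix(xc[, 1, ], 8, 3))
  # CP factorization stores fewer parameters than the dense bilinear form
  cp <- ns$nn_se_cp(64L, 16L, 10L)
  cp_params <- length(cp$A) + length(cp$Bf) + length(cp$Cf)
  expect_lt(cp_params, 16 * 64 * 64)
})

test_that("analytic gradients match finite differences", {
  cfg <- micro_config(se_variant = "custom_lowrank", cp_rank = 3L,
                      kernel_size = 3L)
  model <- build_legnet(cfg, seed = 42)
  ns <- asNamespace("seq2expr")
  set.seed(7)
  x <- array(runif(6 * 12 * 4), c(6, 12, 4))
  target <- matrix(expression_to_bins(c(3, 8, 11, 15)), 18, 4)
  lossfn <- function(m) {
    fw <- ns$forward_legnet(m, x, training = TRUE)
    kl_loss(target, fw$probs)
  }
  fw <- ns$forward_legnet(model, x, training = TRUE)
  grads <- ns$flatten_grads(
    ns$backward_legnet(model, fw$caches, (fw$probs - target) / 4))
  params <- ns$collect_params(model)
  eps <- 1e-6
  set.seed(8)
  for (nm in sample(names(params), 12)) {
    j <- sample(length(params[[nm]]), 1)
    pp <- params
    pp[[nm]][j] <- pp[[nm]][j] + eps
    lp <- lossfn(ns$set_params(model, pp))
    pp[[nm]][j] <- pp[[nm]][j] - 2 * eps
    lm <- lossfn(ns$set_params(model, pp))
    num <- (lp - lm) / (2 * eps)
    expect_equal(grads[[nm]][j], num, tolerance = 1e-3)
  }
})

test_that("fused single-precision step matches the reference path", {
  ns <- asNamespace("seq2expr")
  set.seed(5)
  x <- array(runif(6 * 20 * 3), c(6, 20, 3))
  # pooled-bins head with KL loss
  m <- build_legnet(micro_config(), seed = 5)
  target <- matrix(expression_to_bins(c(4, 9, 14)), 18, 3)
  fw <- ns$forward_legnet(m, x, training = TRUE)
  gref <- ns$flatten_grads(
    ns$backward_legnet(m, fw$caches, (fw$probs - target) / 3))
  ff <- ns$fast_flatten(m)
  r <- ns$fast_step(ff$values, ff$groups, ff$n_blocks, x, target, 0L, 0L,
                    TRUE, TRUE, TRUE)
  expect_equal(r$loss, kl_loss(target, fw$probs), tolerance = 1e-5)
  expect_equal(r$probs, fw$probs, tolerance = 1e-5, ignore_attr = TRUE)
  gfast <- stats::setNames(r$grads[ff$trainable], ff$names[ff$trainable])
  for (nm in names(gref)) {
    scale <- max(1e-6, max(abs(gref[[nm]])))
    expect_lt(max(abs(gref[[nm]] - gfast[[nm]])) / scale, 1e-4)
  }
  # per-position head with cross-entropy
  g <- build_legnet(micro_config(head_type = "per_position"), seed = 5)
  codes <- matrix(sample.int(4L, 60, replace = TRUE), 20, 3)
  t2 <- ns$encode_codes_batch(codes, 0, 0)[1:4, , , drop = FALSE]
  fw2 <- ns$forward_legnet(g, x, training = TRUE)
  gref2 <- ns$flatten_grads(
    ns$backward_legnet(g, fw2$caches, (fw2$probs - t2) / 60))
  ff2 <- ns$fast_flatten(g)
  r2 <- ns$fast_step(ff2$values, ff2$groups, ff2$n_blocks, x, t2, 1L, 2L,
                     TRUE, FALSE, TRUE)
  gfast2 <- stats::setNames(r2$grads[ff2$trainable], ff2$names[ff2$trainable])
  for (nm in names(gref2)) {
    scale <- max(1e-6, max(abs(gref2[[nm]])))
    expect_lt(max(abs(gref2[[nm]] - gfast2[[nm]])) / scale, 1e-4)
  }
})

test_that("checkpoints round trip with a JSON sidecar", {
  m <- build_legnet(micro_config(), seed = 9)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  back <- load_checkpoint(path)
  expect_identical(seq2expr:::collect_params(back),
                   seq2expr:::collect_params(m))
  sidecar <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(sidecar$seed, 9L)
  expect_equal(sidecar$parameter_count, count_parameters(m))
  expect_equal(sidecar$config$stem_channels, 16L)
})
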