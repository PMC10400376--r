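# Shared fixtures: a small seeded synthetic GPRA dataset, the desk-scale
# 80-bp frame used for fast training runs, and memoised heavy artifacts
# (the trained desk predictor) shared between the recovery and diffusion
# acceptance tests.

desk_flank <- function() flank_context(strrep("N", 80), frame = 80)

.fixture_env <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- simulator_config(n_sequences = 2000, n_test = 400, seed = 42)
    .fixture_env$small <- list(cfg = cfg, data = simulate_dataset(cfg))
  }
  .fixture_env$small
}

# The full desk-scale study: 50 000 simulated training rows, tiny
# architecture, 5 epochs. Trained once and reused by the acceptance tests.
desk_study <- function() {
  if (is.null(.fixture_env$study)) {
    cfg <- simulator_config(n_sequences = 50000, seed = 1)
    data <- simulate_dataset(cfg)
    tc <- train_config(batch_size = 128L, batches_per_epoch = NULL,
                       epochs = 5L, seed = 1L)
    fit <- train_predictor(data$train, tc, tiny_config(),
                           flank = desk_flank())
    .fixture_env$study <- list(cfg = cfg, data = data, model = fit$model,
                               log = fit$log)
  }
  .fixture_env$study
}

random_insert <- function(n = 1, len = 80) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
}

# A tiny architecture for fast structural tests (seconds, not minutes);
# named arguments override the defaults.
micro_config <- function(head_type = "pooled_bins", ...) {
  args <- list(stem_channels = 16L, block_channels = c(8L, 8L),
               conv_mode = "grouped", group_size = 4L,
               se_variant = "efficientnetv2", se_reduction = 2L,
               expansion_policy = "fixed_ratio", expansion_ratio = 1,
               head_type = head_type)
  do.call(legnet_config, utils::modifyList(args, list(...)))
}

# Numerical-integration oracle for E[clamp(floor(X), 0, 17)] with
# X ~ N(e + 0.5, 0.5): quadrature over each unit interval, independent of
# the closed-form CDF differences used by the implementation.
integration_oracle <- function(e) {
  total <- 0
  for (i in 0:17) {
    lo <- if (i == 0) -20 else i
    hi <- if (i == 17) 40 else i + 1
    total <- total + i * stats::integrate(function(x)
      stats::dnorm(x, e + 0.5, 0.5), lo, hi, rel.tol = 1e-12)$value
  }
  total
}

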