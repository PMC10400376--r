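# Bridge to the fused single-precision C++ step (src/fast_step.cpp). The
# fused path covers the standard topology (concatenation residual,
# standard SE); other configurations (CP-factorized SE, additive
# residual) run through the layer-by-layer double-precision reference
# implementation, which the fused path is tested against.

fast_eligible <- function(config) {
  config$residual_variant == "concat" &&
    config$se_variant == "efficientnetv2"
}

# Flatten a model into the fixed parameter order of fast_step: stem stage,
# then per block (expand, spatial, se, project, resize), then head W and
# bias. Each stage contributes W, gamma, beta, run_mean, run_var; only the
# first three are trainable. Returns values, aligned names (matching
# collect_params), a trainable mask, spatial groups per block and the
# positions of the running statistics in forward order (stem, then
# expand/spatial/project/resize per block).
fast_flatten <- function(model) {
  values <- list(); nms <- character(); trainable <- logical()
  rm_idx <- integer(); rv_idx <- integer()
  add <- function(v, n, tr) {
    values[[length(values) + 1L]] <<- v
    nms[length(nms) + 1L] <<- n
    trainable[length(trainable) + 1L] <<- tr
    length(values)
  }
  add_stage <- function(st, prefix) {
    add(st$conv$W, paste0(prefix, ".W"), TRUE)
    add(st$bn$gamma, paste0(prefix, ".gamma"), TRUE)
    add(st$bn$beta, paste0(prefix, ".beta"), TRUE)
    rm_idx[length(rm_idx) + 1L] <<-
      add(st$bn$run_mean, paste0(prefix, ".run_mean"), FALSE)
    rv_idx[length(rv_idx) + 1L] <<-
      add(st$bn$run_var, paste0(prefix, ".run_var"), FALSE)
  }
  add_stage(model$stem, "stem")
  groups <- integer(length(model$blocks))
  for (i in seq_along(model$blocks)) {
    bl <- model$blocks[[i]]
    p <- function(part) sprintf("block%d.%s", i, part)
    add_stage(bl$expand, p("expand"))
    add_stage(bl$spatial, p("spatial"))
    groups[i] <- bl$spatial$conv$groups
    add(bl$se$W1, p("se.W1"), TRUE)
    add(bl$se$b1, p("se.b1"), TRUE)
    add(bl$se$W2, p("se.W2"), TRUE)
    add(bl$se$b2, p("se.b2"), TRUE)
    add_stage(bl$project, p("project"))
    add_stage(bl$resize, p("resize"))
  }
  add(model$head$W, "head.W", TRUE)
  add(model$head$b, "head.b", TRUE)
  list(values = values, names = nms, trainable = trainable,
       groups = groups, rm_idx = rm_idx, rv_idx = rv_idx,
       n_blocks = length(model$blocks))
}

# Write a fast_flatten value list back into the model structure.
fast_unflatten <- function(model, values, nms) {
  v <- stats::setNames(values, nms)
  put_stage <- function(st, prefix) {
    st$conv$W <- v[[paste0(prefix, ".W")]]
    st$bn$gamma <- as.numeric(v[[paste0(prefix, ".gamma")]])
    st$bn$beta <- as.numeric(v[[paste0(prefix, ".beta")]])
    st$bn$run_mean <- as.numeric(v[[paste0(prefix, ".run_mean")]])
    st$bn$run_var <- as.numeric(v[[paste0(prefix, ".run_var")]])
    st
  }
  model$stem <- put_stage(model$stem, "stem")
  for (i in seq_along(model$blocks)) {
    bl <- model$blocks[[i]]
    p <- function(part) sprintf("block%d.%s", i, part)
    bl$expand <- put_stage(bl$expand, p("expand"))
    bl$spatial <- put_stage(bl$spatial, p("spatial"))
    bl$se$W1 <- v[[p("se.W1")]]
    bl$se$b1 <- as.numeric(v[[p("se.b1")]])
    bl$se$W2 <- v[[p("se.W2")]]
    bl$se$b2 <- as.numeric(v[[p("se.b2")]])
    bl$project <- put_stage(bl$project, p("project"))
    bl$resize <- put_stage(bl$resize, p("resize"))
    model$blocks[[i]] <- bl
  }
  model$head$W <- v[["head.W"]]
  model$head$b <- as.numeric(v[["head.b"]])
  model
}

loss_code <- function(loss) {
  switch(loss, kl_soft_classification = 0L, mse_regression = 1L,
         per_position_ce = 2L, stopf("unknown loss '%s'", loss))
}

# Forward-only closure: uses the fused float path when the configuration
# supports it, otherwise the reference implementation (eval mode).
make_forward <- function(model) {
  cfg <- model$config
  if (fast_eligible(cfg)) {
    ff <- fast_flatten(model)
    head_code <- if (cfg$head_type == "pooled_bins") 0L else 1L
    function(x) {
      fast_step(ff$values, ff$groups, ff$n_blocks, x, NULL, head_code,
                -1L, FALSE, cfg$final_activation_before_pool, FALSE)$probs
    }
  } else {
    function(x) forward_legnet(model, x, training = FALSE)$probs
  }
}
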