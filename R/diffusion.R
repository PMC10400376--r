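# Cold-diffusion promoter design. A conditioned denoiser (the network
# trunk with a per-position 4-way head) is trained to reconstruct original
# sequences from memorylessly mutated copies given the declared mutation
# count and the original expression. Generation starts from a fully random
# sequence and iteratively denoises while re-corrupting with a shifted
# (smaller) mutation count, which tricks the model into drifting far from
# the random start toward the target expression.

#' Diffusion configuration
#'
#' Defaults follow the published illustrative run: a 300-mutation ceiling
#' (enough to make expression indistinguishable from random sequences),
#' 100 generation iterations with 100 declared mutations at the first
#' step, and a shift of 30.
#'
#' @param max_mutations Mutation-count ceiling used for training and
#'   conditioning normalization.
#' @param iterations Number of denoising iterations during generation.
#' @param shift Corruption-count shift: after denoising with declared
#'   count `n`, the sequence is re-corrupted with `max(n - 1 - shift, 0)`
#'   mutations and re-supplied with declared count `n - 1`.
#' @param insert_length Designed sequence length.
#' @param conditioning Conditioning scheme; mutation count and target
#'   expression enter as two broadcast input channels.
#' @param seed Default generation seed.
#' @return A `diffusion_config` object.
#' @export
diffusion_config <- function(max_mutations = 300L, iterations = 100L,
                             shift = 30L, insert_length = 80L,
                             conditioning = "extra_channels", seed = 1L) {
  stopifnot(shift >= 0, shift < iterations, iterations <= max_mutations,
            insert_length >= 1)
  structure(list(max_mutations = as.integer(max_mutations),
                 iterations = as.integer(iterations),
                 shift = as.integer(shift),
                 insert_length = as.integer(insert_length),
                 conditioning = match.arg(conditioning, "extra_channels"),
                 seed = as.integer(seed)),
            class = "diffusion_config")
}

#' Generator training configuration
#'
#' Published regime: 200 epochs, AdamW at learning rate 0.001, batches of
#' 1024, 1000 batches per epoch, 4:1 train-to-validation split. Desk-scale
#' runs override the sizes.
#'
#' @param epochs,lr,batch_size,batches_per_epoch Training regime; if
#'   `batches_per_epoch` is `NULL`, each epoch is one pass over the data.
#' @param weight_decay Decoupled AdamW weight decay.
#' @param train_val_ratio Train:validation ratio (4 means 4:1).
#' @param n_range Optional length-2 integer range restricting the drawn
#'   mutation counts (e.g. `c(0, 0)` for the copy task); defaults to
#'   `0:max_mutations`.
#' @param seed Training seed (split, corruption, init).
#' @return A `generator_train_config` object.
#' @export
generator_train_config <- function(epochs = 200L, lr = 0.001,
                                   batch_size = 1024L,
                                   batches_per_epoch = 1000L,
                                   weight_decay = 0.01,
                                   train_val_ratio = 4, n_range = NULL,
                                   seed = 1L) {
  stopifnot(epochs >= 1, lr > 0, batch_size >= 1, train_val_ratio > 0,
            weight_decay >= 0)
  structure(list(epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay,
                 batches_per_epoch =
                   if (is.null(batches_per_epoch)) NULL
                   else as.integer(batches_per_epoch),
                 train_val_ratio = train_val_ratio,
                 n_range = if (is.null(n_range)) NULL
                   else as.integer(n_range),
                 seed = as.integer(seed)),
            class = "generator_train_config")
}

# Apply k memoryless substitution events to each column of an integer code
# matrix (L x B). Events are applied sequentially: each picks a position
# uniformly (with replacement across events) and replaces the current base
# with one of the other three, so later events can revert earlier ones.
mutate_codes <- function(codes, k) {
  L <- nrow(codes); B <- ncol(codes)
  k <- rep_len(as.integer(k), B)
  if (any(k < 0)) stopf("mutation count must be non-negative")
  kmax <- max(k)
  if (kmax == 0L) return(codes)
  for (round in seq_len(kmax)) {
    act <- which(k >= round)
    pos <- sample.int(L, length(act), replace = TRUE)
    jump <- sample.int(3L, length(act), replace = TRUE)
    i <- cbind(pos, act)
    codes[i] <- ((codes[i] - 1L + jump) %% 4L) + 1L
  }
  codes
}

#' Apply k memoryless point substitutions to a sequence
#'
#' Each of the `k` events independently picks a position uniformly and
#' replaces the current base with one of the other three; the process has
#' no memory, so an event can revert an earlier substitution. A single
#' event always changes its position, so `k = 1` gives Hamming distance
#' exactly 1. Uses the current RNG state (seed with `set.seed()` for
#' reproducibility).
#'
#' @param seq DNA string over `{A,C,G,T}`.
#' @param k Number of substitution events (>= 0).
#' @return The mutated sequence.
#' @export
mutate_sequence <- function(seq, k) {
  if (k < 0) stopf("mutation count must be non-negative")
  codes <- matrix(seq_to_codes(seq, allow_n = FALSE), ncol = 1)
  codes_to_seq(mutate_codes(codes, k)[, 1])
}

# Batch generator input: 4 one-hot channels + declared-mutation channel
# (n / max_mutations) + expression channel (e / 17), both broadcast along
# positions. codes: L x B.
encode_generator_batch <- function(codes, n_declared, expression, cfg) {
  B <- ncol(codes); L <- nrow(codes)
  n_declared <- rep_len(n_declared, B)
  expression <- rep_len(expression, B)
  if (any(n_declared < 0 | n_declared > cfg$max_mutations))
    stopf("declared mutation count outside [0, max_mutations]")
  if (any(expression < 0 | expression > 17))
    stopf("conditioning expression outside [0, 17]")
  arr <- encode_codes_batch(codes, n_declared / cfg$max_mutations,
                            expression / 17)
  arr
}

#' Encode a generator input sequence with its conditioning
#'
#' @param seq DNA string of length `cfg$insert_length`.
#' @param n_declared Declared mutation count in `[0, max_mutations]`.
#' @param expression Conditioning expression in `[0, 17]`.
#' @param cfg A [diffusion_config].
#' @return A 6 x L matrix: 4 one-hot nucleotide channels plus the
#'   constant channels `n_declared / max_mutations` and
#'   `expression / 17`.
#' @export
encode_generator_input <- function(seq, n_declared, expression, cfg) {
  codes <- matrix(seq_to_codes(seq, allow_n = FALSE), ncol = 1)
  m <- encode_generator_batch(codes, n_declared, expression, cfg)[, , 1]
  rownames(m) <- c("A", "C", "G", "T", "n_mutations", "expression")
  m
}

#' Desk-scale generator architecture
#'
#' The generator reuses the convolutional trunk with a per-position 4-way
#' head instead of the pooled classification head.
#'
#' @return A [legnet_config] with `head_type = "per_position"`.
#' @export
tiny_generator_config <- function() {
  legnet_config(stem_channels = 32L,
                block_channels = c(24L, 24L, 24L),
                conv_mode = "grouped", group_size = 16L,
                se_variant = "efficientnetv2", se_reduction = 4L,
                expansion_policy = "fixed_ratio", expansion_ratio = 2,
                head_type = "per_position")
}

#' Train the cold-diffusion generator
#'
#' Every training example draws a mutation count `n` uniformly from the
#' configured range, corrupts the sequence with `n` memoryless
#' substitutions, and trains the per-position 4-way classifier to
#' reconstruct the original sequence given the corrupted sequence, `n`,
#' and the original expression; the loss is the mean per-position
#' cross-entropy.
#'
#' @param records A [gpra_records] data frame (insert + expression).
#' @param diffusion_cfg A [diffusion_config].
#' @param gen_cfg A [generator_train_config].
#' @param arch A [legnet_config] with `head_type = "per_position"`.
#' @param model Optionally, an already-built generator to continue
#'   training.
#' @return `list(model, log)`; the log holds per-epoch train loss,
#'   validation loss and validation per-position accuracy.
#' @export
train_generator <- function(records, diffusion_cfg = diffusion_config(),
                            gen_cfg = generator_train_config(),
                            arch = tiny_generator_config(), model = NULL) {
  stopifnot(arch$head_type == "per_position",
            nrow(records) >= 2)
  L <- diffusion_cfg$insert_length
  if (any(nchar(records$insert) != L))
    stopf("all inserts must have length %d", L)
  n_range <- gen_cfg$n_range %||% c(0L, diffusion_cfg$max_mutations)
  if (is.null(model)) model <- build_legnet(arch, seed = gen_cfg$seed)
  else arch <- model$config
  n <- nrow(records)
  codes <- vapply(strsplit(toupper(records$insert), "", fixed = TRUE),
                  function(ch) match(ch, c("A", "C", "G", "T")),
                  integer(L))
  expr <- records$expression
  # 4:1 (or configured) train/validation split, seeded
  perm <- with_seed(sub_seed(gen_cfg$seed, "split"), sample.int(n))
  n_val <- max(1L, round(n / (gen_cfg$train_val_ratio + 1)))
  val_idx <- perm[seq_len(n_val)]
  tr_idx <- perm[-seq_len(n_val)]
  steps_per_epoch <- ceiling(length(tr_idx) / gen_cfg$batch_size)
  if (!is.null(gen_cfg$batches_per_epoch))
    steps_per_epoch <- min(steps_per_epoch, gen_cfg$batches_per_epoch)
  use_fast <- fast_eligible(arch)
  if (use_fast) {
    ff <- fast_flatten(model)
    vals <- ff$values
    params <- stats::setNames(ff$values[ff$trainable],
                              ff$names[ff$trainable])
  } else {
    params <- collect_params(model)
  }
  opt <- make_optimizer(train_config(max_lr = gen_cfg$lr,
                                     weight_decay = gen_cfg$weight_decay,
                                     optimizer = "adamw"), params)
  log <- vector("list", gen_cfg$epochs)
  with_seed(sub_seed(gen_cfg$seed, "gen-train"), {
    for (epoch in seq_len(gen_cfg$epochs)) {
      t0 <- proc.time()[["elapsed"]]
      eperm <- sample(tr_idx)
      losses <- numeric(steps_per_epoch)
      for (s in seq_len(steps_per_epoch)) {
        lo <- (s - 1L) * gen_cfg$batch_size + 1L
        idx <- eperm[lo:min(lo + gen_cfg$batch_size - 1L, length(eperm))]
        B <- length(idx)
        orig <- codes[, idx, drop = FALSE]
        nk <- sample(n_range[1]:n_range[2], B, replace = TRUE)
        corrupt <- mutate_codes(orig, nk)
        x <- encode_generator_batch(corrupt, nk, expr[idx], diffusion_cfg)
        target <- encode_codes_batch(orig, 0, 0)[1:4, , , drop = FALSE]
        if (use_fast) {
          vals[ff$trainable] <- params
          r <- fast_step(vals, ff$groups, ff$n_blocks, x, target, 1L, 2L,
                         TRUE, FALSE, TRUE)
          loss <- r$loss
          grads <- stats::setNames(r$grads[ff$trainable], names(params))
          n_el <- prod(dim(x)[2:3])
          ub <- n_el / max(n_el - 1, 1)
          for (j in seq_along(ff$rm_idx)) {
            vals[[ff$rm_idx[j]]] <- 0.9 * vals[[ff$rm_idx[j]]] +
              0.1 * r$bn_mu[[j]]
            vals[[ff$rv_idx[j]]] <- 0.9 * vals[[ff$rv_idx[j]]] +
              0.1 * r$bn_var[[j]] * ub
          }
        } else {
          fw <- forward_legnet(model, x, training = TRUE)
          model <- fw$model
          pm <- matrix(fw$probs, 4L, L * B)
          tm <- matrix(target, 4L, L * B)
          loss <- -mean(colSums(tm * log(pmax(pm, 1e-12))))
          dz <- (fw$probs - target) / (L * B)
          grads <- flatten_grads(backward_legnet(model, fw$caches, dz))
        }
        if (!is.finite(loss))
          stopf("non-finite generator loss at epoch %d step %d", epoch, s)
        stepped <- optimizer_step(opt, params, grads, gen_cfg$lr)
        params <- stepped$params; opt <- stepped$opt
        if (!use_fast) model <- set_params(model, params)
        losses[s] <- loss
      }
      if (use_fast) {
        vals[ff$trainable] <- params
        model <- fast_unflatten(model, vals, ff$names)
      }
      val <- generator_validate(model, codes[, val_idx, drop = FALSE],
                                expr[val_idx], n_range, diffusion_cfg)
      log[[epoch]] <- data.frame(epoch = epoch,
                                 train_loss = mean(losses),
                                 val_loss = val$loss,
                                 val_accuracy = val$accuracy,
                                 wall = proc.time()[["elapsed"]] - t0)
    }
  })
  list(model = model, log = do.call(rbind, log))
}

# Validation loss/accuracy of a generator on held-out sequences (uses the
# current RNG stream for corruption draws).
generator_validate <- function(model, codes, expr, n_range, diffusion_cfg,
                               max_rows = 1024L) {
  if (ncol(codes) > max_rows) {
    keep <- seq_len(max_rows)
    codes <- codes[, keep, drop = FALSE]; expr <- expr[keep]
  }
  B <- ncol(codes); L <- nrow(codes)
  nk <- sample(n_range[1]:n_range[2], B, replace = TRUE)
  corrupt <- mutate_codes(codes, nk)
  x <- encode_generator_batch(corrupt, nk, expr, diffusion_cfg)
  fwd <- make_forward(model)
  probs <- fwd(x)
  target <- encode_codes_batch(codes, 0, 0)[1:4, , , drop = FALSE]
  pm <- matrix(probs, 4L, L * B)
  tm <- matrix(target, 4L, L * B)
  calls <- max.col(t(pm), ties.method = "first")
  truth <- max.col(t(tm), ties.method = "first")
  list(loss = -mean(colSums(tm * log(pmax(pm, 1e-12)))),
       accuracy = mean(calls == truth))
}

#' Per-position reconstruction accuracy of a generator
#'
#' Corrupts each record with `n` mutations and measures the fraction of
#' positions the denoiser restores correctly.
#'
#' @param model A trained generator.
#' @param records A [gpra_records] data frame.
#' @param n Mutation count applied before denoising.
#' @param diffusion_cfg A [diffusion_config].
#' @param seed Corruption seed.
#' @return Mean per-position accuracy.
#' @export
generator_accuracy <- function(model, records, n, diffusion_cfg, seed = 1L) {
  L <- diffusion_cfg$insert_length
  codes <- vapply(strsplit(toupper(records$insert), "", fixed = TRUE),
                  function(ch) match(ch, c("A", "C", "G", "T")),
                  integer(L))
  with_seed(sub_seed(seed, "gen-acc"),
    generator_validate(model, codes, records$expression, c(n, n),
                       diffusion_cfg, max_rows = ncol(codes))$accuracy)
}

#' Generate promoter sequences with a target expression
#'
#' Cold-diffusion loop: start from uniformly random sequences with the
#' declared mutation counter `n = iterations`; repeatedly (1) denoise by
#' per-position argmax of the generator conditioned on `(n, target)`,
#' (2) decrement `n`, (3) stop when `n` reaches 0, otherwise (4) corrupt
#' the denoised sequence with `max(n - shift, 0)` memoryless mutations.
#' The declared count stays `shift` above the actual corruption (the
#' shifted schedule drives the model to keep introducing changes).
#'
#' @param generator A trained generator model.
#' @param target_expression Numeric vector of target expressions in
#'   `[0, 17]` (one designed sequence per entry).
#' @param cfg A [diffusion_config].
#' @param seed Generation seed; the run is reproducible given
#'   (checkpoint, seed, config, decode settings).
#' @param decode `"argmax"` takes the most probable base per position;
#'   `"sample"` draws each base from the (temperature-sharpened)
#'   per-position posterior. Sampling avoids the copy fixed point of
#'   lightly trained denoisers, whose per-position argmax simply returns
#'   the input at high declared corruption (see the methods vignette).
#' @param temperature Softmax temperature for `decode = "sample"`;
#'   values below 1 sharpen the posterior.
#' @return Character vector of designed sequences, with a `trace`
#'   attribute recording the declared and applied mutation counts per
#'   iteration.
#' @export
generate_promoters <- function(generator, target_expression,
                               cfg = diffusion_config(),
                               seed = cfg$seed,
                               decode = c("argmax", "sample"),
                               temperature = 1) {
  stopifnot(all(target_expression >= 0 & target_expression <= 17),
            temperature > 0)
  decode <- match.arg(decode)
  B <- length(target_expression)
  L <- cfg$insert_length
  fwd <- make_forward(generator)
  with_seed(sub_seed(seed, "generate"), {
    codes <- random_code_matrix(B, L)
    n <- cfg$iterations
    trace <- list()
    repeat {
      x <- encode_generator_batch(codes, n, target_expression, cfg)
      pm <- matrix(fwd(x), 4L, L * B)
      if (decode == "argmax") {
        codes <- matrix(max.col(t(pm), ties.method = "first"), L, B)
      } else {
        if (temperature != 1) {
          pm <- pm ^ (1 / temperature)
          pm <- sweep(pm, 2, colSums(pm), "/")
        }
        u <- runif(L * B)
        cum <- apply(pm, 2, cumsum)
        codes <- matrix(colSums(cum < rep(u, each = 4L)) + 1L, L, B)
      }
      n <- n - 1L
      if (n == 0L) break
      k <- max(n - cfg$shift, 0L)
      trace[[length(trace) + 1L]] <- c(declared = n, corrupted = k)
      if (k > 0L) codes <- mutate_codes(codes, k)
    }
    out <- apply(codes, 2, function(cl)
      paste(c("A", "C", "G", "T")[cl], collapse = ""))
    attr(out, "trace") <- do.call(rbind, trace)
    out
  })
}

#' Score designed sequences with a predictor
#'
#' @param predictor A trained expression predictor.
#' @param sequences Designed sequences.
#' @param targets Target expressions the designs were generated for.
#' @param flank A [flank_context].
#' @return `list(predicted, pearson, spearman, n, note)`.
#' @export
score_designs <- function(predictor, sequences, targets,
                          flank = flank_context()) {
  stopifnot(length(sequences) == length(targets))
  pred <- predict_with_tta(predictor, sequences, flank)$expression
  cc <- correlations(targets, pred)
  list(predicted = pred, pearson = cc$pearson, spearman = cc$spearman,
       n = cc$n, note = cc$note %||% "")
}

#' Calibrate the mutation-count ceiling against an expression oracle
#'
#' Reproduces the numeric procedure behind the mutation ceiling: apply
#' `k` memoryless substitutions to random sequences and measure how
#' correlated the oracle expression remains with the starting sequences.
#' The smallest `k` whose correlation drops below `threshold` is the
#' count sufficient to make expression indistinguishable from random
#' sequences, and is a sensible `max_mutations` for that assay.
#'
#' @param cfg A [simulator_config] supplying the oracle.
#' @param k_grid Integer vector of mutation counts to probe.
#' @param n_sequences Monte-Carlo sample size.
#' @param threshold Absolute-correlation cutoff.
#' @param seed Seed for the draw.
#' @return A data frame (`k`, `correlation`) with the selected ceiling in
#'   the `recommended` attribute (`NA` if no probed `k` crosses the
#'   cutoff).
#' @export
mutations_to_randomness <- function(cfg, k_grid = c(25, 50, 75, 100, 150,
                                                    200, 300),
                                    n_sequences = 2000L, threshold = 0.05,
                                    seed = 1L) {
  with_seed(sub_seed(seed, "mut-cal"), {
    codes <- random_code_matrix(n_sequences, cfg$insert_length)
    e0 <- oracle_expression(codes, cfg)
    cors <- vapply(k_grid, function(k)
      cor(e0, oracle_expression(mutate_codes(codes, k), cfg)), numeric(1))
    out <- data.frame(k = as.integer(k_grid), correlation = cors)
    hit <- which(abs(cors) < threshold)
    attr(out, "recommended") <- if (length(hit))
      out$k[hit[1]] else NA_integer_
    out
  })
}
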