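# Synthetic GPRA simulator: a deterministic sequence->expression oracle
# built from a planted motif grammar (random information-rich PWMs with
# signed effect weights) and a sorting-bin measurement model that
# reproduces the singleton structure of the real assay: each sequence is
# observed in 1 + Poisson(lambda) cells, each cell is sorted into a bin
# around the true expression, and the measured expression is the mean bin
# number. Sequences seen in a single cell are singletons with integer
# measured expression.

# One random log-odds PWM (4 x width), sharp columns (Dirichlet 0.2).
random_pwm <- function(width) {
  p <- matrix(stats::rgamma(4 * width, shape = 0.2), 4, width)
  p <- sweep(p, 2, colSums(p), "/")
  p <- pmax(p, 1e-4)
  log2(p / 0.25)
}

#' Configuration of the synthetic GPRA experiment
#'
#' All stochastic pieces (motif draw, oracle calibration) are fixed at
#' construction time from `seed`, so the resulting oracle is a pure
#' function of sequence.
#'
#' @param n_sequences Number of training sequences to simulate.
#' @param insert_length Insert length in base pairs.
#' @param n_motifs Number of random planted PWMs (used when `motifs` is
#'   `NULL`).
#' @param motifs Optional list of 4 x width log-odds PWMs.
#' @param motif_effects Signed effect weight per motif (activators
#'   positive, repressors negative).
#' @param strand_policy `"forward_only"` scores motifs on the given strand
#'   only (strand-asymmetric grammar); `"both_strands"` takes the best
#'   window over both orientations.
#' @param lambda_cells Poisson rate of extra cells per sequence; each
#'   sequence is observed in `1 + Poisson(lambda_cells)` cells, so the
#'   singleton fraction is `exp(-lambda_cells)`.
#' @param lambda_cells_test Elevated rate used for the held-out test
#'   table, mimicking its higher-replication measurements.
#' @param sort_noise_sd SD of the Gaussian sorting noise, in bins.
#' @param n_test Number of held-out test sequences.
#' @param expression_scale Optional `list(center, scale, offset)` affine
#'   map from raw motif score to expression; when `NULL` it is calibrated
#'   on random sequences so expression centers at 8.5 with SD 3 before
#'   clamping to `[0, 17]`.
#' @param seed Seed fixing motifs, calibration and dataset draws.
#' @return A `simulator_config` object.
#' @export
simulator_config <- function(n_sequences = 50000L, insert_length = 80L,
                             n_motifs = 5L, motifs = NULL,
                             motif_effects = NULL,
                             strand_policy = c("forward_only",
                                               "both_strands"),
                             lambda_cells = 1.5, lambda_cells_test = 20,
                             sort_noise_sd = 1.0, n_test = 5000L,
                             expression_scale = NULL, seed = 1L) {
  strand_policy <- match.arg(strand_policy)
  stopifnot(n_sequences >= 1, lambda_cells >= 0, sort_noise_sd >= 0)
  if (is.null(motifs)) {
    motifs <- with_seed(sub_seed(seed, "motifs"), {
      widths <- sample(6:10, n_motifs, replace = TRUE)
      lapply(widths, random_pwm)
    })
  }
  if (any(vapply(motifs, ncol, 1L) > insert_length))
    stopf("motif longer than the insert")
  if (is.null(motif_effects)) {
    k <- length(motifs)
    motif_effects <- with_seed(sub_seed(seed, "effects"),
      sample(c(-1, 1), k, replace = TRUE) * runif(k, 0.5, 2))
  }
  cfg <- list(n_sequences = as.integer(n_sequences),
              insert_length = as.integer(insert_length),
              motifs = motifs, motif_effects = motif_effects,
              strand_policy = strand_policy,
              lambda_cells = lambda_cells,
              lambda_cells_test = lambda_cells_test,
              sort_noise_sd = sort_noise_sd, n_test = as.integer(n_test),
              expression_scale = expression_scale,
              seed = as.integer(seed))
  class(cfg) <- "simulator_config"
  if (is.null(cfg$expression_scale))
    cfg$expression_scale <- calibrate_scale(cfg)
  cfg
}

random_code_matrix <- function(n, L) {
  matrix(sample.int(4L, n * L, replace = TRUE), nrow = L, ncol = n)
}

# Raw grammar score: sum over motifs of effect * best sliding-window
# log-odds (over strands per policy). codes: L x N matrix.
raw_scores <- function(codes, cfg) {
  L <- nrow(codes); n <- ncol(codes)
  total <- numeric(n)
  for (j in seq_along(cfg$motifs)) {
    M <- cfg$motifs[[j]]
    w <- ncol(M)
    best <- rep(-Inf, n)
    mats <- list(M)
    if (cfg$strand_policy == "both_strands")
      mats <- c(mats, list(M[4:1, w:1, drop = FALSE]))
    for (Mk in mats) {
      for (start in seq_len(L - w + 1L)) {
        s <- numeric(n)
        for (k in seq_len(w))
          s <- s + Mk[codes[start + k - 1L, ], k]
        best <- pmax(best, s)
      }
    }
    total <- total + cfg$motif_effects[j] * best
  }
  total
}

calibrate_scale <- function(cfg) {
  with_seed(sub_seed(cfg$seed, "calibrate"), {
    codes <- random_code_matrix(2000L, cfg$insert_length)
    raw <- raw_scores(codes, cfg)
    s0 <- stats::sd(raw)
    list(center = mean(raw),
         scale = if (is.finite(s0) && s0 > 1e-12) 3 / s0 else 0,
         offset = 8.5)
  })
}

#' Oracle expression of sequences under the planted grammar
#'
#' Deterministic ground truth: the affine-mapped motif score, clamped to
#' `[0, 17]`.
#'
#' @param seqs Character vector of insert sequences (or an integer code
#'   matrix, one column per sequence).
#' @param cfg A [simulator_config].
#' @return Numeric vector of oracle expressions.
#' @export
oracle_expression <- function(seqs, cfg) {
  codes <- if (is.matrix(seqs)) seqs
  else vapply(seqs, function(s) seq_to_codes(s, FALSE),
              integer(cfg$insert_length))
  if (nrow(codes) != cfg$insert_length)
    stopf("sequence length %d does not match insert_length %d",
          nrow(codes), cfg$insert_length)
  sc <- cfg$expression_scale
  e <- (raw_scores(codes, cfg) - sc$center) * sc$scale + sc$offset
  pmin(pmax(e, 0), 17)
}

#' Simulate the sorting-bin measurement of true expressions
#'
#' Each sequence is observed in `m = 1 + Poisson(lambda)` cells; every
#' cell's bin is `clamp(round(e_true + N(0, sort_noise_sd)), 0, 17)` and
#' the measured expression is the mean bin number. `m == 1` yields a
#' singleton with integer measured expression.
#'
#' @param e_true Numeric vector of true expressions in `[0, 17]`.
#' @param cfg A [simulator_config].
#' @param lambda Poisson rate (defaults to `cfg$lambda_cells`).
#' @return Data frame `measured`, `is_singleton`, `cells`.
#' @export
simulate_measurement <- function(e_true, cfg, lambda = cfg$lambda_cells) {
  n <- length(e_true)
  m <- 1L + rpois(n, lambda)
  cell_of <- rep.int(seq_len(n), m)
  bins <- round(e_true[cell_of] + rnorm(length(cell_of), 0,
                                        cfg$sort_noise_sd))
  bins <- pmin(pmax(bins, 0), 17)
  measured <- as.numeric(rowsum(bins, cell_of)) / m
  data.frame(measured = measured, is_singleton = m == 1L, cells = m)
}

#' Simulate a full synthetic GPRA dataset
#'
#' Draws disjoint random train and test sequence sets, measures the train
#' set at the singleton-heavy replication level (`lambda_cells`) and the
#' test set at high replication (`lambda_cells_test`), and returns the
#' oracle truth separately so evaluation code never leaks it into
#' training.
#'
#' @param cfg A [simulator_config].
#' @return `list(train = , test = , truth = )`: two [gpra_records] tables
#'   and a truth data frame (`insert`, `oracle`, `split`).
#' @export
simulate_dataset <- function(cfg) {
  with_seed(sub_seed(cfg$seed, "dataset"), {
    n_all <- cfg$n_sequences + cfg$n_test
    codes <- random_code_matrix(n_all, cfg$insert_length)
    seqs <- apply(codes, 2, function(cl)
      paste(c("A", "C", "G", "T")[cl], collapse = ""))
    dup <- duplicated(seqs)
    while (any(dup)) {
      codes[, dup] <- random_code_matrix(sum(dup), cfg$insert_length)
      seqs[dup] <- apply(codes[, dup, drop = FALSE], 2, function(cl)
        paste(c("A", "C", "G", "T")[cl], collapse = ""))
      dup <- duplicated(seqs)
    }
    oracle <- oracle_expression(codes, cfg)
    tr <- seq_len(cfg$n_sequences)
    te <- cfg$n_sequences + seq_len(cfg$n_test)
    m_tr <- simulate_measurement(oracle[tr], cfg)
    m_te <- simulate_measurement(oracle[te], cfg,
                                 lambda = cfg$lambda_cells_test)
    list(
      train = gpra_records(seqs[tr], m_tr$measured, m_tr$is_singleton),
      test = gpra_records(seqs[te], m_te$measured, m_te$is_singleton),
      truth = data.frame(insert = seqs, oracle = oracle,
                         split = rep(c("train", "test"),
                                     c(length(tr), length(te))),
                         stringsAsFactors = FALSE)
    )
  })
}
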