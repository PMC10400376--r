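# Soft-classification label transform: expression values become 18-bin
# target distributions under a Gaussian measurement-noise heuristic, the
# model is trained with a KL divergence loss, and scalar expression is
# decoded from predicted bin probabilities by soft-argmax.

N_BINS <- 18L

#' Transform expression values into 18-bin target distributions
#'
#' A measured expression `e` (the average of observed sorting-bin numbers)
#' is treated as arising from a latent expression distributed
#' `N(mean = e + 0.5, sd = 0.5)`. Bin `i` (1-16) receives the probability
#' mass of the `[i, i+1)` interval; the boundary bins 0 and 17 absorb the
#' full tails `(-Inf, 1]` and `[17, Inf)`, so the 18 probabilities sum to
#' one exactly by construction.
#'
#' @param e Numeric vector of expression values in `[0, 17]`.
#' @param mu_offset,sd Location offset and scale of the Gaussian noise
#'   model (defaults 0.5 and 0.5).
#' @return If `length(e) == 1`, a length-18 probability vector (bin 0 at
#'   index 1); otherwise an 18 x `length(e)` matrix.
#' @export
#' @examples
#' p <- expression_to_bins(8)
#' sum(p)            # exactly 1
#' p[9]              # pnorm(1) - pnorm(-1)
expression_to_bins <- function(e, mu_offset = 0.5, sd = 0.5) {
  if (any(!is.finite(e)) || any(e < 0 | e > 17))
    stopf("expression must be finite and within [0, 17]")
  mu <- e + mu_offset
  edges <- 1:17  # interior bin edges
  cdf <- vapply(edges, function(x) pnorm(x, mean = mu, sd = sd),
                numeric(length(e)))
  cdf <- matrix(cdf, nrow = length(e))  # length(e) x 17
  probs <- cbind(cdf[, 1, drop = FALSE],
                 cdf[, -1, drop = FALSE] - cdf[, -17, drop = FALSE],
                 1 - cdf[, 17, drop = FALSE])
  probs <- t(probs)  # 18 x n
  rownames(probs) <- as.character(0:17)
  if (length(e) == 1) probs[, 1] else probs
}

#' Decode expression from a bin distribution by soft-argmax
#'
#' Returns the expected bin number `sum(i * p_i)` over bins 0-17; combined
#' with a softmax output layer this is the soft-argmax decoding of the
#' classifier head.
#'
#' @param d A length-18 probability vector or an 18 x n matrix of
#'   distributions (columns).
#' @return Numeric expression value(s) in `[0, 17]`.
#' @export
soft_argmax <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != N_BINS) stopf("expected %d bins, got %d", N_BINS, nrow(d))
  s <- colSums(d)
  if (any(abs(s - 1) > 1e-6))
    stopf("bin distribution is not normalized (sum deviates by %.2e)",
          max(abs(s - 1)))
  as.numeric(colSums(d * 0:17))
}

#' Kullback-Leibler divergence loss between target and predicted bins
#'
#' Computes `KL(target || predicted) = sum(t * log(t / p))` with the
#' `0 * log(0) = 0` convention; for a batch (matrix columns) the mean
#' divergence over sequences is returned. Predicted probabilities are
#' clamped at `1e-12` before the log, so softmax outputs are never an
#' error.
#'
#' @param target,predicted Length-18 probability vectors or 18 x n
#'   matrices (columns are distributions).
#' @return Mean KL divergence (non-negative scalar).
#' @export
kl_loss <- function(target, predicted) {
  t_ <- as.matrix(target); p_ <- as.matrix(predicted)
  if (!identical(dim(t_), dim(p_))) stopf("target/predicted shape mismatch")
  p_ <- pmax(p_, 1e-12)
  terms <- ifelse(t_ > 0, t_ * (log(t_) - log(p_)), 0)
  mean(colSums(terms))
}
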