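# Minimal neural-network primitives for 1-D sequence models: grouped/
# depthwise convolutions (C++ kernels), batch normalization, SiLU,
# squeeze-and-excitation blocks (standard and CP-factorized bilinear), with
# hand-derived backward passes. Activations are (channels, length, batch)
# arrays.

sigmoid <- function(x) 1 / (1 + exp(-x))
silu <- function(x) x * sigmoid(x)
silu_grad <- function(x) { s <- sigmoid(x); s * (1 + x * (1 - s)) }

# Broadcast a (C, B) matrix along the length axis into a (C, L, B) array.
bcast_len <- function(g, L) {
  aperm(array(g, dim = c(nrow(g), ncol(g), L)), c(1, 3, 2))
}

# Sum a (C, L, B) array over the length axis -> (C, B) matrix.
sum_len <- function(x) {
  d <- dim(x)
  colSums(aperm(x, c(2, 1, 3)))
}

# ---- convolution -----------------------------------------------------------

# EfficientNetV2-style fan-out init for conv weights.
nn_conv <- function(c_in, c_out, kernel, groups = 1L, bias = FALSE) {
  if (c_in %% groups || c_out %% groups)
    stopf("channels (%d -> %d) not divisible by groups (%d)", c_in, c_out,
          groups)
  fan_out <- kernel * c_out / groups
  W <- array(rnorm(c_out * (c_in / groups) * kernel, 0, sqrt(2 / fan_out)),
             dim = c(c_out, c_in / groups, kernel))
  list(type = "conv", W = W,
       b = if (bias) numeric(c_out) else NULL,
       kernel = as.integer(kernel), groups = as.integer(groups),
       c_in = as.integer(c_in), c_out = as.integer(c_out))
}

conv_fw <- function(ly, x) {
  d <- dim(x)
  if (ly$kernel == 1L && ly$groups == 1L) {
    xm <- matrix(x, d[1], d[2] * d[3])
    y <- matrix(ly$W[, , 1], ly$c_out, ly$c_in) %*% xm
    if (!is.null(ly$b)) y <- y + ly$b
    dim(y) <- c(ly$c_out, d[2], d[3])
    y
  } else {
    conv1d_fw(x, ly$W, if (is.null(ly$b)) numeric(ly$c_out) else ly$b,
              ly$groups, !is.null(ly$b))
  }
}

conv_bw <- function(ly, x, dy, need_dx = TRUE) {
  d <- dim(x)
  if (ly$kernel == 1L && ly$groups == 1L) {
    xm <- matrix(x, d[1], d[2] * d[3])
    dym <- matrix(dy, ly$c_out, d[2] * d[3])
    dW <- dym %*% t(xm)
    dim(dW) <- c(ly$c_out, ly$c_in, 1L)
    dx <- NULL
    if (need_dx) {
      dx <- t(matrix(ly$W[, , 1], ly$c_out, ly$c_in)) %*% dym
      dim(dx) <- d
    }
    list(dx = dx, dW = dW,
         db = if (is.null(ly$b)) NULL else rowSums(dym))
  } else {
    r <- conv1d_bw(x, ly$W, dy, ly$groups, !is.null(ly$b), need_dx)
    list(dx = if (need_dx) r$dx else NULL, dW = r$dW,
         db = if (is.null(ly$b)) NULL else as.numeric(r$db))
  }
}

# ---- batch normalization ---------------------------------------------------

nn_bn <- function(C, eps = 1e-5, momentum = 0.1) {
  list(type = "bn", gamma = rep(1, C), beta = numeric(C),
       run_mean = numeric(C), run_var = rep(1, C),
       eps = eps, momentum = momentum, C = as.integer(C))
}

# ---- squeeze-and-excitation ------------------------------------------------

# Standard EfficientNetV2 SE: squeeze -> reduce -> SiLU -> expand -> sigmoid.
nn_se_std <- function(C, hidden) {
  list(type = "se_std",
       W1 = matrix(rnorm(hidden * C, 0, 1 / sqrt(C)), hidden, C),
       b1 = numeric(hidden),
       W2 = matrix(rnorm(C * hidden, 0, 1 / sqrt(hidden)), C, hidden),
       b2 = numeric(C), C = as.integer(C), hidden = as.integer(hidden))
}

# Custom SE: the first stage is a bilinear form of the squeezed vector with
# itself whose (hidden x C x C) weight tensor is stored in CP-factorized
# form of rank `rank`: W[h,i,j] = sum_r A[h,r] * Bf[i,r] * Cf[j,r].
nn_se_cp <- function(C, hidden, rank) {
  if (rank <= 0) stopf("cp_rank must be positive")
  sc <- (1 / C) ^ (1 / 3) / rank ^ (1 / 3)
  list(type = "se_cp",
       A = matrix(rnorm(hidden * rank, 0, sc), hidden, rank),
       Bf = matrix(rnorm(C * rank, 0, sc), C, rank),
       Cf = matrix(rnorm(C * rank, 0, sc), C, rank),
       b1 = numeric(hidden),
       W2 = matrix(rnorm(C * hidden, 0, 1 / sqrt(hidden)), C, hidden),
       b2 = numeric(C),
       C = as.integer(C), hidden = as.integer(hidden),
       rank = as.integer(rank))
}

se_fw <- function(ly, x) {
  d <- dim(x); L <- d[2]
  s <- seq_mean_len(x)  # (C, B) squeeze
  if (ly$type == "se_std") {
    u1 <- ly$W1 %*% s + ly$b1
    a1 <- silu(u1)
  } else {
    u <- crossprod(ly$Bf, s)   # (R, B)
    v <- crossprod(ly$Cf, s)
    u1 <- ly$A %*% (u * v) + ly$b1
    a1 <- silu(u1)
  }
  u2 <- ly$W2 %*% a1 + ly$b2
  g <- sigmoid(u2)             # (C, B) gate
  list(y = scale_by_gate(x, g),
       cache = list(x = x, s = s, u1 = u1, a1 = a1, g = g,
                    u = if (ly$type == "se_cp") u else NULL,
                    v = if (ly$type == "se_cp") v else NULL, L = L))
}

se_bw <- function(ly, cache, dy) {
  L <- cache$L
  dg <- gate_grad(dy, cache$x)                 # (C, B)
  du2 <- dg * cache$g * (1 - cache$g)
  dW2 <- du2 %*% t(cache$a1)
  db2 <- rowSums(du2)
  da1 <- crossprod(ly$W2, du2)
  du1 <- da1 * silu_grad(cache$u1)
  db1 <- rowSums(du1)
  if (ly$type == "se_std") {
    dW1 <- du1 %*% t(cache$s)
    ds <- crossprod(ly$W1, du1)
    grads <- list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
  } else {
    uv <- cache$u * cache$v
    dA <- du1 %*% t(uv)
    duv <- crossprod(ly$A, du1)
    du <- duv * cache$v
    dv <- duv * cache$u
    dBf <- cache$s %*% t(du)
    dCf <- cache$s %*% t(dv)
    ds <- ly$Bf %*% du + ly$Cf %*% dv
    grads <- list(A = dA, Bf = dBf, Cf = dCf, b1 = db1, W2 = dW2, b2 = db2)
  }
  dx <- gate_dx(dy, cache$g, ds / L)
  list(dx = dx, grads = grads)
}

se_param_names <- function(ly) {
  if (ly$type == "se_std") c("W1", "b1", "W2", "b2")
  else c("A", "Bf", "Cf", "b1", "W2", "b2")
}
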