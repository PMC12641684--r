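# Minimal reverse-mode autodiff for small 3D convolutional networks.
#
# Tensors are 4D arrays (channels, x, y, z). Convolutions are 3x3x3,
# stride 1, pad 1, computed as an im2col gather followed by one BLAS
# matrix product; downsampling is 2x average pooling and upsampling
# nearest-neighbour, so all spatial dims must be powers-of-two multiples
# of the bottleneck size. A per-forward tape records nodes in creation
# order; backward replays it reversed. This is deliberately desk-scale:
# whole-volume batches of one, a few dozen channels, no GPU.

.nn <- new.env(parent = emptyenv())
.nn$tape <- NULL

nn_node <- function(val, backward = NULL) {
  n <- new.env(parent = emptyenv())
  n$val <- val
  n$grad <- NULL
  n$backward <- backward
  if (!is.null(.nn$tape)) .nn$tape[[length(.nn$tape) + 1L]] <- n
  n
}

nn_add_grad <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

with_tape <- function(expr) {
  old <- .nn$tape
  .nn$tape <- list()
  on.exit(.nn$tape <- old)
  res <- force(expr)
  list(result = res, tape = .nn$tape)
}

nn_backward <- function(loss, tape) {
  loss$grad <- 1
  for (i in rev(seq_along(tape))) {
    n <- tape[[i]]
    if (!is.null(n$grad) && !is.null(n$backward)) n$backward(n$grad)
  }
  invisible(NULL)
}

# ---- parameters -------------------------------------------------------

nn_param <- function(val) {
  p <- new.env(parent = emptyenv())
  p$val <- val
  p$grad <- NULL
  p$m <- NULL
  p$v <- NULL
  p
}

nn_param_accum <- function(p, g) {
  p$grad <- if (is.null(p$grad)) g else p$grad + g
}

nn_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# Adam with polynomial decay of the base rate: lr_t = lr0 * (1 - t/T)^0.9
nn_adam_step <- function(params, lr, step, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8) {
  for (p in params) {
    if (is.null(p$grad)) next
    g <- p$grad
    if (is.null(p$m)) { p$m <- g * 0; p$v <- g * 0 }
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g^2
    mh <- p$m / (1 - beta1^step)
    vh <- p$v / (1 - beta2^step)
    p$val <- p$val - lr * mh / (sqrt(vh) + eps)
  }
  invisible(NULL)
}

poly_lr <- function(lr0, step, total, power = 0.9) {
  lr0 * (1 - min(step / (total + 1), 0.999))^power
}

# He-style init for a 3x3x3 conv stored as (c_out, c_in*27)
conv_init <- function(c_in, c_out, k = 27L) {
  matrix(stats::rnorm(c_out * c_in * k, 0, sqrt(2 / (c_in * k))),
         c_out, c_in * k)
}

# ---- conv and pooling ops ---------------------------------------------

OFFS27 <- as.matrix(expand.grid(dx = 0:2, dy = 0:2, dz = 0:2))

im2col3 <- function(x) {                   # x: (C, X, Y, Z)
  d <- dim(x)
  C <- d[1]; X <- d[2]; Y <- d[3]; Z <- d[4]
  pad <- array(0, c(C, X + 2L, Y + 2L, Z + 2L))
  pad[, 2:(X + 1), 2:(Y + 1), 2:(Z + 1)] <- x
  col <- matrix(0, C * 27L, X * Y * Z)
  for (o in 1:27) {
    dxyz <- OFFS27[o, ]
    col[((o - 1L) * C + 1L):(o * C), ] <-
      pad[, dxyz[1] + (1:X), dxyz[2] + (1:Y), dxyz[3] + (1:Z), drop = FALSE]
  }
  col
}

col2im3 <- function(dcol, d) {
  C <- d[1]; X <- d[2]; Y <- d[3]; Z <- d[4]
  dpad <- array(0, c(C, X + 2L, Y + 2L, Z + 2L))
  for (o in 1:27) {
    dxyz <- OFFS27[o, ]
    sl <- dpad[, dxyz[1] + (1:X), dxyz[2] + (1:Y), dxyz[3] + (1:Z),
               drop = FALSE]
    dpad[, dxyz[1] + (1:X), dxyz[2] + (1:Y), dxyz[3] + (1:Z)] <-
      sl + array(dcol[((o - 1L) * C + 1L):(o * C), ], c(C, X, Y, Z))
  }
  dpad[, 2:(X + 1), 2:(Y + 1), 2:(Z + 1), drop = FALSE]
}

# 3x3x3 conv, stride 1, pad 1. W: (c_out, c_in*27), b: length c_out.
op_conv3 <- function(x, W, b) {
  d <- dim(x$val)
  col <- im2col3(x$val)
  out <- W$val %*% col + b$val
  dout <- c(nrow(W$val), d[2], d[3], d[4])
  nn_node(array(out, dout), backward = function(g) {
    gm <- matrix(g, nrow(W$val))
    nn_param_accum(W, gm %*% t(col))
    nn_param_accum(b, rowSums(gm))
    nn_add_grad(x, col2im3(t(W$val) %*% gm, d))
  })
}

# 1x1x1 conv. W: (c_out, c_in), b: length c_out.
op_conv1 <- function(x, W, b) {
  d <- dim(x$val)
  xm <- matrix(x$val, d[1])
  out <- W$val %*% xm + b$val
  nn_node(array(out, c(nrow(W$val), d[2], d[3], d[4])),
          backward = function(g) {
            gm <- matrix(g, nrow(W$val))
            nn_param_accum(W, gm %*% t(xm))
            nn_param_accum(b, rowSums(gm))
            nn_add_grad(x, array(t(W$val) %*% gm, d))
          })
}

op_avgpool2 <- function(x) {
  d <- dim(x$val)
  stopifnot(all(d[2:4] %% 2L == 0L))
  e1 <- seq(1L, d[2], 2L); e2 <- seq(1L, d[3], 2L); e3 <- seq(1L, d[4], 2L)
  out <- (x$val[, e1, e2, e3, drop = FALSE] +
            x$val[, e1 + 1, e2, e3, drop = FALSE] +
            x$val[, e1, e2 + 1, e3, drop = FALSE] +
            x$val[, e1 + 1, e2 + 1, e3, drop = FALSE] +
            x$val[, e1, e2, e3 + 1, drop = FALSE] +
            x$val[, e1 + 1, e2, e3 + 1, drop = FALSE] +
            x$val[, e1, e2 + 1, e3 + 1, drop = FALSE] +
            x$val[, e1 + 1, e2 + 1, e3 + 1, drop = FALSE]) / 8
  nn_node(out, backward = function(g) {
    gi <- g / 8
    dx <- array(0, d)
    for (a in 0:1) for (b in 0:1) for (cc in 0:1)
      dx[, e1 + a, e2 + b, e3 + cc] <- gi
    nn_add_grad(x, dx)
  })
}

op_upsample2 <- function(x) {
  d <- dim(x$val)
  r1 <- rep(seq_len(d[2]), each = 2); r2 <- rep(seq_len(d[3]), each = 2)
  r3 <- rep(seq_len(d[4]), each = 2)
  nn_node(x$val[, r1, r2, r3, drop = FALSE], backward = function(g) {
    e1 <- seq(1L, 2L * d[2], 2L); e2 <- seq(1L, 2L * d[3], 2L)
    e3 <- seq(1L, 2L * d[4], 2L)
    dx <- g[, e1, e2, e3, drop = FALSE]
    for (a in 0:1) for (b in 0:1) for (cc in 0:1)
      if (a + b + cc > 0)
        dx <- dx + g[, e1 + a, e2 + b, e3 + cc, drop = FALSE]
    nn_add_grad(x, dx)
  })
}

op_concat_c <- function(x, y) {
  dx <- dim(x$val); dy <- dim(y$val)
  out <- array(0, c(dx[1] + dy[1], dx[2], dx[3], dx[4]))
  out[seq_len(dx[1]), , , ] <- x$val
  out[dx[1] + seq_len(dy[1]), , , ] <- y$val
  nn_node(out, backward = function(g) {
    nn_add_grad(x, g[seq_len(dx[1]), , , , drop = FALSE])
    nn_add_grad(y, g[dx[1] + seq_len(dy[1]), , , , drop = FALSE])
  })
}

op_lrelu <- function(x, slope = 0.1) {
  pos <- x$val > 0
  nn_node(ifelse(pos, x$val, slope * x$val), backward = function(g) {
    nn_add_grad(x, ifelse(pos, g, slope * g))
  })
}

# ---- losses (scalar nodes) --------------------------------------------

op_bce_logits <- function(x, target) {
  z <- x$val
  p <- 1 / (1 + exp(-z))
  n <- length(z)
  val <- mean(pmax(z, 0) - z * target + log1p(exp(-abs(z))))
  nn_node(val, backward = function(g) {
    nn_add_grad(x, g * (p - target) / n)
  })
}

op_softdice_logits <- function(x, target, eps = 1e-5) {
  p <- 1 / (1 + exp(-dim_keep(x$val)))
  num <- 2 * sum(p * target) + eps
  den <- sum(p) + sum(target) + eps
  nn_node(1 - num / den, backward = function(g) {
    dp <- -(2 * target * den - num) / den^2
    nn_add_grad(x, g * dp * p * (1 - p))
  })
}

dim_keep <- function(v) v   # readability: logits already shaped

op_l1 <- function(x, target) {
  d <- x$val - target
  n <- length(d)
  nn_node(mean(abs(d)), backward = function(g) {
    nn_add_grad(x, g * sign(d) / n)
  })
}

# KL(q || N(0,I)) per element, averaged
op_kl_gauss <- function(mu, logvar) {
  n <- length(mu$val)
  val <- mean(-0.5 * (1 + logvar$val - mu$val^2 - exp(logvar$val)))
  nn_node(val, backward = function(g) {
    nn_add_grad(mu, g * mu$val / n)
    nn_add_grad(logvar, g * 0.5 * (exp(logvar$val) - 1) / n)
  })
}

# z = mu + eps * exp(logvar/2), eps fixed at forward time
op_reparam <- function(mu, logvar, eps) {
  sd_ <- exp(logvar$val / 2)
  nn_node(mu$val + eps * sd_, backward = function(g) {
    nn_add_grad(mu, g)
    nn_add_grad(logvar, g * eps * sd_ / 2)
  })
}

op_global_mean <- function(x) {
  n <- length(x$val)
  nn_node(mean(x$val), backward = function(g) {
    nn_add_grad(x, array(g / n, dim(x$val)))
  })
}

# weighted sum of scalar nodes
op_wsum <- function(nodes, weights) {
  val <- sum(mapply(function(n, w) w * n$val, nodes, weights))
  nn_node(val, backward = function(g) {
    for (i in seq_along(nodes)) nn_add_grad(nodes[[i]], g * weights[i])
  })
}
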