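# Minimal reverse-mode autodiff on matrices.
#
# A tape records ops in creation order; backward() walks them in reverse.
# Node handles are integer ids into the tape's parallel lists. Parameters
# live outside the tape (environments with $value/$grad) so they persist
# across forward passes; gradients accumulate into them during backward.
# With grad_on = FALSE the tape stores values only (inference mode).

# Node values/backward-closures/gradients live in hashed environments keyed
# by the node id (as a string): R lists held in an env field would be
# duplicated wholesale on every `[[<-`, turning tape appends quadratic.
tape_new <- function(grad_on = TRUE) {
  tp <- new.env(parent = emptyenv())
  tp$vals <- new.env(parent = emptyenv(), size = 4096L)
  tp$backs <- new.env(parent = emptyenv(), size = 4096L)
  tp$grads <- NULL
  tp$n <- 0L
  tp$grad_on <- grad_on
  tp
}

emit <- function(tp, value, back = NULL) {
  i <- tp$n + 1L
  tp$n <- i
  assign(as.character(i), value, envir = tp$vals)
  if (tp$grad_on && !is.null(back))
    assign(as.character(i), back, envir = tp$backs)
  i
}

tp_val <- function(tp, id) get(as.character(id), envir = tp$vals)

accum <- function(tp, id, g) {
  key <- as.character(id)
  cur <- get0(key, envir = tp$grads)
  assign(key, if (is.null(cur)) g else cur + g, envir = tp$grads)
}

backward <- function(tp, id) {
  stopifnot(tp$grad_on)
  tp$grads <- new.env(parent = emptyenv(), size = 4096L)
  v <- tp_val(tp, id)
  assign(as.character(id), array(1, dim = dim(v)), envir = tp$grads)
  for (i in seq(tp$n, 1L)) {
    key <- as.character(i)
    g <- get0(key, envir = tp$grads)
    if (!is.null(g)) {
      bk <- get0(key, envir = tp$backs)
      if (!is.null(bk)) bk(g)
      rm(list = key, envir = tp$grads)  # release
    }
  }
  invisible(NULL)
}

# ---- parameters -----------------------------------------------------------

pr_new <- function(name, nrow, ncol, init = c("xavier", "zeros", "ones"),
                   gain = 1) {
  init <- match.arg(init)
  v <- switch(init,
    xavier = matrix(stats::rnorm(nrow * ncol,
                                 sd = gain * sqrt(2 / (nrow + ncol))),
                    nrow, ncol),
    zeros = matrix(0, nrow, ncol),
    ones = matrix(1, nrow, ncol))
  pr <- new.env(parent = emptyenv())
  pr$name <- name
  pr$value <- v
  pr$grad <- NULL
  pr
}

pr_zero_grads <- function(params) for (pr in params) pr$grad <- NULL

t_param <- function(tp, pr) {
  emit(tp, pr$value, back = function(g) {
    pr$grad <- if (is.null(pr$grad)) g else pr$grad + g
  })
}

t_const <- function(tp, v) emit(tp, v)

# ---- elementary ops -------------------------------------------------------
#
# Every op force()s its node arguments before touching tp$vals: nested op
# calls arrive as unevaluated promises, and `tp_val(tp, a)` would otherwise
# snapshot the list before the promise emits its node.

t_mm <- function(tp, a, b) {
  force(a); force(b)
  A <- tp_val(tp, a); B <- tp_val(tp, b)
  emit(tp, A %*% B, back = function(g) {
    accum(tp, a, g %*% t(B))
    accum(tp, b, crossprod(A, g))
  })
}

# b may be a 1 x ncol(a) row (bias broadcast over rows)
t_add <- function(tp, a, b) {
  force(a); force(b)
  A <- tp_val(tp, a); B <- tp_val(tp, b)
  if (nrow(B) == 1L && nrow(A) > 1L) {
    emit(tp, A + matrix(B, nrow(A), ncol(A), byrow = TRUE), back = function(g) {
      accum(tp, a, g)
      accum(tp, b, matrix(colSums(g), 1L))
    })
  } else {
    emit(tp, A + B, back = function(g) { accum(tp, a, g); accum(tp, b, g) })
  }
}

t_sub <- function(tp, a, b) {
  force(a); force(b)
  emit(tp, tp_val(tp, a) - tp_val(tp, b),
       back = function(g) { accum(tp, a, g); accum(tp, b, -g) })
}

t_add_const <- function(tp, a, C) {
  force(a)
  emit(tp, tp_val(tp, a) + C, back = function(g) accum(tp, a, g))
}

t_mul <- function(tp, a, b) {
  force(a); force(b)
  A <- tp_val(tp, a); B <- tp_val(tp, b)
  emit(tp, A * B, back = function(g) {
    accum(tp, a, g * B)
    accum(tp, b, g * A)
  })
}

t_scale <- function(tp, a, s) {
  force(a)
  emit(tp, tp_val(tp, a) * s, back = function(g) accum(tp, a, g * s))
}

# multiply row i by constant m[i] (mask broadcast across columns)
t_rowscale <- function(tp, a, m) {
  force(a)
  emit(tp, tp_val(tp, a) * m, back = function(g) accum(tp, a, g * m))
}

t_sigmoid <- function(tp, a) {
  force(a)
  y <- 1 / (1 + exp(-tp_val(tp, a)))
  emit(tp, y, back = function(g) accum(tp, a, g * y * (1 - y)))
}

t_tanh <- function(tp, a) {
  force(a)
  y <- tanh(tp_val(tp, a))
  emit(tp, y, back = function(g) accum(tp, a, g * (1 - y * y)))
}

t_relu <- function(tp, a) {
  force(a)
  x <- tp_val(tp, a)
  y <- x * (x > 0)
  emit(tp, y, back = function(g) accum(tp, a, g * (x > 0)))
}

t_softmax_rows <- function(tp, a) {
  force(a)
  x <- tp_val(tp, a)
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  y <- e / rowSums(e)
  emit(tp, y, back = function(g) accum(tp, a, y * (g - rowSums(g * y))))
}

t_transpose <- function(tp, a) {
  force(a)
  emit(tp, t(tp_val(tp, a)), back = function(g) accum(tp, a, t(g)))
}

t_cbind <- function(tp, a, b) {
  force(a); force(b)
  A <- tp_val(tp, a); B <- tp_val(tp, b)
  na <- ncol(A)
  emit(tp, cbind(A, B), back = function(g) {
    accum(tp, a, g[, seq_len(na), drop = FALSE])
    accum(tp, b, g[, -seq_len(na), drop = FALSE])
  })
}

t_slice_cols <- function(tp, a, cols) {
  force(a)
  A <- tp_val(tp, a)
  nc <- ncol(A)
  emit(tp, A[, cols, drop = FALSE], back = function(g) {
    G <- matrix(0, nrow(A), nc)
    G[, cols] <- g
    accum(tp, a, G)
  })
}

t_slice_rows <- function(tp, a, rows) {
  force(a)
  A <- tp_val(tp, a)
  nr <- nrow(A)
  emit(tp, A[rows, , drop = FALSE], back = function(g) {
    G <- matrix(0, nr, ncol(A))
    G[rows, ] <- G[rows, ] + g
    accum(tp, a, G)
  })
}

t_pad_rows <- function(tp, a, before, after) {
  force(a)
  A <- tp_val(tp, a)
  nc <- ncol(A)
  v <- rbind(matrix(0, before, nc), A, matrix(0, after, nc))
  emit(tp, v, back = function(g)
    accum(tp, a, g[seq_len(nrow(A)) + before, , drop = FALSE]))
}

# embedding lookup: rows of a parameter matrix, scatter-add on backward
t_embed <- function(tp, pr, idx) {
  emit(tp, pr$value[idx, , drop = FALSE], back = function(g) {
    agg <- rowsum(g, group = idx)
    rows <- as.integer(rownames(agg))
    if (is.null(pr$grad)) pr$grad <- matrix(0, nrow(pr$value), ncol(pr$value))
    pr$grad[rows, ] <- pr$grad[rows, ] + agg
  })
}

# im2col for 1-D convolution over rows (positions) with C channels (cols):
# output row i concatenates rows (i-1)*stride + 1..k of the input.
t_unfold <- function(tp, a, k, stride) {
  force(a)
  A <- tp_val(tp, a)
  Tn <- nrow(A); C <- ncol(A)
  T_out <- (Tn - k) %/% stride + 1L
  ridx <- as.vector(t(outer(seq(0L, by = stride, length.out = T_out), 1:k, "+")))
  B <- A[ridx, , drop = FALSE]
  v <- matrix(t(B), nrow = T_out, byrow = TRUE)
  emit(tp, v, back = function(g) {
    gB <- matrix(t(g), ncol = C, byrow = TRUE)
    agg <- rowsum(gB, group = ridx)
    G <- matrix(0, Tn, C)
    G[as.integer(rownames(agg)), ] <- agg
    accum(tp, a, G)
  })
}

# nearest-neighbour upsampling over rows
t_rows_repeat <- function(tp, a, k) {
  force(a)
  A <- tp_val(tp, a)
  grp <- rep(seq_len(nrow(A)), each = k)
  emit(tp, A[grp, , drop = FALSE],
       back = function(g) accum(tp, a, rowsum(g, group = grp)))
}

# average-pool rows in blocks of k
t_avgpool_rows <- function(tp, a, k) {
  force(a)
  A <- tp_val(tp, a)
  grp <- rep(seq_len(nrow(A) %/% k), each = k)
  emit(tp, rowsum(A[seq_along(grp), , drop = FALSE], grp) / k,
       back = function(g) {
    G <- g[grp, , drop = FALSE] / k
    if (nrow(G) < nrow(A))
      G <- rbind(G, matrix(0, nrow(A) - nrow(G), ncol(A)))
    accum(tp, a, G)
  })
}

# flatten to a single row (row-major over positions)
t_flatten_row <- function(tp, a) {
  force(a)
  A <- tp_val(tp, a)
  emit(tp, matrix(t(A), nrow = 1L), back = function(g)
    accum(tp, a, matrix(g, nrow(A), ncol(A), byrow = TRUE)))
}

# row-wise max over the first lim[i] columns (lim = NULL: all columns);
# gradient routes to the argmax entry of each row
t_max_rows <- function(tp, a, lim = NULL) {
  force(a)
  A <- tp_val(tp, a)
  n <- nrow(A)
  if (is.null(lim)) {
    wh <- max.col(A, ties.method = "first")
    mx <- A[cbind(seq_len(n), wh)]
  } else {
    wh <- integer(n); mx <- numeric(n)
    for (i in seq_len(n)) {
      r <- A[i, seq_len(lim[i])]
      wh[i] <- which.max(r)
      mx[i] <- r[wh[i]]
    }
  }
  emit(tp, matrix(mx, ncol = 1L), back = function(g) {
    G <- matrix(0, n, ncol(A))
    G[cbind(seq_len(n), wh)] <- g
    accum(tp, a, G)
  })
}

# gather row `row` from each node in `nodes[take]`, stacked as a matrix
t_stack_row <- function(tp, nodes, row, take = seq_along(nodes)) {
  vals <- lapply(take, function(j) tp_val(tp, nodes[[j]])[row, , drop = FALSE])
  v <- do.call(rbind, vals)
  emit(tp, v, back = function(g) {
    for (jj in seq_along(take)) {
      src <- tp_val(tp, nodes[[take[jj]]])
      G <- matrix(0, nrow(src), ncol(src))
      G[row, ] <- g[jj, ]
      accum(tp, nodes[[take[jj]]], G)
    }
  })
}

t_layernorm <- function(tp, a, gamma, beta, eps = 1e-5) {
  force(a); force(gamma); force(beta)
  X <- tp_val(tp, a); gm <- tp_val(tp, gamma); bt <- tp_val(tp, beta)
  mu <- rowMeans(X)
  xc <- X - mu
  va <- rowMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * istd
  v <- sweep(xhat, 2L, as.vector(gm), "*")
  v <- sweep(v, 2L, as.vector(bt), "+")
  emit(tp, v, back = function(g) {
    accum(tp, gamma, matrix(colSums(g * xhat), 1L))
    accum(tp, beta, matrix(colSums(g), 1L))
    dxh <- sweep(g, 2L, as.vector(gm), "*")
    dx <- istd * (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat))
    accum(tp, a, dx)
  })
}

# ---- losses (numerically stable, logit-level) -----------------------------

t_bce_logits <- function(tp, z, y) {
  force(z)
  Z <- tp_val(tp, z)
  l <- mean(pmax(Z, 0) - Z * y + log1p(exp(-abs(Z))))
  emit(tp, matrix(l, 1L, 1L), back = function(g) {
    accum(tp, z, as.numeric(g) * (1 / (1 + exp(-Z)) - y) / length(Z))
  })
}

# mean softmax cross-entropy; cls: integer class per row of z
t_ce_logits <- function(tp, z, cls) {
  force(z)
  Z <- tp_val(tp, z)
  m <- apply(Z, 1L, max)
  lse <- m + log(rowSums(exp(Z - m)))
  l <- mean(lse - Z[cbind(seq_len(nrow(Z)), cls)])
  emit(tp, matrix(l, 1L, 1L), back = function(g) {
    P <- exp(Z - lse)
    P[cbind(seq_len(nrow(Z)), cls)] <- P[cbind(seq_len(nrow(Z)), cls)] - 1
    accum(tp, z, as.numeric(g) * P / nrow(Z))
  })
}

# ---- optimizer ------------------------------------------------------------

adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st$t <- 0L
  for (pr in params) {
    pr$m <- matrix(0, nrow(pr$value), ncol(pr$value))
    pr$v <- matrix(0, nrow(pr$value), ncol(pr$value))
  }
  st
}

adam_step <- function(st) {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  corr1 <- 1 - b1^st$t; corr2 <- 1 - b2^st$t
  for (pr in st$params) {
    g <- pr$grad
    if (is.null(g)) next
    pr$m <- b1 * pr$m + (1 - b1) * g
    pr$v <- b2 * pr$v + (1 - b2) * g * g
    pr$value <- pr$value - st$lr * (pr$m / corr1) /
      (sqrt(pr$v / corr2) + st$eps)
  }
  pr_zero_grads(st$params)
  invisible(NULL)
}

# sinusoidal positional encoding, rows = positions
positional_encoding <- function(n_pos, dim) {
  pe <- matrix(0, n_pos, dim)
  pos <- seq_len(n_pos) - 1L
  for (j in seq_len(dim)) {
    k <- (j - 1L) %/% 2L
    ang <- pos / (10000^(2 * k / dim))
    pe[, j] <- if (j %% 2L == 1L) sin(ang) else cos(ang)
  }
  pe
}
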