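# Minimal reverse-mode automatic differentiation over numeric matrices.
#
# Every value on the tape is a plain R matrix. A graph (`ag_graph`) records
# nodes in execution order; `ag_backward()` walks the tape in reverse and
# accumulates gradients via each node's hand-derived vector-Jacobian product.
# This is deliberately tiny: just enough operator coverage for the three
# classifier architectures (dense / 1-D conv / LSTM / GRU / self-attention),
# and every backward rule is finite-difference checked in the test suite.

ag_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- vector("list", 256L)
  g$n <- 0L
  g
}

ag_node <- function(g, value, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  g$n <- g$n + 1L
  if (g$n > length(g$nodes)) g$nodes <- c(g$nodes, vector("list", length(g$nodes)))
  g$nodes[[g$n]] <- nd
  nd
}

ag_const <- function(g, value) ag_node(g, value)

ag_accum <- function(nd, grad) {
  nd$grad <- if (is.null(nd$grad)) grad else nd$grad + grad
  invisible(NULL)
}

# Backpropagate from a scalar loss node (seed gradient 1).
ag_backward <- function(g, loss) {
  loss$grad <- matrix(1, 1L, 1L)
  for (i in seq.int(g$n, 1L)) {
    nd <- g$nodes[[i]]
    if (!is.null(nd$backfn) && !is.null(nd$grad)) nd$backfn(nd$grad)
  }
  invisible(NULL)
}

## ---- primitive operators ----------------------------------------------

ag_matmul <- function(g, a, b) {
  ag_node(g, a$value %*% b$value, list(a, b), function(dz) {
    ag_accum(a, dz %*% t(b$value))
    ag_accum(b, crossprod(a$value, dz))
  })
}

# a: n x m, b: either n x m or a 1 x m row (bias broadcast over rows)
ag_add <- function(g, a, b) {
  bv <- b$value
  if (nrow(bv) == 1L && nrow(a$value) > 1L) {
    ag_node(g, sweep(a$value, 2L, as.numeric(bv), "+"), list(a, b), function(dz) {
      ag_accum(a, dz)
      ag_accum(b, matrix(colSums(dz), 1L))
    })
  } else {
    ag_node(g, a$value + bv, list(a, b), function(dz) {
      ag_accum(a, dz)
      ag_accum(b, dz)
    })
  }
}

ag_mul <- function(g, a, b) {
  ag_node(g, a$value * b$value, list(a, b), function(dz) {
    ag_accum(a, dz * b$value)
    ag_accum(b, dz * a$value)
  })
}

ag_scale <- function(g, a, s) {
  ag_node(g, a$value * s, list(a), function(dz) ag_accum(a, dz * s))
}

ag_sigmoid <- function(g, a) {
  y <- 1 / (1 + exp(-a$value))
  ag_node(g, y, list(a), function(dz) ag_accum(a, dz * y * (1 - y)))
}

ag_tanh <- function(g, a) {
  y <- tanh(a$value)
  ag_node(g, y, list(a), function(dz) ag_accum(a, dz * (1 - y * y)))
}

ag_relu <- function(g, a) {
  y <- a$value
  mask <- y > 0
  y[!mask] <- 0
  ag_node(g, y, list(a), function(dz) ag_accum(a, dz * mask))
}

ag_oneminus <- function(g, a) {
  ag_node(g, 1 - a$value, list(a), function(dz) ag_accum(a, -dz))
}

ag_colslice <- function(g, a, from, to) {
  ag_node(g, a$value[, from:to, drop = FALSE], list(a), function(dz) {
    da <- matrix(0, nrow(a$value), ncol(a$value))
    da[, from:to] <- dz
    ag_accum(a, da)
  })
}

ag_cbind2 <- function(g, a, b) {
  na <- ncol(a$value)
  ag_node(g, cbind(a$value, b$value), list(a, b), function(dz) {
    ag_accum(a, dz[, seq_len(na), drop = FALSE])
    ag_accum(b, dz[, -seq_len(na), drop = FALSE])
  })
}

# Inverted dropout with a precomputed mask (0 or 1/(1-p)); identity when
# mask is NULL (inference mode).
ag_dropout <- function(g, a, mask) {
  if (is.null(mask)) return(a)
  ag_node(g, a$value * mask, list(a), function(dz) ag_accum(a, dz * mask))
}

# Row-wise layer normalization with learnable gain/shift (1 x d each).
ag_layernorm <- function(g, x, gamma, beta, eps = 1e-5) {
  xv <- x$value
  d <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(xhat, 2L, as.numeric(gamma$value), "*")
  y <- sweep(y, 2L, as.numeric(beta$value), "+")
  ag_node(g, y, list(x, gamma, beta), function(dz) {
    dgamma <- matrix(colSums(dz * xhat), 1L)
    dbeta <- matrix(colSums(dz), 1L)
    dxhat <- sweep(dz, 2L, as.numeric(gamma$value), "*")
    # d/dx of row-standardization
    t1 <- dxhat
    t2 <- rowMeans(dxhat)
    t3 <- xhat * rowMeans(dxhat * xhat)
    dx <- (t1 - t2 - t3) * inv
    ag_accum(x, dx)
    ag_accum(gamma, dgamma)
    ag_accum(beta, dbeta)
  })
}

# Fused softmax + cross-entropy over rows of `logits` (n x K) against
# integer class indices `target` in 1..K. Returns scalar mean loss node;
# row probabilities are attached as attribute "probs" on the value.
ag_softmax_xent <- function(g, logits, target) {
  z <- logits$value
  z <- z - apply(z, 1L, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  n <- nrow(z)
  idx <- cbind(seq_len(n), target)
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  nd <- ag_node(g, matrix(loss, 1L, 1L), list(logits), function(dz) {
    dzs <- as.numeric(dz)
    dl <- p
    dl[idx] <- dl[idx] - 1
    ag_accum(logits, dl * (dzs / n))
  })
  nd$probs <- p
  nd
}

## ---- sequence operators (stacked time-block layout) --------------------
#
# A batch of b sequences of length w with d features is stored as a single
# (b*w) x d matrix whose rows are ordered time-major: rows (t-1)*b + 1 ... t*b
# hold time step t for all b sequences.

ag_timeslice <- function(g, x, b, t) {
  rows <- ((t - 1L) * b + 1L):(t * b)
  ag_node(g, x$value[rows, , drop = FALSE], list(x), function(dz) {
    dx <- matrix(0, nrow(x$value), ncol(x$value))
    dx[rows, ] <- dz
    ag_accum(x, dx)
  })
}

ag_timestack <- function(g, steps, b) {
  vals <- lapply(steps, function(nd) nd$value)
  ag_node(g, do.call(rbind, vals), steps, function(dz) {
    for (t in seq_along(steps)) {
      rows <- ((t - 1L) * b + 1L):(t * b)
      ag_accum(steps[[t]], dz[rows, , drop = FALSE])
    }
  })
}

# Mean over the w time blocks -> b x d.
ag_timemean <- function(g, x, b, w) {
  xv <- x$value
  d <- ncol(xv)
  acc <- matrix(0, b, d)
  for (t in seq_len(w)) acc <- acc + xv[((t - 1L) * b + 1L):(t * b), , drop = FALSE]
  ag_node(g, acc / w, list(x), function(dz) {
    dx <- matrix(0, nrow(xv), d)
    for (t in seq_len(w)) dx[((t - 1L) * b + 1L):(t * b), ] <- dz / w
    ag_accum(x, dx)
  })
}

# Valid (no padding) 1-D convolution over time. x is stacked (b*w) x C,
# wlist a list of k weight nodes (C x F), bias 1 x F. Output stacked
# (b*(w-k+1)) x F.
ag_conv1d <- function(g, x, wlist, bias, b, w) {
  k <- length(wlist)
  wo <- w - k + 1L
  C <- ncol(x$value)
  F <- ncol(wlist[[1L]]$value)
  blocks <- function(v, t) v[((t - 1L) * b + 1L):(t * b), , drop = FALSE]
  out <- matrix(0, b * wo, F)
  for (t in seq_len(wo)) {
    acc <- matrix(0, b, F)
    for (i in seq_len(k)) acc <- acc + blocks(x$value, t + i - 1L) %*% wlist[[i]]$value
    out[((t - 1L) * b + 1L):(t * b), ] <- sweep(acc, 2L, as.numeric(bias$value), "+")
  }
  ag_node(g, out, c(list(x, bias), wlist), function(dz) {
    dx <- matrix(0, nrow(x$value), C)
    dW <- lapply(seq_len(k), function(i) matrix(0, C, F))
    db <- colSums(dz)
    for (t in seq_len(wo)) {
      dzt <- blocks(dz, t)
      for (i in seq_len(k)) {
        rows <- ((t + i - 2L) * b + 1L):((t + i - 1L) * b)
        dx[rows, ] <- dx[rows, ] + dzt %*% t(wlist[[i]]$value)
        dW[[i]] <- dW[[i]] + crossprod(x$value[rows, , drop = FALSE], dzt)
      }
    }
    ag_accum(x, dx)
    ag_accum(bias, matrix(db, 1L))
    for (i in seq_len(k)) ag_accum(wlist[[i]], dW[[i]])
  })
}

# Max pooling over time with pool size `size` (non-overlapping), stacked
# layout. Trailing remainder blocks are dropped.
ag_maxpool_time <- function(g, x, b, w, size = 2L) {
  wo <- w %/% size
  d <- ncol(x$value)
  out <- matrix(-Inf, b * wo, d)
  argt <- matrix(1L, b * wo, d)
  for (t in seq_len(wo)) {
    orows <- ((t - 1L) * b + 1L):(t * b)
    for (s in seq_len(size)) {
      tt <- (t - 1L) * size + s
      blk <- x$value[((tt - 1L) * b + 1L):(tt * b), , drop = FALSE]
      upd <- blk > out[orows, , drop = FALSE]
      out[orows, ][upd] <- blk[upd]
      argt[orows, ][upd] <- tt
    }
  }
  ag_node(g, out, list(x), function(dz) {
    dx <- matrix(0, nrow(x$value), d)
    for (t in seq_len(wo)) {
      orows <- ((t - 1L) * b + 1L):(t * b)
      for (s in seq_len(size)) {
        tt <- (t - 1L) * size + s
        sel <- argt[orows, , drop = FALSE] == tt
        tmp <- matrix(0, b, d)
        tmp[sel] <- dz[orows, , drop = FALSE][sel]
        rows <- ((tt - 1L) * b + 1L):(tt * b)
        dx[rows, ] <- dx[rows, ] + tmp
      }
    }
    ag_accum(x, dx)
  })
}

# Flatten the stacked sequence into one b x (w*d) matrix (time-major column
# blocks), feeding dense heads.
ag_flatten_time <- function(g, x, b, w) {
  d <- ncol(x$value)
  out <- matrix(0, b, w * d)
  for (t in seq_len(w)) {
    out[, ((t - 1L) * d + 1L):(t * d)] <- x$value[((t - 1L) * b + 1L):(t * b), , drop = FALSE]
  }
  ag_node(g, out, list(x), function(dz) {
    dx <- matrix(0, nrow(x$value), d)
    for (t in seq_len(w)) {
      dx[((t - 1L) * b + 1L):(t * b), ] <- dz[, ((t - 1L) * d + 1L):(t * d), drop = FALSE]
    }
    ag_accum(x, dx)
  })
}

# Batched scaled dot-product self-attention on a stacked (b*w) x d_k layout.
# Computes, independently per sequence s: softmax(Q_s K_s^T / sqrt(dk)) V_s.
# Vectorized across the batch by looping over the w^2 time pairs.
ag_attention_seq <- function(g, q, k, v, b, w) {
  dk <- ncol(k$value)
  dv <- ncol(v$value)
  sc <- 1 / sqrt(dk)
  blk <- function(m, t) m[((t - 1L) * b + 1L):(t * b), , drop = FALSE]
  qv <- q$value; kv <- k$value; vv <- v$value
  # scores: array (b, w, w): S[s,i,j] = <q_si, k_sj> * sc
  S <- array(0, c(b, w, w))
  for (i in seq_len(w)) {
    qi <- blk(qv, i)
    for (j in seq_len(w)) S[, i, j] <- rowSums(qi * blk(kv, j)) * sc
  }
  A <- S
  for (i in seq_len(w)) {
    si <- S[, i, , drop = FALSE]
    dim(si) <- c(b, w)
    si <- si - apply(si, 1L, max)
    es <- exp(si)
    A[, i, ] <- es / rowSums(es)
  }
  out <- matrix(0, b * w, dv)
  for (i in seq_len(w)) {
    acc <- matrix(0, b, dv)
    for (j in seq_len(w)) acc <- acc + A[, i, j] * blk(vv, j)
    out[((i - 1L) * b + 1L):(i * b), ] <- acc
  }
  ag_node(g, out, list(q, k, v), function(dz) {
    dq <- matrix(0, nrow(qv), dk)
    dkm <- matrix(0, nrow(kv), dk)
    dv_ <- matrix(0, nrow(vv), dv)
    dA <- array(0, c(b, w, w))
    for (i in seq_len(w)) {
      dzi <- blk(dz, i)
      for (j in seq_len(w)) {
        vj_rows <- ((j - 1L) * b + 1L):(j * b)
        dA[, i, j] <- rowSums(dzi * vv[vj_rows, , drop = FALSE])
        dv_[vj_rows, ] <- dv_[vj_rows, ] + A[, i, j] * dzi
      }
    }
    # softmax backward per (s, i) row
    dS <- dA
    for (i in seq_len(w)) {
      ai <- A[, i, ]; dim(ai) <- c(b, w)
      dai <- dA[, i, ]; dim(dai) <- c(b, w)
      dS[, i, ] <- ai * (dai - rowSums(dai * ai))
    }
    for (i in seq_len(w)) {
      qi_rows <- ((i - 1L) * b + 1L):(i * b)
      for (j in seq_len(w)) {
        kj_rows <- ((j - 1L) * b + 1L):(j * b)
        dq[qi_rows, ] <- dq[qi_rows, ] + dS[, i, j] * kv[kj_rows, , drop = FALSE] * sc
        dkm[kj_rows, ] <- dkm[kj_rows, ] + dS[, i, j] * qv[qi_rows, , drop = FALSE] * sc
      }
    }
    ag_accum(q, dq)
    ag_accum(k, dkm)
    ag_accum(v, dv_)
  })
}
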