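#' @include AllClasses.R
NULL

# ---------------------------------------------------------------------------
# Minimal reverse-mode autodiff.
#
# No deep-learning framework ships with this R stack, so the transformer is
# trained through a small tape-based engine: every operation appends a node
# (value + parents + hand-derived backward closure) to a tape; ad_backward
# walks the tape in reverse and accumulates gradients into parameter stores.
# Heavy primitives (layernorm, scaled dot-product attention, the contrastive
# and cross-entropy losses) are fused single nodes to keep tapes short.
# Correctness is pinned by finite-difference tests.
# ---------------------------------------------------------------------------

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512L)
  tp$n <- 0L
  tp
}

.ad_new <- function(tape, val, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  n <- tape$n + 1L
  if (n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

ad_const <- function(tape, val) .ad_new(tape, val)

# leaf bound to a persistent parameter store (env with $val/$grad)
ad_param <- function(tape, p) {
  nd <- .ad_new(tape, p$val)
  nd$param <- p
  nd
}

ad_backward <- function(tape, loss) {
  loss$grad <- if (is.matrix(loss$val)) array(1, dim(loss$val)) else 1
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad)) next
    if (!is.null(nd$backfn)) {
      gs <- nd$backfn(nd$grad)
      ps <- nd$parents
      for (j in seq_along(ps)) {
        g <- gs[[j]]
        if (is.null(g)) next
        p <- ps[[j]]
        p$grad <- if (is.null(p$grad)) g else p$grad + g
      }
    }
    if (!is.null(nd$param))
      nd$param$grad <- nd$param$grad + nd$grad
  }
  invisible(loss)
}

# --- parameter stores -------------------------------------------------------

nnParam <- function(dims, init = c("trunc_normal", "xavier", "zeros", "ones"),
                    sd = 0.02) {
  init <- match.arg(init)
  n <- prod(dims)
  if (init == "xavier") sd <- sqrt(2 / sum(dims))
  v <- switch(init,
    trunc_normal = pmin(pmax(stats::rnorm(n, 0, sd), -2 * sd), 2 * sd),
    xavier = stats::rnorm(n, 0, sd),
    zeros = numeric(n),
    ones = rep(1, n))
  p <- new.env(parent = emptyenv())
  p$val <- if (length(dims) == 2L) matrix(v, dims[1], dims[2]) else v
  p$grad <- p$val * 0
  p$m <- p$val * 0
  p$v <- p$val * 0
  p$t <- 0L
  p
}

.zero_grads <- function(params) {
  for (nm in ls(params)) params[[nm]]$grad[] <- 0
  invisible(NULL)
}

# --- elementwise / linear algebra ops ---------------------------------------

ad_add <- function(tape, a, b) {
  .ad_new(tape, a$val + b$val, list(a, b), function(g) list(g, g))
}

ad_scale <- function(tape, a, s) {
  .ad_new(tape, a$val * s, list(a), function(g) list(g * s))
}

ad_matmul <- function(tape, a, b) {
  .ad_new(tape, a$val %*% b$val, list(a, b), function(g)
    list(g %*% t(b$val), crossprod(a$val, g)))
}

# add a bias (row) vector to every row
ad_bias <- function(tape, x, b) {
  bv <- as.numeric(b$val)
  .ad_new(tape, sweep(x$val, 2L, bv, "+"), list(x, b), function(g)
    list(g, colSums(g)))
}

ad_linear <- function(tape, x, Wp, bp) {
  ad_bias(tape, ad_matmul(tape, x, ad_param(tape, Wp)), ad_param(tape, bp))
}

ad_gelu <- function(tape, x) {
  xv <- x$val
  Ph <- stats::pnorm(xv)
  .ad_new(tape, xv * Ph, list(x), function(g)
    list(g * (Ph + xv * stats::dnorm(xv))))
}

ad_dropout <- function(tape, x, rate, training) {
  if (!training || rate <= 0) return(x)
  keep <- 1 - rate
  m <- (matrix(stats::runif(length(x$val)), nrow(x$val)) < keep) / keep
  .ad_new(tape, x$val * m, list(x), function(g) list(g * m))
}

# fused row-wise LayerNorm with learned gain/bias
ad_layernorm <- function(tape, x, gp, bp, eps = 1e-5) {
  gnode <- ad_param(tape, gp)
  bnode <- ad_param(tape, bp)
  xv <- x$val
  mu <- rowMeans(xv)
  xc <- xv - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  gamma <- as.numeric(gp$val)
  beta <- as.numeric(bp$val)
  val <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  .ad_new(tape, val, list(x, gnode, bnode), function(g) {
    dgamma <- colSums(g * xhat)
    dbeta <- colSums(g)
    dxhat <- sweep(g, 2L, gamma, "*")
    dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * inv
    list(dx, dgamma, dbeta)
  })
}

# --- shape ops --------------------------------------------------------------

ad_rows <- function(tape, x, idx) {
  nr <- nrow(x$val)
  .ad_new(tape, x$val[idx, , drop = FALSE], list(x), function(g) {
    dx <- matrix(0, nr, ncol(g))
    # idx rows are distinct in every use here
    dx[idx, ] <- g
    list(dx)
  })
}

# insert a learnable token row into each sample block of a (B*n) x d batch
ad_insert_token <- function(tape, x, tokp, B, n, where = c("back", "front")) {
  where <- match.arg(where)
  tnode <- ad_param(tape, tokp)
  m <- n + 1L
  d <- ncol(x$val)
  xpos <- as.vector(vapply(seq_len(B), function(b)
    (b - 1L) * m + (if (where == "back") seq_len(n) else seq_len(n) + 1L),
    integer(n)))
  tpos <- if (where == "back") seq_len(B) * m else (seq_len(B) - 1L) * m + 1L
  val <- matrix(0, B * m, d)
  val[xpos, ] <- x$val
  val[tpos, ] <- matrix(as.numeric(tokp$val), B, d, byrow = TRUE)
  .ad_new(tape, val, list(x, tnode), function(g)
    list(g[xpos, , drop = FALSE],
         matrix(colSums(g[tpos, , drop = FALSE]), 1)))
}

# add a learned position table (n x d) to each sample block of (B*n) x d
ad_positional <- function(tape, x, posp, B, n) {
  pnode <- ad_param(tape, posp)
  rep_idx <- rep(seq_len(n), times = B)
  .ad_new(tape, x$val + posp$val[rep_idx, , drop = FALSE], list(x, pnode),
          function(g) list(g, rowsum(g, rep_idx)))
}

# embedding lookup: rows of a table, with scatter-add backward
ad_embed <- function(tape, tabp, ids) {
  tnode <- ad_param(tape, tabp)
  nr <- nrow(tabp$val)
  .ad_new(tape, tabp$val[ids, , drop = FALSE], list(tnode), function(g) {
    dT <- matrix(0, nr, ncol(g))
    agg <- rowsum(g, ids)
    dT[as.integer(rownames(agg)), ] <- agg
    list(dT)
  })
}

# --- attention --------------------------------------------------------------

.softmax_rows <- function(S) {
  e <- exp(S - apply(S, 1L, max))
  e / rowSums(e)
}

# scaled dot-product attention core for one sample: Q (nq x d), K/V (nk x d),
# h heads over columns; mask is nq x nk logical (TRUE = may attend) or NULL.
# Returns output and the per-head attention weights.
.sdpa_core <- function(Q, K, V, h, mask = NULL, scale = "sqrt") {
  d <- ncol(Q)
  dh <- d %/% h
  coef <- if (scale == "sqrt") 1 / sqrt(dh) else 1 / dh
  out <- matrix(0, nrow(Q), d)
  W <- vector("list", h)
  for (hd in seq_len(h)) {
    cols <- seq.int((hd - 1L) * dh + 1L, hd * dh)
    S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) * coef
    if (!is.null(mask)) S[!mask] <- -1e30
    A <- .softmax_rows(S)
    out[, cols] <- A %*% V[, cols, drop = FALSE]
    W[[hd]] <- A
  }
  list(out = out, weights = W)
}

# fused batched attention node: q is (B*nq) x d, k/v are (B*nk) x d
ad_sdpa <- function(tape, q, k, v, B, h, mask = NULL, scale = "sqrt") {
  nq <- nrow(q$val) %/% B
  nk <- nrow(k$val) %/% B
  d <- ncol(q$val)
  dh <- d %/% h
  coef <- if (scale == "sqrt") 1 / sqrt(dh) else 1 / dh
  val <- matrix(0, B * nq, d)
  cache <- vector("list", B)
  for (b in seq_len(B)) {
    rq <- seq.int((b - 1L) * nq + 1L, b * nq)
    rk <- seq.int((b - 1L) * nk + 1L, b * nk)
    cc <- .sdpa_core(q$val[rq, , drop = FALSE], k$val[rk, , drop = FALSE],
                     v$val[rk, , drop = FALSE], h, mask, scale)
    val[rq, ] <- cc$out
    cache[[b]] <- cc$weights
  }
  .ad_new(tape, val, list(q, k, v), function(g) {
    dq <- matrix(0, B * nq, d)
    dk <- matrix(0, B * nk, d)
    dv <- matrix(0, B * nk, d)
    for (b in seq_len(B)) {
      rq <- seq.int((b - 1L) * nq + 1L, b * nq)
      rk <- seq.int((b - 1L) * nk + 1L, b * nk)
      for (hd in seq_len(h)) {
        cols <- seq.int((hd - 1L) * dh + 1L, hd * dh)
        A <- cache[[b]][[hd]]
        dO <- g[rq, cols, drop = FALSE]
        Vb <- v$val[rk, cols, drop = FALSE]
        dA <- tcrossprod(dO, Vb)
        dS <- A * (dA - rowSums(A * dA))
        dv[rk, cols] <- dv[rk, cols] + crossprod(A, dO)
        dq[rq, cols] <- dq[rq, cols] +
          dS %*% k$val[rk, cols, drop = FALSE] * coef
        dk[rk, cols] <- dk[rk, cols] +
          crossprod(dS, q$val[rq, cols, drop = FALSE]) * coef
      }
    }
    list(dq, dk, dv)
  })
}

# --- normalization and losses ----------------------------------------------

ad_l2rows <- function(tape, x, eps = 1e-12) {
  xv <- x$val
  r <- sqrt(rowSums(xv * xv) + eps)
  z <- xv / r
  .ad_new(tape, z, list(x), function(g)
    list((g - z * rowSums(g * z)) / r))
}

# bidirectional InfoNCE on L2-normalized rows; scalar node with components
# stashed in $extra
ad_contrastive <- function(tape, zi, zt, tau) {
  S <- tcrossprod(zi$val, zt$val) / tau
  N <- nrow(S)
  lse <- function(M) {
    mx <- apply(M, 1L, max)
    mx + log(rowSums(exp(M - mx)))
  }
  di <- diag(S)
  l_i2t <- mean(lse(S) - di)
  l_t2i <- mean(lse(t(S)) - di)
  P1 <- .softmax_rows(S)
  P2 <- .softmax_rows(t(S))
  nd <- .ad_new(tape, l_i2t + l_t2i, list(zi, zt), function(g) {
    E <- diag(N)
    dS <- g * ((P1 - E) + t(P2 - E)) / N
    list(dS %*% zt$val / tau, crossprod(dS, zi$val) / tau)
  })
  nd$extra <- c(i2t = l_i2t, t2i = l_t2i)
  nd
}

# mean softmax cross-entropy; labels are 0-based class indices
ad_softmaxce <- function(tape, logits, labels) {
  P <- .softmax_rows(logits$val)
  N <- nrow(P)
  ii <- cbind(seq_len(N), labels + 1L)
  nd <- .ad_new(tape, -mean(log(pmax(P[ii], 1e-12))), list(logits),
                function(g) {
    Y <- matrix(0, N, ncol(P))
    Y[ii] <- 1
    list(g * (P - Y) / N)
  })
  nd$extra <- P
  nd
}

# a * x + b * y for scalar nodes
ad_wsum2 <- function(tape, x, y, a, b) {
  .ad_new(tape, a * x$val + b * y$val, list(x, y), function(g)
    list(g * a, g * b))
}
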