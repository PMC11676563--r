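# Independent reference implementations used as oracles.  These are written
# straight from the model equations in plain R with explicit loops and a
# row-major (time-in-rows) layout, deliberately sharing no code with the
# package internals they check.

o_sigmoid <- function(x) 1 / (1 + exp(-x))
o_softplus <- function(x) log1p(exp(x))

# single-direction GRU; X: T x in (rows = time); returns T x H
o_gru <- function(W, U, b, X) {
  H <- ncol(U)
  T_ <- nrow(X)
  out <- matrix(0, T_, H)
  h <- rep(0, H)
  for (t in seq_len(T_)) {
    pre <- as.numeric(W %*% X[t, ]) + b
    z <- o_sigmoid(pre[1:H] + as.numeric(U[1:H, ] %*% h))
    r <- o_sigmoid(pre[(H + 1):(2 * H)] + as.numeric(U[(H + 1):(2 * H), ] %*% h))
    cand <- tanh(pre[(2 * H + 1):(3 * H)] +
                   as.numeric(U[(2 * H + 1):(3 * H), ] %*% (r * h)))
    h <- (1 - z) * h + z * cand
    out[t, ] <- h
  }
  out
}

# bidirectional GRU from a params list with Wf/Uf/bf and Wb/Ub/bb
o_bigru <- function(pp, X) {
  fwd <- o_gru(pp$Wf, pp$Uf, pp$bf, X)
  bwd <- o_gru(pp$Wb, pp$Ub, pp$bb, X[rev(seq_len(nrow(X))), , drop = FALSE])
  cbind(fwd, bwd[rev(seq_len(nrow(X))), , drop = FALSE])
}

# attention pooling; Hm: T x I; returns list(a, s)
o_att <- function(W, b, q, Hm) {
  T_ <- nrow(Hm)
  sc <- numeric(T_)
  for (t in seq_len(T_)) {
    u <- tanh(as.numeric(W %*% Hm[t, ]) + b)
    sc[t] <- sum(u * q)
  }
  e <- exp(sc - max(sc))
  a <- e / sum(e)
  s <- rep(0, ncol(Hm))
  for (t in seq_len(T_)) s <- s + a[t] * Hm[t, ]
  list(a = a, s = s)
}

# full straight-line forward pass over a bundle, mirroring the documented
# architecture; params is the model$params list
o_forward <- function(params, bundle) {
  M <- bundle$n_periods
  H <- ncol(params$g1f_U) / 3 * 3  # placeholder, recomputed below
  H <- ncol(params$g1f_U)
  g1 <- list(Wf = params$g1f_W, Uf = params$g1f_U, bf = params$g1f_b,
             Wb = params$g1b_W, Ub = params$g1b_U, bb = params$g1b_b)
  g2 <- list(Wf = params$g2f_W, Uf = params$g2f_U, bf = params$g2f_b,
             Wb = params$g2b_W, Ub = params$g2b_U, bb = params$g2b_b)
  g3 <- list(Wf = params$g3f_W, Uf = params$g3f_U, bf = params$g3f_b,
             Wb = params$g3b_W, Ub = params$g3b_U, bb = params$g3b_b)

  X3 <- NULL
  for (p in seq_len(M)) {
    ctx <- matrix(0, 6, 2 * H)
    for (cc in seq_len(6)) {
      tok <- bundle$tokens[[p]][[cc]]
      if (length(tok) == 0) {
        ctx[cc, ] <- params$empty_ctx[, cc]
      } else {
        X <- params$E[tok + 1, , drop = FALSE]       # T x d
        S <- o_bigru(g1, X)
        ctx[cc, ] <- o_att(params$a1_W, params$a1_b, params$a1_q, S)$s
      }
    }
    S2 <- o_bigru(g2, ctx)
    s2 <- o_att(params$a2_W, params$a2_b, params$a2_q, S2)$s
    X3 <- rbind(X3, c(s2, bundle$period_numeric[p, ], bundle$period_mask[p, ]))
  }
  S3 <- o_bigru(g3, X3)
  s3 <- o_att(params$a3_W, params$a3_b, params$a3_q, S3)$s
  patrep <- c(s3, bundle$onsite, bundle$onsite_mask)
  h1 <- pmax(as.numeric(params$ffW1 %*% patrep) + params$ffb1, 0)
  out <- as.numeric(params$ffW2 %*% h1) + params$ffb2
  o_softplus(out)
}

# brute-force pairwise AUROC
o_auroc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# exhaustive confusion-table scan for max sensitivity at a specificity floor
o_sens_at_spec <- function(scores, labels, floor = 0.75) {
  labels <- as.logical(labels)
  u <- sort(unique(scores))
  thr <- c(u[1] - 1, if (length(u) > 1) (head(u, -1) + tail(u, -1)) / 2,
           u[length(u)] + 1)
  best <- c(sensitivity = 0, specificity = 1, threshold = Inf)
  found <- FALSE
  for (t in thr) {
    tp <- sum(scores > t & labels); fn <- sum(scores <= t & labels)
    tn <- sum(scores <= t & !labels); fp <- sum(scores > t & !labels)
    sens <- tp / (tp + fn); spec <- tn / (tn + fp)
    if (spec > floor && (!found || sens > best["sensitivity"])) {
      best <- c(sensitivity = sens, specificity = spec, threshold = t)
      found <- TRUE
    }
  }
  best
}

# linear-interpolation percentile (Hyndman-Fan type 7), coded independently
o_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
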