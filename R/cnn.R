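# Native text CNN: embedding layer (initialized from pre-trained word
# vectors, optionally frozen), one 1-D convolution layer (width-3 windows,
# 128 filters by default) with rectified-linear activation, global max
# pooling, and a fully-connected softmax output trained with categorical
# cross-entropy and RMSprop. Index 1 is the padding row (zero vector, never
# updated); out-of-vocabulary tokens map to padding.

cnn_sequences <- function(x, spec) {
  if (is.data.frame(x)) x <- tokenize(as_corpus(x)$text)
  if (!is.list(x)) stop("cnn input must be a corpus or a list of token vectors",
                        call. = FALSE)
  vocab <- rownames(spec$table)
  lapply(x, function(tokens) {
    idx <- match(tolower(tokens), vocab)
    idx[is.na(idx)] <- 0L
    idx <- idx + 1L                    # 1 = padding / OOV
    len <- spec$max_len
    if (length(idx) >= len) idx[seq_len(len)]
    else c(idx, rep(1L, len - length(idx)))
  })
}

cnn_init <- function(spec, n_classes) {
  k <- embedding_dim(spec$table)
  E <- rbind(numeric(k), unclass(spec$table))   # row 1 = padding
  f <- spec$filters; win <- spec$window
  W <- matrix(stats::rnorm(f * win * k, sd = sqrt(2 / (win * k))), f, win * k)
  b <- numeric(f)
  W2 <- matrix(stats::rnorm(f * n_classes, sd = sqrt(2 / f)), f, n_classes)
  b2 <- numeric(n_classes)
  list(E = E, W = W, b = b, W2 = W2, b2 = b2, k = k, window = win,
       filters = f, max_len = spec$max_len, n_classes = n_classes,
       freeze = spec$freeze_embeddings)
}

cnn_windows <- function(par, seq_idx) {
  # (max_len - window + 1) x (window * k) matrix of concatenated embeddings
  len <- length(seq_idx); win <- par$window; k <- par$k
  nw <- len - win + 1L
  emb <- par$E[seq_idx, , drop = FALSE]
  cols <- matrix(0, nw, win * k)
  for (j in seq_len(win))
    cols[, ((j - 1) * k + 1):(j * k)] <- emb[j:(j + nw - 1), , drop = FALSE]
  cols
}

cnn_forward <- function(par, seq_idx) {
  C <- cnn_windows(par, seq_idx)
  Z <- C %*% t(par$W)
  Z <- sweep(Z, 2, par$b, "+")
  A <- pmax(Z, 0)
  tmax <- max.col(t(A), ties.method = "first")   # argmax position per filter
  pooled <- A[cbind(tmax, seq_len(par$filters))]
  logits <- as.numeric(crossprod(par$W2, pooled)) + par$b2
  logits <- logits - max(logits)
  p <- exp(logits); p <- p / sum(p)
  list(C = C, Z = Z, tmax = tmax, pooled = pooled, p = p)
}

cnn_loss_grad <- function(par, seq_idx, y_idx) {
  fw <- cnn_forward(par, seq_idx)
  loss <- -log(max(fw$p[y_idx], 1e-12))
  dlogit <- fw$p
  dlogit[y_idx] <- dlogit[y_idx] - 1
  gW2 <- outer(fw$pooled, dlogit)
  gb2 <- dlogit
  dpool <- as.numeric(par$W2 %*% dlogit)
  active <- fw$pooled > 0
  gW <- matrix(0, par$filters, ncol(par$W))
  gb <- numeric(par$filters)
  gE <- NULL
  if (!par$freeze) gE <- list()
  win <- par$window; k <- par$k
  for (f in which(active & dpool != 0)) {
    t0 <- fw$tmax[f]
    gW[f, ] <- dpool[f] * fw$C[t0, ]
    gb[f] <- dpool[f]
    if (!par$freeze) {
      dC <- dpool[f] * par$W[f, ]
      for (j in seq_len(win)) {
        row <- seq_idx[t0 + j - 1L]
        if (row == 1L) next                       # padding row stays zero
        g <- dC[((j - 1) * k + 1):(j * k)]
        key <- as.character(row)
        gE[[key]] <- if (is.null(gE[[key]])) g else gE[[key]] + g
      }
    }
  }
  list(loss = loss, gW = gW, gb = gb, gW2 = gW2, gb2 = gb2, gE = gE)
}

cnn_train <- function(seqs, y, spec) {
  par <- cnn_init(spec, nlevels(y))
  yi <- as.integer(y)
  n <- length(seqs)
  lr <- spec$learning_rate; dc <- spec$decay; epsv <- 1e-8
  cache <- list(W = par$W * 0, b = par$b * 0, W2 = par$W2 * 0, b2 = par$b2 * 0,
                E = par$E * 0)
  for (ep in seq_len(spec$epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = spec$batch_size)) {
      idx <- ord[start:min(start + spec$batch_size - 1, n)]
      m <- length(idx)
      gW <- par$W * 0; gb <- par$b * 0; gW2 <- par$W2 * 0; gb2 <- par$b2 * 0
      gErows <- list()
      for (i in idx) {
        g <- cnn_loss_grad(par, seqs[[i]], yi[i])
        gW <- gW + g$gW; gb <- gb + g$gb; gW2 <- gW2 + g$gW2; gb2 <- gb2 + g$gb2
        if (!par$freeze) for (key in names(g$gE))
          gErows[[key]] <- if (is.null(gErows[[key]])) g$gE[[key]]
                           else gErows[[key]] + g$gE[[key]]
      }
      gW <- gW / m; gb <- gb / m; gW2 <- gW2 / m; gb2 <- gb2 / m
      cache$W <- dc * cache$W + (1 - dc) * gW^2
      par$W <- par$W - lr * gW / (sqrt(cache$W) + epsv)
      cache$b <- dc * cache$b + (1 - dc) * gb^2
      par$b <- par$b - lr * gb / (sqrt(cache$b) + epsv)
      cache$W2 <- dc * cache$W2 + (1 - dc) * gW2^2
      par$W2 <- par$W2 - lr * gW2 / (sqrt(cache$W2) + epsv)
      cache$b2 <- dc * cache$b2 + (1 - dc) * gb2^2
      par$b2 <- par$b2 - lr * gb2 / (sqrt(cache$b2) + epsv)
      if (!par$freeze) for (key in names(gErows)) {
        r <- as.integer(key)
        g <- gErows[[key]] / m
        cache$E[r, ] <- dc * cache$E[r, ] + (1 - dc) * g^2
        par$E[r, ] <- par$E[r, ] - lr * g / (sqrt(cache$E[r, ]) + epsv)
      }
    }
  }
  par
}

cnn_predict <- function(par, seqs) {
  vapply(seqs, function(s) which.max(cnn_forward(par, s)$p), integer(1))
}
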