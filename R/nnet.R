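# Minimal single-hidden-layer perceptron with full-batch Adam, used for both
# the instance-classifier head (dense 256 -> dropout -> dense 2 softmax) and
# the patient-level aggregator (hidden 18 -> logistic output). Pure matrix
# algebra; deterministic under with_seed().

relu <- function(x) pmax(x, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

mlp_init <- function(d_in, hidden, d_out) {
  list(W1 = matrix(stats::rnorm(d_in * hidden, 0, sqrt(2 / d_in)), d_in, hidden),
       b1 = numeric(hidden),
       W2 = matrix(stats::rnorm(hidden * d_out, 0, sqrt(2 / hidden)), hidden, d_out),
       b2 = numeric(d_out))
}

mlp_forward <- function(par, X, output) {
  H <- relu(sweep(X %*% par$W1, 2, par$b1, "+"))
  O <- sweep(H %*% par$W2, 2, par$b2, "+")
  P <- if (output == "softmax") softmax_rows(O) else sigmoid(O)
  list(H = H, P = P)
}

mlp_loss <- function(P, Y) {
  eps <- 1e-12
  if (ncol(Y) > 1L) -mean(rowSums(Y * log(P + eps)))
  else -mean(Y * log(P + eps) + (1 - Y) * log(1 - P + eps))
}

# X: n x d features; Y: n x K one-hot (softmax) or n x 1 in {0,1} (sigmoid).
# Validation data, when given, select the best epoch's parameters (the
# returned network is the one minimizing validation loss).
mlp_train <- function(X, Y, hidden, output = c("softmax", "sigmoid"),
                      dropout = 0, epochs = 200, lr = 1e-2, l2 = 1e-4,
                      seed = 1, X_val = NULL, Y_val = NULL) {
  output <- match.arg(output)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  d_out <- ncol(Y)
  with_seed(seed, {
    par <- mlp_init(ncol(X), hidden, d_out)
    m <- lapply(par, function(p) p * 0)
    v <- lapply(par, function(p) p * 0)
    b1a <- 0.9; b2a <- 0.999; epsa <- 1e-8
    best <- NULL; best_loss <- Inf; best_epoch <- NA_integer_
    history <- numeric(epochs)
    for (t in seq_len(epochs)) {
      H <- relu(sweep(X %*% par$W1, 2, par$b1, "+"))
      Hd <- H
      mask <- NULL
      if (dropout > 0) {
        mask <- matrix(stats::runif(length(H)) >= dropout, nrow(H), ncol(H))
        Hd <- H * mask / (1 - dropout)   # inverted dropout
      }
      O <- sweep(Hd %*% par$W2, 2, par$b2, "+")
      P <- if (output == "softmax") softmax_rows(O) else sigmoid(O)
      dO <- (P - Y) / n
      g <- list(W1 = NULL, b1 = NULL,
                W2 = crossprod(Hd, dO) + l2 * par$W2,
                b2 = colSums(dO))
      dH <- dO %*% t(par$W2)
      if (!is.null(mask)) dH <- dH * mask / (1 - dropout)
      dH[H <= 0] <- 0
      g$W1 <- crossprod(X, dH) + l2 * par$W1
      g$b1 <- colSums(dH)
      for (k in names(par)) {
        m[[k]] <- b1a * m[[k]] + (1 - b1a) * g[[k]]
        v[[k]] <- b2a * v[[k]] + (1 - b2a) * g[[k]]^2
        mh <- m[[k]] / (1 - b1a^t)
        vh <- v[[k]] / (1 - b2a^t)
        par[[k]] <- par[[k]] - lr * mh / (sqrt(vh) + epsa)
      }
      if (!is.null(X_val)) {
        pv <- mlp_forward(par, as.matrix(X_val), output)$P
        lv <- mlp_loss(pv, as.matrix(Y_val))
        history[t] <- lv
        if (lv < best_loss) { best_loss <- lv; best <- par; best_epoch <- t }
      } else {
        history[t] <- mlp_loss(mlp_forward(par, X, output)$P, Y)
      }
    }
    if (!is.null(best)) par <- best
    structure(list(par = par, output = output, hidden = hidden,
                   d_in = ncol(X), d_out = d_out, epochs = epochs,
                   best_epoch = best_epoch, history = history, seed = seed),
              class = "milct_mlp")
  })
}

mlp_predict <- function(net, X) {
  stopifnot(inherits(net, "milct_mlp"))
  X <- as.matrix(X)
  if (ncol(X) != net$d_in) {
    stop(sprintf("feature length %d does not match the trained network (%d)",
                 ncol(X), net$d_in), call. = FALSE)
  }
  mlp_forward(net$par, X, net$output)$P
}
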