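# Linear-chain conditional random field over abstract-level sentence
# sequences. Emission weights W (features x states), transition weights
# Trans (state x state) and start weights give
#   score(y | x) = start[y1] + sum_t emit_t[y_t] + sum_{t>1} Trans[y_{t-1}, y_t]
# The negative log-likelihood with an L2 penalty is minimized with
# stats::optim (L-BFGS-B); forward-backward supplies exact gradients and
# Viterbi the MAP label sequence.

.logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

# built: output of .build_instances (gives sequence boundaries and labels);
# X: instance matrix over all sentences in corpus order
.fit_crf <- function(X, built, classes, control) {
  K <- length(classes)
  P <- ncol(X)
  maxit <- if (is.null(control$maxit)) 100 else control$maxit
  lambda <- if (is.null(control$lambda)) 0.01 else control$lambda
  # sequences of row indices + label indices; drop sentences without gold
  offs <- 0L
  seqs <- list()
  for (b in built) {
    n <- length(b$ids)
    rows <- offs + seq_len(n)
    offs <- offs + n
    ok <- !is.na(b$gold)
    if (!any(ok)) next
    seqs[[length(seqs) + 1]] <- list(rows = rows[ok],
                                     y = match(b$gold[ok], classes))
  }
  npar <- P * K + K * K + K
  unpack <- function(theta) {
    list(W = matrix(theta[seq_len(P * K)], P, K),
         Trans = matrix(theta[P * K + seq_len(K * K)], K, K),
         Start = theta[P * K + K * K + seq_len(K)])
  }
  fg <- function(theta) {
    pars <- unpack(theta)
    Emis <- X %*% pars$W                        # all emissions at once
    nll <- 0
    gW <- matrix(0, P, K); gT <- matrix(0, K, K); gS <- numeric(K)
    for (sq in seqs) {
      E <- Emis[sq$rows, , drop = FALSE]
      Tt <- nrow(E)
      y <- sq$y
      # forward
      la <- matrix(-Inf, Tt, K)
      la[1, ] <- pars$Start + E[1, ]
      if (Tt > 1) for (t in 2:Tt)
        la[t, ] <- E[t, ] + vapply(seq_len(K), function(k)
          .logsumexp(la[t - 1, ] + pars$Trans[, k]), 0)
      logZ <- .logsumexp(la[Tt, ])
      # backward
      lb <- matrix(0, Tt, K)
      if (Tt > 1) for (t in (Tt - 1):1)
        lb[t, ] <- vapply(seq_len(K), function(j)
          .logsumexp(pars$Trans[j, ] + E[t + 1, ] + lb[t + 1, ]), 0)
      gamma <- exp(la + lb - logZ)              # Tt x K marginals
      # observed score
      obs <- pars$Start[y[1]] + sum(E[cbind(seq_len(Tt), y)])
      if (Tt > 1) obs <- obs + sum(pars$Trans[cbind(y[-Tt], y[-1])])
      nll <- nll + (logZ - obs)
      # gradients: expected minus empirical
      D <- gamma
      D[cbind(seq_len(Tt), y)] <- D[cbind(seq_len(Tt), y)] - 1
      gW <- gW + crossprod(X[sq$rows, , drop = FALSE], D)
      gS <- gS + gamma[1, ]
      gS[y[1]] <- gS[y[1]] - 1
      if (Tt > 1) for (t in 2:Tt) {
        xi <- exp(outer(la[t - 1, ], E[t, ] + lb[t, ], "+") + pars$Trans -
                    logZ)
        gT <- gT + xi
        gT[y[t - 1], y[t]] <- gT[y[t - 1], y[t]] - 1
      }
    }
    list(value = nll + lambda / 2 * sum(theta^2),
         grad = c(gW, gT, gS) + lambda * theta)
  }
  env <- new.env()
  fn <- function(theta) {
    r <- fg(theta); env$grad <- r$grad; r$value
  }
  gr <- function(theta) env$grad
  opt <- stats::optim(numeric(npar), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit))
  pars <- unpack(opt$par)
  list(W = structure(pars$W, dimnames = list(colnames(X), classes)),
       Trans = structure(pars$Trans, dimnames = list(classes, classes)),
       Start = stats::setNames(pars$Start, classes),
       classes = classes, convergence = opt$convergence,
       nll = opt$value)
}

.crf_viterbi <- function(fit, X) {
  classes <- fit$classes
  K <- length(classes)
  E <- X %*% fit$W
  Tt <- nrow(E)
  if (Tt == 0) return(character())
  delta <- matrix(-Inf, Tt, K)
  back <- matrix(0L, Tt, K)
  delta[1, ] <- fit$Start + E[1, ]
  if (Tt > 1) for (t in 2:Tt) for (k in seq_len(K)) {
    v <- delta[t - 1, ] + fit$Trans[, k]
    back[t, k] <- which.max(v)
    delta[t, k] <- v[back[t, k]] + E[t, k]
  }
  path <- integer(Tt)
  path[Tt] <- which.max(delta[Tt, ])
  if (Tt > 1) for (t in (Tt - 1):1) path[t] <- back[t + 1, path[t + 1]]
  classes[path]
}
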