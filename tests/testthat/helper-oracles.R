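# Independent brute-force oracles. These deliberately take different
# computational routes than the package (explicit normal equations, eigen
# instead of svd, KKT state enumeration instead of libsvm, plain loops
# instead of vectorized code) so agreement is evidence, not tautology.

# Least squares via explicit Gram-matrix inversion.
oracle_normal_eq <- function(X, s) {
  as.vector(solve(t(X) %*% X) %*% t(X) %*% s)
}

# Best rank-k approximation (plus row mean) via eigendecomposition of the
# channel covariance — the package reconstructs through the SVD instead.
oracle_rank_k <- function(X, k) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  eg <- eigen(crossprod(Xc), symmetric = TRUE)
  k <- min(k, sum(eg$values > max(eg$values) * 1e-12))
  V <- eg$vectors[, seq_len(k), drop = FALSE]
  sweep(Xc %*% V %*% t(V), 2, mu, `+`)
}

# Direct per-class evaluation of the three discriminant rules, loops only.
oracle_discriminant <- function(Xtr, ytr, Xq, variant, ridge_eps = 1e-6) {
  labels <- sort(unique(as.character(ytr)))
  K <- length(labels)
  p <- ncol(Xtr)
  means <- lapply(labels, function(l) colMeans(Xtr[ytr == l, , drop = FALSE]))
  ridge <- function(S) S + ridge_eps * mean(diag(S)) * diag(p)
  if (variant == "linear") {
    S <- matrix(0, p, p)
    for (l in labels) {
      Xl <- Xtr[ytr == l, , drop = FALSE]
      S <- S + cov(Xl) * (nrow(Xl) - 1)
    }
    S <- ridge(S / (nrow(Xtr) - K))
    covs <- rep(list(S), K)
  } else {
    covs <- lapply(labels, function(l) ridge(cov(Xtr[ytr == l, , drop = FALSE])))
  }
  prior <- 1 / K
  apply(Xq, 1, function(x) {
    sc <- vapply(seq_len(K), function(k) {
      Si <- solve(covs[[k]])
      d2 <- as.numeric(t(x - means[[k]]) %*% Si %*% (x - means[[k]]))
      switch(variant,
        linear = as.numeric(t(x) %*% Si %*% means[[k]]) -
          0.5 * as.numeric(t(means[[k]]) %*% Si %*% means[[k]]) + log(prior),
        quadratic = -0.5 * determinant(covs[[k]])$modulus[1] - 0.5 * d2 + log(prior),
        mahalanobis = -d2
      )
    }, numeric(1))
    m <- max(sc)
    sort(labels[sc >= m - 1e-9 * (1 + abs(m))])[1]
  })
}

# Exact C-SVC dual solution by enumerating every KKT state (each point
# zero / free / at the C bound), solving the equality system for the free
# multipliers and the bias, and keeping the feasible state with the
# largest dual objective. Exponential in n: use for n <= 8.
oracle_svc_dual <- function(X, y, C, tol = 1e-7) {
  n <- nrow(X)
  stopifnot(all(y %in% c(-1, 1)), n <= 8)
  Kmat <- X %*% t(X)
  best <- NULL
  states <- as.matrix(expand.grid(rep(list(0:2), n)))
  for (si in seq_len(nrow(states))) {
    st <- states[si, ]
    Fset <- which(st == 1)
    Uset <- which(st == 2)
    alpha <- numeric(n)
    alpha[Uset] <- C
    nf <- length(Fset)
    if (nf > 0) {
      A <- matrix(0, nf + 1, nf + 1)
      rhs <- numeric(nf + 1)
      for (r in seq_len(nf)) {
        i <- Fset[r]
        A[r, seq_len(nf)] <- y[Fset] * Kmat[i, Fset]
        A[r, nf + 1] <- 1
        rhs[r] <- y[i] - C * sum(y[Uset] * Kmat[i, Uset])
      }
      A[nf + 1, seq_len(nf)] <- y[Fset]
      rhs[nf + 1] <- -C * sum(y[Uset])
      sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      af <- sol[seq_len(nf)]
      b <- sol[nf + 1]
      if (any(af < -tol) || any(af > C + tol)) next
      alpha[Fset] <- pmin(pmax(af, 0), C)
    } else {
      if (abs(sum(alpha * y)) > tol) next
      b <- NA_real_
    }
    g <- as.vector(Kmat %*% (alpha * y)) # f(x_i) - b
    if (nf == 0) {
      # pick b from the feasible interval implied by the inequalities
      lo <- -Inf; hi <- Inf
      for (i in seq_len(n)) {
        # y_i (g_i + b) >= 1 for zero points, <= 1 for bound points
        lim <- (1 - y[i] * g[i]) / y[i]
        if (st[i] == 0) { if (y[i] > 0) lo <- max(lo, lim) else hi <- min(hi, lim) }
        if (st[i] == 2) { if (y[i] > 0) hi <- min(hi, lim) else lo <- max(lo, lim) }
      }
      if (lo > hi + tol) next
      b <- mean(c(max(lo, -1e6), min(hi, 1e6)))
    }
    fmarg <- y * (g + b)
    ok <- all(fmarg[st == 0] >= 1 - 1e-6) && all(fmarg[st == 2] <= 1 + 1e-6)
    if (!ok) next
    obj <- sum(alpha) - 0.5 * sum((alpha * y) * as.vector(Kmat %*% (alpha * y)))
    if (is.null(best) || obj > best$objective + 1e-12) {
      best <- list(alpha = alpha, b = b, objective = obj)
    }
  }
  best
}

# One-vs-one prediction by explicit enumeration: every pairwise machine is
# solved with the KKT oracle and votes are tallied in a plain loop.
oracle_ovo_predict <- function(Xtr, ytr, Xq, C) {
  labels <- sort(unique(as.character(ytr)))
  prs <- combn(labels, 2, simplify = FALSE)
  machines <- lapply(prs, function(pr) {
    idx <- which(ytr %in% pr)
    yy <- ifelse(ytr[idx] == pr[1], 1, -1)
    sol <- oracle_svc_dual(Xtr[idx, , drop = FALSE], yy, C)
    w <- as.vector(t(Xtr[idx, , drop = FALSE]) %*% (sol$alpha * yy))
    list(pr = pr, w = w, b = sol$b)
  })
  apply(Xq, 1, function(x) {
    votes <- setNames(integer(length(labels)), labels)
    supp <- setNames(numeric(length(labels)), labels)
    for (m in machines) {
      f <- sum(m$w * x) + m$b
      winner <- if (f >= 0) m$pr[1] else m$pr[2]
      votes[winner] <- votes[winner] + 1L
      supp[m$pr[1]] <- supp[m$pr[1]] + f
      supp[m$pr[2]] <- supp[m$pr[2]] - f
    }
    tied <- names(votes)[votes == max(votes)]
    if (length(tied) > 1) tied <- tied[supp[tied] == max(supp[tied])]
    sort(tied)[1]
  })
}

# Group-by-count fractions via plain loops.
oracle_fractions <- function(patient_id, truth, pred) {
  ids <- unique(patient_id)
  data.frame(
    patient_id = ids,
    fraction = vapply(ids, function(id) {
      sel <- patient_id == id
      sum(pred[sel] == truth[sel]) / sum(sel)
    }, numeric(1))
  )
}

# FWHM of a single-peak spectrum by linear interpolation of the half-max
# crossings on the (descending) wavenumber axis.
measure_fwhm <- function(wn, a) {
  half <- max(a) / 2
  above <- which(a >= half)
  i1 <- min(above); i2 <- max(above)
  interp <- function(ilo, ihi) {
    if (ilo < 1) return(wn[ihi])
    if (ihi > length(a)) return(wn[ilo])
    wn[ilo] + (half - a[ilo]) * (wn[ihi] - wn[ilo]) / (a[ihi] - a[ilo])
  }
  hi_edge <- interp(i1 - 1, i1)
  lo_edge <- interp(i2 + 1, i2)
  abs(hi_edge - lo_edge)
}
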