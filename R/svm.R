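#' Fit a linear soft-margin SVM (C-SVC or nu-SVC)
#'
#' Trains a one-vs-one multi-class margin classifier on the training rows
#' of a split spectra table. For each unordered pair of classes one binary
#' linear machine is fitted by solving the corresponding dual problem
#' (C-SVC: `0 <= alpha_i <= C`; nu-SVC: the nu-parameterized equivalent)
#' with libsvm (via e1071) at KKT tolerance 1e-7 — deterministic for fixed
#' input. Each binary machine's separating hyperplane is extracted
#' explicitly as a weight vector and bias, oriented so that positive
#' decision values favour the pair's first class in (SQ, LUAD, SCLC) order.
#'
#' @param table A spectra table with roles assigned ([split_alternating()]).
#' @param formulation `"c_svc"` or `"nu_svc"`.
#' @param cost Penalty C for C-SVC (default 1).
#' @param nu nu parameter in (0, 1) for nu-SVC (default 0.5); must satisfy
#'   `nu <= 2 * min(n_a, n_b) / (n_a + n_b)` for every class pair.
#' @param scale_features If `TRUE`, standardize each channel on the training
#'   rows and apply the same scaling at prediction (off by default; recorded
#'   in the model).
#' @return An object of class `mir_svm`: formulation, hyperparameters,
#'   labels, channel set, and one machine per class pair with weight vector,
#'   bias, support-vector row indices and signed dual coefficients.
#' @export
fit_margin <- function(table, formulation = c("c_svc", "nu_svc"),
                       cost = 1, nu = 0.5, scale_features = FALSE) {
  formulation <- rlang::arg_match(formulation)
  if (formulation == "c_svc" && cost <= 0) rlang::abort("`cost` must be > 0.")
  if (formulation == "nu_svc" && (nu <= 0 || nu >= 1)) {
    rlang::abort("`nu` must lie in (0, 1).")
  }
  train <- dplyr::filter(table, .data$role == "train")
  X <- spc_matrix(train)
  labels <- levels(droplevels(table$subtype))
  y <- factor(as.character(train$subtype), levels = labels)
  absent <- setdiff(labels, unique(as.character(y)))
  if (length(absent) > 0) {
    rlang::abort(paste0("Class(es) absent from training data: ",
                        paste(absent, collapse = ", ")))
  }
  if (length(labels) < 2) rlang::abort("Need at least 2 classes.")

  center <- scale_sd <- NULL
  if (scale_features) {
    center <- colMeans(X)
    scale_sd <- apply(X, 2, stats::sd)
    scale_sd[scale_sd == 0] <- 1
    X <- sweep(sweep(X, 2, center), 2, scale_sd, `/`)
  }

  pairs <- utils::combn(labels, 2, simplify = FALSE)
  machines <- purrr::map(pairs, function(pr) {
    idx <- which(y %in% pr)
    Xp <- X[idx, , drop = FALSE]
    yp <- factor(as.character(y[idx]), levels = pr)
    n1 <- sum(yp == pr[1]); n2 <- sum(yp == pr[2])
    if (formulation == "nu_svc") {
      bound <- 2 * min(n1, n2) / (n1 + n2)
      if (nu > bound) {
        rlang::abort(sprintf(
          "nu = %g infeasible for pair %s/%s: requires nu <= 2*min(n1,n2)/(n1+n2) = %g.",
          nu, pr[1], pr[2], bound
        ))
      }
    }
    fit <- e1071::svm(
      x = Xp, y = yp,
      type = if (formulation == "c_svc") "C-classification" else "nu-classification",
      kernel = "linear", cost = cost, nu = nu,
      scale = FALSE, tolerance = 1e-7
    )
    w <- as.vector(crossprod(fit$coefs, fit$SV))
    b <- -fit$rho
    # orient the decision function so class pr[1] sits on the positive side
    f <- as.vector(Xp %*% w) + b
    if (mean(f[yp == pr[1]]) < mean(f[yp == pr[2]])) {
      w <- -w; b <- -b
    }
    list(
      labels = pr,
      w = w,
      b = b,
      alpha = as.vector(fit$coefs), # signed dual coefficients y_i * alpha_i
      sv_index = idx[fit$index],    # row indices into the training subset
      n_sv = nrow(fit$SV)
    )
  })

  structure(
    list(
      formulation = formulation,
      cost = if (formulation == "c_svc") cost else NULL,
      nu = if (formulation == "nu_svc") nu else NULL,
      labels = labels,
      machines = machines,
      wavenumbers = spc_wavenumbers(train),
      center = center,
      scale_sd = scale_sd
    ),
    class = "mir_svm"
  )
}

#' @export
print.mir_svm <- function(x, ...) {
  par <- if (x$formulation == "c_svc") sprintf("C = %g", x$cost) else sprintf("nu = %g", x$nu)
  cat(sprintf("<mir_svm> linear %s (%s), %d classes, %d binary machines\n",
              x$formulation, par, length(x$labels), length(x$machines)))
  invisible(x)
}

#' Predict subtype labels from a margin model
#'
#' Each pairwise machine votes for one of its two classes by the sign of
#' its decision value (an exact zero goes to the pair's first class in
#' label order). The label with the most votes wins; vote ties are broken
#' by the larger sum of signed decision values over the tied labels'
#' machines, then lexicographically. With two classes this reduces to the
#' sign of the single decision function.
#'
#' @param object A [fit_margin()] model.
#' @param newdata Spectra table or numeric matrix on the model's channels.
#' @param ... Unused.
#' @return Factor of predicted labels.
#' @export
predict.mir_svm <- function(object, newdata, ...) {
  X <- coerce_spectra(newdata, object$wavenumbers)
  if (!is.null(object$center)) {
    X <- sweep(sweep(X, 2, object$center), 2, object$scale_sd, `/`)
  }
  n <- nrow(X)
  labels <- object$labels
  votes <- matrix(0L, n, length(labels), dimnames = list(NULL, labels))
  support <- matrix(0, n, length(labels), dimnames = list(NULL, labels))
  for (m in object$machines) {
    f <- as.vector(X %*% m$w) + m$b
    pos <- f >= 0
    votes[, m$labels[1]] <- votes[, m$labels[1]] + as.integer(pos)
    votes[, m$labels[2]] <- votes[, m$labels[2]] + as.integer(!pos)
    support[, m$labels[1]] <- support[, m$labels[1]] + f
    support[, m$labels[2]] <- support[, m$labels[2]] - f
  }
  pred <- vapply(seq_len(n), function(i) {
    v <- votes[i, ]
    tied <- labels[v == max(v)]
    if (length(tied) > 1) {
      s <- support[i, tied]
      tied <- tied[s >= max(s) - 1e-12 * (1 + abs(max(s)))]
      sort(tied)[1]
    } else {
      tied
    }
  }, character(1))
  factor(pred, levels = labels)
}

#' @rdname augment.mir_lda
#' @export
augment.mir_svm <- function(x, data, ...) {
  data$.pred <- predict(x, data)
  data$model <- paste0("svm_", if (x$formulation == "c_svc") "c" else "nu")
  data
}

#' Tidy a margin model: one row per binary machine
#'
#' @param x A `mir_svm`.
#' @param ... Unused.
#' @return Tibble: positive/negative class, support-vector count, bias and
#'   geometric margin `2 / ||w||` per pairwise machine.
#' @export
tidy.mir_svm <- function(x, ...) {
  purrr::map_dfr(x$machines, function(m) {
    tibble::tibble(
      label_pos = m$labels[1],
      label_neg = m$labels[2],
      n_sv = m$n_sv,
      bias = m$b,
      margin = 2 / sqrt(sum(m$w^2))
    )
  })
}

#' @rdname glance.mir_lda
#' @export
glance.mir_svm <- function(x, ...) {
  tibble::tibble(
    variant = x$formulation,
    n_classes = length(x$labels),
    n_channels = length(x$wavenumbers),
    n_machines = length(x$machines),
    parameter = if (x$formulation == "c_svc") x$cost else x$nu
  )
}
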