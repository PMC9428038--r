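#' Fit a discriminant classifier (linear, quadratic or Mahalanobis)
#'
#' Fits a Bayes-rule discriminant on the training rows of a split spectra
#' table. All three variants share the class means (training means per
#' subtype); they differ in the covariance model and decision rule:
#'
#' * `linear` — pooled within-class covariance; scores
#'   `x' S^-1 mu_k - mu_k' S^-1 mu_k / 2 + log pi_k`.
#' * `quadratic` — per-class covariances; scores
#'   `-log|S_k|/2 - (x - mu_k)' S_k^-1 (x - mu_k)/2 + log pi_k`.
#' * `mahalanobis` — per-class covariances, but classifies by the smallest
#'   squared Mahalanobis distance to the class centroid alone: no
#'   determinant and no prior term. The missing determinant penalty is what
#'   lets the class with the widest covariance swallow essentially all
#'   predictions — the characteristic failure mode of this variant.
#'
#' Covariances are unbiased (n-1, pooled-df) estimates, each augmented with
#' a ridge `ridge_eps * mean(diag) * I` for numerical definiteness. Priors
#' are uniform (the cohort design is balanced).
#'
#' @param table A spectra table with roles assigned ([split_alternating()]).
#' @param variant `"linear"`, `"quadratic"` or `"mahalanobis"`.
#' @param ridge_eps Relative ridge added to every covariance (default 1e-6).
#' @return An object of class `mir_lda` with fields `variant`, `labels`,
#'   `means`, `cov` (pooled) or `covs` (per class), `priors`, `ridge_eps`,
#'   `wavenumbers` and per-class training counts.
#' @export
fit_discriminant <- function(table, variant = c("linear", "quadratic", "mahalanobis"),
                             ridge_eps = 1e-6) {
  variant <- rlang::arg_match(variant)
  train <- dplyr::filter(table, .data$role == "train")
  X <- spc_matrix(train)
  labels <- levels(droplevels(table$subtype))
  y <- factor(as.character(train$subtype), levels = labels)
  counts <- base::table(y)
  absent <- labels[counts == 0]
  if (length(absent) > 0) {
    rlang::abort(paste0("Class(es) absent from training data: ",
                        paste(absent, collapse = ", ")))
  }
  if (length(labels) < 2) rlang::abort("Need at least 2 classes.")
  if (any(counts < 2)) {
    rlang::abort("Every class needs at least 2 training rows.")
  }
  p <- ncol(X)
  means <- t(vapply(labels, function(l) colMeans(X[y == l, , drop = FALSE]),
                    numeric(p)))
  ridge <- function(S) {
    Sg <- S + ridge_eps * mean(diag(S)) * diag(p)
    ok <- tryCatch({ chol(Sg); TRUE }, error = function(e) FALSE)
    if (!ok) {
      rlang::abort(sprintf(
        "Covariance is singular (ridge_eps = %g); increase `ridge_eps`.",
        ridge_eps
      ))
    }
    Sg
  }
  if (variant == "linear") {
    pooled <- matrix(0, p, p)
    for (l in labels) {
      Xl <- X[y == l, , drop = FALSE]
      pooled <- pooled + stats::cov(Xl) * (nrow(Xl) - 1)
    }
    pooled <- pooled / (nrow(X) - length(labels))
    covs <- NULL
    pooled <- ridge(pooled)
  } else {
    covs <- purrr::map(labels, function(l) ridge(stats::cov(X[y == l, , drop = FALSE])))
    names(covs) <- labels
    pooled <- NULL
  }
  structure(
    list(
      variant = variant,
      labels = labels,
      means = means,
      cov = pooled,
      covs = covs,
      priors = stats::setNames(rep(1 / length(labels), length(labels)), labels),
      ridge_eps = ridge_eps,
      wavenumbers = spc_wavenumbers(train),
      n_train = as.integer(counts)
    ),
    class = "mir_lda"
  )
}

#' @export
print.mir_lda <- function(x, ...) {
  cat(sprintf("<mir_lda> %s discriminant, %d classes x %d channels (ridge %g)\n",
              x$variant, length(x$labels), length(x$wavenumbers), x$ridge_eps))
  invisible(x)
}

# Score matrix (n x K); higher is better for every variant.
discriminant_scores <- function(model, X) {
  K <- length(model$labels)
  scores <- matrix(NA_real_, nrow(X), K, dimnames = list(NULL, model$labels))
  if (model$variant == "linear") {
    W <- solve(model$cov)
    for (k in seq_len(K)) {
      mu <- model$means[k, ]
      wk <- W %*% mu
      scores[, k] <- X %*% wk - 0.5 * sum(mu * wk) + log(model$priors[k])
    }
  } else {
    for (k in seq_len(K)) {
      S <- model$covs[[k]]
      ch <- chol(S)
      mu <- model$means[k, ]
      Z <- backsolve(ch, t(sweep(X, 2, mu)), transpose = TRUE)
      d2 <- colSums(Z^2)
      scores[, k] <- if (model$variant == "quadratic") {
        -sum(log(diag(ch))) - 0.5 * d2 + log(model$priors[k])
      } else {
        -d2 # mahalanobis: nearest centroid in per-class metric
      }
    }
  }
  scores
}

# argmax with deterministic tie-breaking: near-exact ties go to the
# lexicographically smallest label.
argmax_label <- function(scores, labels) {
  apply(scores, 1, function(s) {
    m <- max(s)
    tied <- labels[s >= m - 1e-9 * (1 + abs(m))]
    sort(tied)[1]
  })
}

coerce_spectra <- function(newdata, wavenumbers) {
  X <- if (is.matrix(newdata)) newdata else spc_matrix(newdata)
  wn <- if (is.null(colnames(X))) NULL else as.numeric(colnames(X))
  if (ncol(X) != length(wavenumbers) ||
      (!is.null(wn) && max(abs(wn - wavenumbers)) > 1e-6)) {
    rlang::abort("Spectra channels do not match the model's wavenumber set.")
  }
  X
}

#' Predict subtype labels from a discriminant model
#'
#' @param object A [fit_discriminant()] model.
#' @param newdata A spectra table or a plain numeric matrix on the model's
#'   channel set.
#' @param ... Unused.
#' @return Factor of predicted labels (levels = the model's label set).
#'   Score ties resolve to the lexicographically smaller label.
#' @export
predict.mir_lda <- function(object, newdata, ...) {
  X <- coerce_spectra(newdata, object$wavenumbers)
  scores <- discriminant_scores(object, X)
  factor(argmax_label(scores, object$labels), levels = object$labels)
}

#' Attach predictions to a spectra table
#'
#' broom-style `augment()`: adds a `.pred` factor column (and a `model`
#' identifier column) with one prediction per row of `data`.
#'
#' @param x A fitted `mir_lda` or `mir_svm` model.
#' @param data A spectra table on the model's channel set.
#' @param ... Unused.
#' @return `data` plus `.pred` and `model` columns.
#' @export
augment.mir_lda <- function(x, data, ...) {
  data$.pred <- predict(x, data)
  data$model <- paste0("lda_", x$variant)
  data
}

#' Tidy a discriminant model: per-class mean spectra in long form
#'
#' @param x A `mir_lda`.
#' @param ... Unused.
#' @return Tibble with columns class, wavenumber_cm1, mean_absorbance.
#' @export
tidy.mir_lda <- function(x, ...) {
  tibble::tibble(
    class = rep(x$labels, each = length(x$wavenumbers)),
    wavenumber_cm1 = rep(x$wavenumbers, times = length(x$labels)),
    mean_absorbance = as.vector(t(x$means))
  )
}

#' One-row model summary
#'
#' @param x A `mir_lda`.
#' @param ... Unused.
#' @return One-row tibble: variant, classes, channels, training size, ridge.
#' @export
glance.mir_lda <- function(x, ...) {
  tibble::tibble(
    variant = x$variant,
    n_classes = length(x$labels),
    n_channels = length(x$wavenumbers),
    n_train = sum(x$n_train),
    ridge_eps = x$ridge_eps
  )
}
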