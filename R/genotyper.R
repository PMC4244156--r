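#' Fit a min–max feature scaler
#'
#' Linear per-dimension rescaling of the training features onto
#' `[-1, 1]`, the customary preconditioning for RBF-kernel SVMs (features
#' on very different scales would otherwise dominate the kernel distance).
#' Constant training dimensions are flagged and map to 0 for any input.
#'
#' @param x Numeric matrix (rows = vectors) or data frame of training
#'   features.
#' @return An `indel_scaler` with per-dimension `min` and `max`.
#' @examples
#' sc <- fit_scaler(matrix(c(0, 5, 10), ncol = 1))
#' apply_scaler(sc, matrix(c(0, 5, 10, 20), ncol = 1))
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 1) abort("fit_scaler(): empty training set")
  if (anyNA(x)) abort("fit_scaler(): NA in training features")
  mn <- apply(x, 2, min); mx <- apply(x, 2, max)
  structure(list(min = mn, max = mx, constant = mx == mn,
                 dim = ncol(x), names = colnames(x)),
            class = "indel_scaler")
}

#' Apply a fitted scaler
#'
#' Componentwise linear map onto `[-1, 1]`; inputs outside the training
#' range extrapolate linearly (no clamping), constant training dimensions
#' give 0.
#'
#' @param scaler An `indel_scaler` from [fit_scaler()].
#' @param x Numeric matrix or data frame with the scaler's dimension.
#' @return The scaled matrix.
#' @export
apply_scaler <- function(scaler, x) {
  x <- as.matrix(x)
  if (ncol(x) != scaler$dim)
    abort(paste0("apply_scaler(): expected ", scaler$dim,
                 " dimensions, got ", ncol(x)))
  rng <- scaler$max - scaler$min
  rng[scaler$constant] <- 1  # arbitrary; result forced to 0 below
  out <- sweep(sweep(x, 2, scaler$min), 2, rng, "/") * 2 - 1
  out[, scaler$constant] <- 0
  out
}

default_cost_grid <- function() 2^seq(-5, 15, by = 2)
default_gamma_grid <- function() 2^seq(-15, 3, by = 2)

#' Train the indel genotype classifier
#'
#' Fits the multi-class genotype SVM: features are min–max scaled to
#' `[-1, 1]`, then an RBF-kernel SVM is tuned by grid search over
#' `(cost, gamma)` with stratified `folds`-fold cross-validation
#' (seed-deterministic fold assignment), and the winning parameters —
#' highest CV accuracy, ties broken toward smaller `cost` then smaller
#' `gamma` (smoother models) — are refit on the full training set.
#'
#' Deletion and insertion sites have different feature semantics, so a
#' model is always trained for a single indel kind.
#'
#' @param features Either a feature tibble (from [extract_features()])
#'   carrying a `label` column of truth genotypes 0/1/2, or a numeric
#'   matrix; in the latter case supply `labels`.
#' @param labels Integer genotypes 0/1/2, one per row (matrix input only).
#' @param kind `"DEL"` or `"INS"`; inferred from a `kind` column when
#'   present (must be a single kind).
#' @param folds Cross-validation folds (default 10); reduced to the
#'   training size with a warning when there are fewer examples.
#' @param cost_grid,gamma_grid Candidate RBF parameters; defaults are the
#'   canonical coarse lattices `2^(-5,-3,...,15)` and `2^(-15,-13,...,3)`.
#' @param seed Integer seed controlling fold assignment.
#' @param class_weights If `TRUE`, weight classes by inverse frequency
#'   (genotype 0 dominates at low allele frequency); off by default.
#' @return A `genotype_model`: scaler, fitted [e1071::svm()] classifier,
#'   winning `cost`/`gamma`, `cv_accuracy`, the full `cv_table` of the grid
#'   search, class set, feature order, and the training data (retained for
#'   deterministic persistence, see [save_genotype_model()]).
#' @export
train_genotyper <- function(features, labels = NULL, kind = NULL,
                            folds = 10L,
                            cost_grid = default_cost_grid(),
                            gamma_grid = default_gamma_grid(),
                            seed = 1L, class_weights = FALSE) {
  if (is.data.frame(features)) {
    if (is.null(labels)) {
      if (!"label" %in% names(features))
        abort("feature tibble must carry a `label` column (truth genotypes)")
      labels <- features$label
    }
    if (is.null(kind) && "kind" %in% names(features)) {
      kinds <- unique(features$kind)
      if (base::length(kinds) > 1)
        abort("mixed DEL/INS features: train one model per indel kind")
      kind <- kinds
    }
    x <- as.matrix(features[, intersect(feature_cols, names(features))])
  } else {
    x <- as.matrix(features)
  }
  kind <- kind %||% "DEL"
  y <- as.integer(labels)
  if (base::length(y) != nrow(x))
    abort("labels do not match the number of feature vectors")
  if (!all(y %in% 0:2)) abort("labels must be genotypes 0, 1 or 2")
  classes <- sort(unique(y))
  if (base::length(classes) < 2)
    abort("training data has a single genotype class; cannot train")
  if (nrow(x) < folds) {
    warn(paste0("fewer examples (", nrow(x), ") than folds (", folds,
                "); reducing folds"))
    folds <- nrow(x)
  }

  scaler <- fit_scaler(x)
  xs <- apply_scaler(scaler, x)
  yf <- factor(y, levels = classes)
  wts <- if (class_weights)
    stats::setNames(sum(table(yf)) / (nlevels(yf) * table(yf)), levels(yf))
  else NULL

  fold_id <- stratified_folds(y, folds, seed)
  grid <- tidyr::expand_grid(cost = sort(cost_grid),
                             gamma = sort(gamma_grid))
  cv_acc <- purrr::map2_dbl(grid$cost, grid$gamma, function(C, g) {
    correct <- 0L
    for (k in seq_len(folds)) {
      tr <- fold_id != k
      if (all(tr) || base::length(unique(y[tr])) < 2) next
      fit <- e1071::svm(xs[tr, , drop = FALSE], yf[tr], kernel = "radial",
                        cost = C, gamma = g, scale = FALSE,
                        class.weights = wts)
      pred <- predict(fit, xs[!tr, , drop = FALSE])
      correct <- correct + sum(pred == yf[!tr])
    }
    correct / nrow(x)
  })
  best <- which(cv_acc == max(cv_acc))[1]  # grid sorted: smaller C, then gamma
  fit <- e1071::svm(xs, yf, kernel = "radial", cost = grid$cost[best],
                    gamma = grid$gamma[best], scale = FALSE,
                    probability = TRUE, class.weights = wts)
  structure(list(scaler = scaler, svm = fit,
                 cost = grid$cost[best], gamma = grid$gamma[best],
                 folds = folds, seed = as.integer(seed),
                 cv_accuracy = cv_acc[best],
                 cv_table = mutate(grid, accuracy = cv_acc),
                 kind = kind, feature_names = feature_names_for(kind),
                 classes = classes, class_weights = class_weights,
                 x_train = x, y_train = y),
            class = "genotype_model")
}

feature_names_for <- function(kind) {
  if (kind == "INS") ins_feature_names else del_feature_names
}

stratified_folds <- function(y, folds, seed) {
  withr::with_seed(seed, {
    fold_id <- integer(base::length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold_id[idx] <- rep_len(seq_len(folds), base::length(idx))
    }
    fold_id
  })
}

#' @export
print.genotype_model <- function(x, ...) {
  cat(sprintf(paste0("<genotype_model> %s sites, %d training vectors, ",
                     "classes {%s}\n  RBF cost=%g gamma=%g, %d-fold CV ",
                     "accuracy %.4f\n"),
              x$kind, nrow(x$x_train), paste(x$classes, collapse = ","),
              x$cost, x$gamma, x$folds, x$cv_accuracy))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the genotyper's grid search
#'
#' @param x A `genotype_model`.
#' @param ... Unused.
#' @return A tibble of grid points with columns `cost`, `gamma`,
#'   `accuracy` (cross-validated).
#' @export
tidy.genotype_model <- function(x, ...) as_tibble(x$cv_table)

#' One-row summary of a genotype model
#'
#' @param x A `genotype_model`.
#' @param ... Unused.
#' @return A one-row tibble: `kind`, `n_train`, `folds`, `cost`, `gamma`,
#'   `cv_accuracy`, `n_support`.
#' @export
glance.genotype_model <- function(x, ...) {
  tibble(kind = x$kind, n_train = nrow(x$x_train), folds = x$folds,
         cost = x$cost, gamma = x$gamma, cv_accuracy = x$cv_accuracy,
         n_support = nrow(x$svm$SV))
}

#' Call genotypes with a trained model
#'
#' Scales the feature vectors with the model's scaler and classifies each
#' into genotype 0/1/2. With `with_probs = TRUE` per-class probabilities
#' (libsvm pairwise coupling) are attached and the called genotype is the
#' probability argmax (ties broken toward the smaller genotype), so call
#' and probabilities are always consistent.
#'
#' @param model A `genotype_model` from [train_genotyper()].
#' @param features Feature tibble (columns `f1`..`f5`, and `sample`,
#'   `site_id` carried through when present) or numeric matrix.
#' @param with_probs Attach per-genotype probabilities `p0`, `p1`, `p2`.
#' @return A tibble with `sample`/`site_id` (when available), `genotype`,
#'   and optionally `p0`, `p1`, `p2` (summing to 1).
#' @export
call_genotypes <- function(model, features, with_probs = FALSE) {
  if (is.data.frame(features)) {
    if ("kind" %in% names(features)) {
      kinds <- unique(features$kind)
      if (!all(kinds == model$kind))
        abort(paste0("model is for ", model$kind, " sites but features ",
                     "contain ", paste(kinds, collapse = ",")))
    }
    ids <- features[, intersect(c("sample", "site_id"), names(features))]
    x <- as.matrix(features[, intersect(feature_cols, names(features))])
  } else {
    x <- as.matrix(features)
    ids <- NULL
  }
  if (ncol(x) != model$scaler$dim)
    abort(paste0("feature dimension ", ncol(x), " does not match the ",
                 "model's ", model$scaler$dim))
  xs <- apply_scaler(model$scaler, x)
  pred <- predict(model$svm, xs, probability = with_probs)
  g <- as.integer(as.character(pred))
  out <- tibble(genotype = g)
  if (with_probs) {
    pr <- attr(pred, "probabilities")
    full <- matrix(0, nrow(x), 3, dimnames = list(NULL, c("0", "1", "2")))
    full[, colnames(pr)] <- pr
    full <- full / rowSums(full)
    # call = probability argmax so probabilities and calls never disagree
    out$genotype <- as.integer(colnames(full)[max.col(full, "first")])
    out$p0 <- full[, "0"]; out$p1 <- full[, "1"]; out$p2 <- full[, "2"]
  }
  if (!is.null(ids) && ncol(ids) > 0) out <- dplyr::bind_cols(ids, out)
  out
}

#' @export
predict.genotype_model <- function(object, newdata, with_probs = FALSE, ...) {
  call_genotypes(object, newdata, with_probs = with_probs)
}
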