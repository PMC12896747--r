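#' Stratified train/test split
#'
#' Splits a feature table (or any tibble with a label column) into disjoint,
#' exhaustive train and test sets, stratified by label when every class has
#' at least 2 samples (falling back to an unstratified split with a warning
#' otherwise). Deterministic for a fixed seed.
#'
#' @param records A tibble with a `label` column.
#' @param test_frac Test fraction in (0, 1); default 0.2 (the 8:2 split).
#' @param seed RNG seed (default 42).
#' @param label Column name to stratify on (default `"label"`).
#' @return A list with tibbles `train` and `test`.
#' @export
split_data <- function(records, test_frac = 0.2, seed = 42, label = "label") {
  if (!label %in% names(records)) stop_validation("no '%s' column", label)
  n <- nrow(records)
  if (n < 5L) stop_validation("need at least 5 samples to split")
  if (test_frac <= 0 || test_frac >= 1) {
    stop_validation("test_frac must lie in (0, 1)")
  }
  y <- as.character(records[[label]])
  tab <- table(y)
  test_idx <- with_seed(seed, {
    if (any(tab < 2L)) {
      warn("a class has fewer than 2 samples; falling back to an unstratified split")
      sample.int(n, size = max(1L, round(test_frac * n)))
    } else {
      unlist(lapply(names(tab), function(cl) {
        idx <- which(y == cl)
        k <- max(1L, round(test_frac * length(idx)))
        sample(idx, size = k)
      }), use.names = FALSE)
    }
  })
  list(train = records[-test_idx, , drop = FALSE],
       test = records[sort(test_idx), , drop = FALSE])
}

#' Classifier specification
#'
#' Hyperparameters of the five qualitative model kinds, with the published
#' settings as defaults: RF (100 trees, seed 42), SVM (linear kernel,
#' balanced class weights, seed 42), GBT (100 rounds, learning rate 0.1,
#' depth 3, seed 42), LR (library defaults, seeded), CNN (the
#' Conv-Attention-MLP backbone).
#'
#' @param kind One of `"cnn"`, `"rf"`, `"svm"`, `"lr"`, `"gbt"`.
#' @param seed Model seed (default 42).
#' @param ... Kind-specific overrides: `n_trees` (rf), `n_rounds`,
#'   `learning_rate`, `max_depth` (gbt), `epochs`, `batch`, `lr`,
#'   `filters`, `kernels` (cnn).
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("cnn", "rf", "svm", "lr", "gbt"),
                            seed = 42, ...) {
  kind <- match.arg(tolower(kind[1]), c("cnn", "rf", "svm", "lr", "gbt"))
  opts <- list(...)
  defaults <- switch(kind,
    rf = list(n_trees = 100),
    svm = list(),
    lr = list(),
    gbt = list(n_rounds = 100, learning_rate = 0.1, max_depth = 3),
    cnn = list(epochs = 120, batch = 32, lr = 1e-3, patience = 20,
               filters = c(64, 256), kernels = c(5, 3))
  )
  for (nm in names(opts)) defaults[[nm]] <- opts[[nm]]
  structure(c(list(kind = kind, seed = seed), defaults),
            class = "classifier_spec")
}

check_training_labels <- function(y) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) {
    stop_validation("training set contains a single class ('%s')", levels(y)[1])
  }
  y
}

#' Train a qualitative classifier
#'
#' Fits one of the five classifier kinds on a feature table. Features are
#' z-scored with training-set statistics before fitting (stored and applied
#' at prediction time). All kinds are deterministic for a fixed seed.
#'
#' @param spec A [classifier_spec()] (or a kind string).
#' @param train A feature table tibble (or list(x, y) with a matrix and
#'   labels).
#' @param label Label column of the feature table.
#' @return An object of class `oil_classifier`.
#' @export
train_classifier <- function(spec, train, label = "label") {
  if (is.character(spec)) spec <- classifier_spec(spec)
  stopifnot(inherits(spec, "classifier_spec"))
  if (is.data.frame(train)) {
    x <- feature_matrix(train)
    y <- train[[label]]
  } else {
    x <- train$x; y <- train$y
  }
  y <- check_training_labels(y)
  scaler <- fit_scaler(x)
  z <- apply_scaler(x, scaler)
  lev <- levels(y)
  fit <- switch(spec$kind,
    rf = with_seed(spec$seed,
      randomForest::randomForest(x = z, y = y, ntree = spec$n_trees)),
    svm = {
      wts <- nrow(z) / (nlevels(y) * table(y))
      with_seed(spec$seed,
        e1071::svm(x = z, y = y, kernel = "linear", scale = FALSE,
                   class.weights = setNames(as.numeric(wts), names(wts)),
                   decision.values = TRUE))
    },
    lr = {
      if (nlevels(y) == 2L) {
        df <- data.frame(z, check.names = FALSE)
        df$.y <- y
        with_seed(spec$seed,
          suppressWarnings(glm(.y ~ ., data = df, family = binomial())))
      } else {
        df <- data.frame(z, check.names = FALSE)
        df$.y <- y
        with_seed(spec$seed,
          nnet::multinom(.y ~ ., data = df, trace = FALSE,
                         MaxNWts = 1e6, maxit = 200))
      }
    },
    gbt = {
      num_y <- as.integer(y) - 1L
      params <- list(max_depth = spec$max_depth, eta = spec$learning_rate,
                     nthread = 1, seed = spec$seed)
      if (nlevels(y) == 2L) {
        params$objective <- "binary:logistic"
      } else {
        params$objective <- "multi:softprob"
        params$num_class <- nlevels(y)
      }
      dtrain <- xgboost::xgb.DMatrix(z, label = num_y)
      with_seed(spec$seed,
        xgboost::xgb.train(params = params, data = dtrain,
                           nrounds = spec$n_rounds, verbose = 0))
    },
    cnn = {
      arch <- cnn_architecture(ncol(z), filters = spec$filters,
                               kernels = spec$kernels)
      yoh <- stats::model.matrix(~ y - 1)
      colnames(yoh) <- lev
      cam_train(z, yoh, arch, loss = "ce", epochs = spec$epochs,
                batch = spec$batch, lr = spec$lr,
                patience = spec$patience, seed = spec$seed)
    }
  )
  structure(list(spec = spec, fit = fit, scaler = scaler, levels = lev,
                 n_features = ncol(x), feature_names = colnames(x)),
            class = "oil_classifier")
}

#' Build an untrained Conv-Attention-MLP classifier network
#'
#' Exposes the network constructor directly: initialises the parameter set
#' of the dual-branch architecture for a given input length and class
#' count. Its forward pass returns a probability simplex per sample.
#'
#' @param arch A [cnn_architecture()].
#' @param n_classes Number of output classes (>= 2).
#' @param seed Initialisation seed.
#' @return A list of class `cam_network` with elements `arch`, `params`;
#'   use [predict()][predict.cam_network] for a forward pass.
#' @export
build_cnn <- function(arch, n_classes, seed = 42) {
  stopifnot(inherits(arch, "cnn_architecture"))
  if (n_classes < 2L) stop_validation("need at least 2 output classes")
  structure(list(arch = arch, params = cam_init(arch, n_classes, seed)),
            class = "cam_network")
}

#' @rdname build_cnn
#' @param object A `cam_network`.
#' @param newdata Numeric matrix of inputs (samples in rows).
#' @param ... Unused.
#' @export
predict.cam_network <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != object$arch$input_len) {
    stop_contract("input length %d does not match network input %d",
                  ncol(newdata), object$arch$input_len)
  }
  cam_forward(object$params, newdata, object$arch)$probs
}

#' Predict class probabilities or scores
#'
#' @param object A fitted `oil_classifier`.
#' @param newdata Feature table or numeric matrix; columns must match the
#'   training features.
#' @param ... Unused.
#' @return A tibble aligned to the input order: one score column per class
#'   (probabilities for RF/LR/GBT/CNN; monotone decision-derived scores for
#'   SVM) and `.pred_class`.
#' @export
predict.oil_classifier <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- feature_matrix(newdata)
  if (!nrow(newdata)) {
    out <- as_tibble(setNames(
      rep(list(numeric(0)), length(object$levels)), object$levels))
    out$.pred_class <- character(0)
    return(out)
  }
  if (ncol(newdata) != object$n_features) {
    stop_contract("feature dimension mismatch: model expects %d, got %d",
                  object$n_features, ncol(newdata))
  }
  z <- apply_scaler(newdata, object$scaler)
  lev <- object$levels
  kind <- object$spec$kind
  scores <- switch(kind,
    rf = {
      p <- predict(object$fit, z, type = "prob")
      p[, lev, drop = FALSE]
    },
    svm = {
      pr <- predict(object$fit, z, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      sc <- matrix(0, nrow(z), length(lev), dimnames = list(NULL, lev))
      for (j in seq_len(ncol(dv))) {
        pair <- strsplit(colnames(dv)[j], "/", fixed = TRUE)[[1]]
        sc[, pair[1]] <- sc[, pair[1]] + dv[, j]
        sc[, pair[2]] <- sc[, pair[2]] - dv[, j]
      }
      sc / max(1L, ncol(dv))
    },
    lr = {
      if (length(lev) == 2L) {
        p1 <- predict(object$fit, newdata = data.frame(z, check.names = FALSE),
                      type = "response")
        cbind(matrix(1 - p1, ncol = 1, dimnames = list(NULL, lev[1])),
              matrix(p1, ncol = 1, dimnames = list(NULL, lev[2])))
      } else {
        p <- predict(object$fit, newdata = data.frame(z, check.names = FALSE),
                     type = "probs")
        if (is.null(dim(p))) p <- matrix(p, nrow = 1L, dimnames = list(NULL, lev))
        p[, lev, drop = FALSE]
      }
    },
    gbt = {
      p <- predict(object$fit, xgboost::xgb.DMatrix(z))
      if (length(lev) == 2L) {
        cbind(matrix(1 - p, ncol = 1, dimnames = list(NULL, lev[1])),
              matrix(p, ncol = 1, dimnames = list(NULL, lev[2])))
      } else {
        matrix(p, ncol = length(lev), byrow = TRUE,
               dimnames = list(NULL, lev))
      }
    },
    cnn = {
      p <- cam_predict(object$fit, z)
      colnames(p) <- lev
      p
    }
  )
  out <- as_tibble(as.data.frame(scores))
  out$.pred_class <- lev[max.col(as.matrix(scores), ties.method = "first")]
  out
}

#' Quantifier specification
#'
#' Training protocol of the Conv-Attention-MLP composition quantifier:
#' softmax output over the five oil fractions, Adam with learning-rate
#' decay, mean-squared-error loss, an internal validation split (20% of the
#' training data) and early stopping.
#'
#' @param epochs,batch,lr,patience,lr_patience,clip Training-loop settings:
#'   epoch cap, minibatch size, initial Adam learning rate, early-stopping
#'   patience, plateau patience before halving the learning rate, and the
#'   global gradient-norm clip.
#' @param warmup,n_starts,start_epochs,plateau_restarts Optimisation-
#'   robustness settings: linear warmup epochs, number of seeded restarts,
#'   the length of the restart phase before the best start (by validation
#'   loss) is trained to completion, and how many times a validation
#'   plateau warm-restarts the learning rate (from the best snapshot)
#'   before training stops.
#' @param filters,kernels Convolution stack sizes.
#' @param val_frac Validation fraction of the training data (default 0.2).
#' @param seed Seed controlling initialisation, shuffling and the
#'   validation split.
#' @return A list of class `quantifier_spec`.
#' @export
quantifier_spec <- function(epochs = 300, batch = 32, lr = 5e-3,
                            patience = 50, lr_patience = 20, clip = 1,
                            warmup = 5, n_starts = 3, start_epochs = 40,
                            plateau_restarts = 2,
                            filters = c(64, 256), kernels = c(5, 3),
                            val_frac = 0.2, seed = 42) {
  structure(list(epochs = epochs, batch = batch, lr = lr, patience = patience,
                 lr_patience = lr_patience, clip = clip, warmup = warmup,
                 n_starts = n_starts, start_epochs = start_epochs,
                 plateau_restarts = plateau_restarts,
                 filters = filters, kernels = kernels, val_frac = val_frac,
                 seed = seed),
            class = "quantifier_spec")
}

#' Train the composition quantifier
#'
#' Fits the Conv-Attention-MLP regression network to predict the five-oil
#' volume-fraction vector. The softmax head guarantees every prediction is
#' a probability simplex (non-negative, summing to 1) for arbitrary inputs.
#'
#' @param spec A [quantifier_spec()].
#' @param train A feature table with the five `frac_*` columns, or
#'   `list(x, y)` with a matrix and a 5-column fraction matrix.
#' @return An object of class `oil_quantifier` with the fitted network and
#'   its training curve.
#' @export
train_quantifier <- function(spec = quantifier_spec(), train) {
  stopifnot(inherits(spec, "quantifier_spec"))
  if (is.data.frame(train)) {
    x <- feature_matrix(train)
    y <- as.matrix(train[fraction_cols()])
  } else {
    x <- train$x; y <- as.matrix(train$y)
  }
  if (ncol(y) != 5L) stop_validation("fraction matrix must have 5 columns")
  if (any(y < 0) || any(abs(rowSums(y) - 1) > 1e-6)) {
    stop_validation("fractions must be >= 0 and sum to 1 per sample")
  }
  scaler <- fit_scaler(x)
  z <- apply_scaler(x, scaler)
  arch <- cnn_architecture(ncol(z), filters = spec$filters,
                           kernels = spec$kernels)
  fit <- cam_train(z, y, arch, loss = "mse", epochs = spec$epochs,
                   batch = spec$batch, lr = spec$lr, val_frac = spec$val_frac,
                   patience = spec$patience, lr_patience = spec$lr_patience,
                   clip = spec$clip, warmup = spec$warmup,
                   n_starts = spec$n_starts, start_epochs = spec$start_epochs,
                   plateau_restarts = spec$plateau_restarts,
                   seed = spec$seed)
  structure(list(spec = spec, fit = fit, scaler = scaler,
                 n_features = ncol(x), oils = oil_classes(),
                 curve = fit$curve),
            class = "oil_quantifier")
}

#' @rdname train_quantifier
#' @param object A fitted `oil_quantifier`.
#' @param newdata Feature table or matrix.
#' @param ... Unused.
#' @return `predict()` returns a tibble with the five predicted fraction
#'   columns (`frac_cao ... frac_suo`), each row summing to 1.
#' @export
predict.oil_quantifier <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- feature_matrix(newdata)
  if (!nrow(newdata)) {
    return(as_tibble(setNames(rep(list(numeric(0)), 5L), fraction_cols())))
  }
  if (ncol(newdata) != object$n_features) {
    stop_contract("feature dimension mismatch: model expects %d, got %d",
                  object$n_features, ncol(newdata))
  }
  z <- apply_scaler(newdata, object$scaler)
  p <- cam_predict(object$fit, z)
  colnames(p) <- fraction_cols()
  as_tibble(as.data.frame(p))
}

#' @export
print.oil_classifier <- function(x, ...) {
  cat(sprintf("<oil_classifier> kind=%s, %d features, classes: %s\n",
              x$spec$kind, x$n_features, paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' @export
print.oil_quantifier <- function(x, ...) {
  cat(sprintf("<oil_quantifier> Conv-Attention-MLP, %d features, best epoch %d (val MSE %.3g)\n",
              x$n_features, x$fit$best_epoch, x$fit$val_loss))
  invisible(x)
}

#' @method glance oil_quantifier
#' @export
glance.oil_quantifier <- function(x, ...) {
  tibble(best_epoch = x$fit$best_epoch, val_mse = x$fit$val_loss,
         epochs_run = nrow(x$curve))
}

#' @method tidy oil_quantifier
#' @export
tidy.oil_quantifier <- function(x, ...) x$curve
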