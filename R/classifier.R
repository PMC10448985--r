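# Small feed-forward classifier over the 16 sensor features: 16 -> 10 -> 2 by
# default, SELU activations, unnormalized 2-score output trained with
# softmax cross-entropy from logits (Adam, early stopping on validation loss),
# five models from disjoint 20% validation folds of one balanced sample.

SELU_LAMBDA <- 1.0507009873554804934193349852946
SELU_ALPHA  <- 1.6732632423543772848170429916717

selu <- function(x) SELU_LAMBDA * ifelse(x > 0, x, SELU_ALPHA * (exp(x) - 1))
selu_grad <- function(x, a) ifelse(x > 0, SELU_LAMBDA, a + SELU_LAMBDA * SELU_ALPHA)

#' Network architecture and training hyperparameters
#'
#' Defaults follow the published architecture (one hidden layer of 10 SELU
#' neurons, two unnormalized output scores); the optimizer settings are
#' conventional choices for a network this small since none are published:
#' Adam at learning rate 1e-3, batch 256, at most 100 epochs with early
#' stopping patience 5 on validation loss.
#'
#' @param hidden_layers Number of hidden layers (>= 1).
#' @param neurons Neurons per hidden layer.
#' @param learning_rate,batch_size,max_epochs,patience Optimizer settings.
#' @param standardize Standardize features to zero mean / unit sd (SELU
#'   networks assume roughly normalized input).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(hidden_layers = 1L, neurons = 10L,
                       learning_rate = 1e-3, batch_size = 256L,
                       max_epochs = 100L, patience = 5L,
                       standardize = TRUE) {
  stopifnot(hidden_layers >= 1L, neurons >= 1L, learning_rate > 0,
            batch_size >= 1L, max_epochs >= 1L, patience >= 1L)
  structure(list(hidden_layers = as.integer(hidden_layers),
                 neurons = as.integer(neurons),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 standardize = isTRUE(standardize)),
            class = "model_spec")
}

#' Balanced sampling of training positions
#'
#' Draws exactly `n1` coding and `n0` noncoding valid positions from a truth
#' track, each without replacement, reproducibly under `seed`.
#'
#' @param track A [prediction_track()] of truth labels.
#' @param n1,n0 Coding / noncoding sample sizes (the published scheme uses
#'   `n1 = n0 = Ns/2`).
#' @param seed Integer seed.
#' @return Integer vector of `n1 + n0` distinct 1-based positions.
#' @export
sample_balanced <- function(track, n1, n0, seed = 1L) {
  v <- track$valid_start:track$valid_end
  pos1 <- v[track$labels[v] == 1L]
  pos0 <- v[track$labels[v] == 0L]
  if (length(pos1) < n1)
    stop("coding class has ", length(pos1), " valid positions, need ", n1)
  if (length(pos0) < n0)
    stop("noncoding class has ", length(pos0), " valid positions, need ", n0)
  withr::with_seed(seed, {
    c(pos1[sample.int(length(pos1), n1)], pos0[sample.int(length(pos0), n0)])
  })
}

# weight init: LeCun normal (SELU self-normalizing regime)
mlp_init <- function(sizes, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(length(sizes) - 1L), function(i) {
      list(W = matrix(stats::rnorm(sizes[i] * sizes[i + 1L],
                                   sd = 1 / sqrt(sizes[i])),
                      sizes[i], sizes[i + 1L]),
           b = numeric(sizes[i + 1L]))
    })
  })
}

# forward pass; returns logits and (optionally) layer caches for backprop
mlp_forward <- function(params, x, keep = FALSE) {
  L <- length(params)
  caches <- if (keep) vector("list", L) else NULL
  a <- x
  for (l in seq_len(L)) {
    z <- sweep(a %*% params[[l]]$W, 2L, params[[l]]$b, "+")
    if (keep) caches[[l]] <- list(a_in = a, z = z)
    a <- if (l < L) selu(z) else z      # linear output layer (logits)
  }
  list(logits = a, caches = caches)
}

# mean softmax cross-entropy of logits vs labels in {0,1}
ce_loss <- function(logits, y) {
  m <- pmax(logits[, 1], logits[, 2])
  lse <- m + log(exp(logits[, 1] - m) + exp(logits[, 2] - m))
  picked <- logits[cbind(seq_along(y), y + 1L)]
  mean(lse - picked)
}

# one Adam step on a minibatch; returns updated params/state
mlp_train_model <- function(x_tr, y_tr, x_va, y_va, spec, seed) {
  sizes <- c(ncol(x_tr), rep(spec$neurons, spec$hidden_layers), 2L)
  params <- mlp_init(sizes, seed)
  L <- length(params)
  mstate <- lapply(params, function(p)
    list(W = p$W * 0, b = p$b * 0, W2 = p$W * 0, b2 = p$b * 0))
  lr <- spec$learning_rate; b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  n <- nrow(x_tr)
  best_loss <- Inf; best_params <- params; wait <- 0L; epochs_run <- 0L
  order_seed <- seed + 1000L
  for (epoch in seq_len(spec$max_epochs)) {
    idx <- withr::with_seed(order_seed + epoch, sample.int(n))
    for (ofs in seq(1L, n, by = spec$batch_size)) {
      bi <- idx[ofs:min(ofs + spec$batch_size - 1L, n)]
      xb <- x_tr[bi, , drop = FALSE]; yb <- y_tr[bi]
      fw <- mlp_forward(params, xb, keep = TRUE)
      # softmax CE gradient on logits
      lg <- fw$logits
      mx <- pmax(lg[, 1], lg[, 2])
      e <- exp(lg - mx)
      probs <- e / rowSums(e)
      delta <- probs
      delta[cbind(seq_along(yb), yb + 1L)] <-
        delta[cbind(seq_along(yb), yb + 1L)] - 1
      delta <- delta / length(yb)
      t_step <- t_step + 1L
      for (l in L:1) {
        cache <- fw$caches[[l]]
        gW <- crossprod(cache$a_in, delta)
        gb <- colSums(delta)
        if (l > 1L) {
          da <- delta %*% t(params[[l]]$W)
          z <- fw$caches[[l - 1L]]$z
          a_out <- selu(z)
          delta <- da * ifelse(z > 0, SELU_LAMBDA,
                               a_out + SELU_LAMBDA * SELU_ALPHA)
        }
        st <- mstate[[l]]
        st$W <- b1 * st$W + (1 - b1) * gW
        st$b <- b1 * st$b + (1 - b1) * gb
        st$W2 <- b2 * st$W2 + (1 - b2) * gW^2
        st$b2 <- b2 * st$b2 + (1 - b2) * gb^2
        mstate[[l]] <- st
        c1 <- 1 - b1^t_step; c2 <- 1 - b2^t_step
        params[[l]]$W <- params[[l]]$W -
          lr * (st$W / c1) / (sqrt(st$W2 / c2) + eps)
        params[[l]]$b <- params[[l]]$b -
          lr * (st$b / c1) / (sqrt(st$b2 / c2) + eps)
      }
    }
    vl <- ce_loss(mlp_forward(params, x_va)$logits, y_va)
    epochs_run <- epoch
    if (vl < best_loss - 1e-6) {
      best_loss <- vl; best_params <- params; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= spec$patience) break
    }
  }
  va_pred <- mlp_predict_labels(best_params, x_va)
  list(params = best_params, val_loss = best_loss,
       val_accuracy = mean(va_pred == y_va), epochs = epochs_run)
}

# argmax over the two scores; exact tie -> noncoding (0)
mlp_predict_labels <- function(params, x) {
  lg <- mlp_forward(params, x)$logits
  as.integer(lg[, 2] > lg[, 1])
}

#' Train the 5-fold model ensemble
#'
#' Splits the balanced sample into five disjoint 20% validation folds; each
#' model trains on the complementary 80% (the published 80/20 split realized
#' as 5-fold cross-validation). Feature standardization statistics (mean/sd
#' per feature) are fitted once on the full sample and shared by all models.
#'
#' @param x Numeric matrix of sensor features (rows = samples).
#' @param y Integer labels in `{0,1}`.
#' @param spec A [model_spec()].
#' @param seed Integer seed controlling fold assignment, weight init and
#'   batch order.
#' @param n_folds Number of folds (default 5).
#' @return An object of class `model_ensemble`: per-fold `models` (weights,
#'   validation loss/accuracy, epochs), `center`/`scale`, `spec`, `seed`.
#' @export
train_ensemble <- function(x, y, spec = model_spec(), seed = 1L, n_folds = 5L) {
  x <- as.matrix(x); y <- as.integer(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  if (spec$standardize) {
    center <- colMeans(x)
    scale <- apply(x, 2L, stats::sd)
    scale[scale == 0] <- 1
  } else {
    center <- numeric(ncol(x)); scale <- rep(1, ncol(x))
  }
  xs <- sweep(sweep(x, 2L, center), 2L, scale, "/")
  n <- nrow(xs)
  fold_of <- withr::with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  models <- lapply(seq_len(n_folds), function(f) {
    va <- which(fold_of == f); tr <- which(fold_of != f)
    mlp_train_model(xs[tr, , drop = FALSE], y[tr],
                    xs[va, , drop = FALSE], y[va],
                    spec, seed = (seed * 131 + f) %% .Machine$integer.max)
  })
  structure(list(models = models, center = center, scale = scale,
                 spec = spec, seed = seed, n_features = ncol(x),
                 feature_names = colnames(x)),
            class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  va <- vapply(x$models, `[[`, numeric(1), "val_accuracy")
  vl <- vapply(x$models, `[[`, numeric(1), "val_loss")
  cat(sprintf(
    "<model_ensemble> %d models (%d->%s->2 SELU); val loss %.4f +/- %.4f, val acc %.4f +/- %.4f\n",
    length(x$models), x$n_features,
    paste(rep(x$spec$neurons, x$spec$hidden_layers), collapse = "->"),
    mean(vl), stats::sd(vl), mean(va), stats::sd(va)))
  invisible(x)
}

#' Initial per-nucleotide predictions from a trained ensemble
#'
#' Applies the stored standardization and classifies each position by the
#' larger of the two output scores (exact ties go to noncoding). `"majority"`
#' returns one consensus-vote track; `"per_model"` returns one track per fold
#' model (published metrics are means across the five models).
#'
#' @param ensemble A `model_ensemble` from [train_ensemble()].
#' @param features A `feature_matrix` from [featurize_track()].
#' @param mode `"majority"` or `"per_model"`.
#' @return A [prediction_track()] (`"majority"`) or list of tracks
#'   (`"per_model"`). Positions outside the valid range are labeled 0.
#' @export
predict_initial <- function(ensemble, features,
                            mode = c("majority", "per_model")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ensemble, "model_ensemble"),
            inherits(features, "feature_matrix"))
  x <- features$values
  if (ncol(x) != ensemble$n_features)
    stop("feature dimension ", ncol(x), " != ", ensemble$n_features)
  xs <- sweep(sweep(x, 2L, ensemble$center), 2L, ensemble$scale, "/")
  per_model <- lapply(ensemble$models, function(m)
    mlp_predict_labels(m$params, xs))
  to_track <- function(lab) {
    full <- integer(features$seq_len)
    full[features$positions] <- lab
    prediction_track(features$seq_id, full, features$window)
  }
  if (mode == "per_model") return(lapply(per_model, to_track))
  votes <- Reduce(`+`, per_model)
  to_track(as.integer(votes * 2L > length(per_model)))
}

#' Save / load a trained ensemble
#'
#' Serializes the architecture spec, weights, standardization statistics and
#' seed to a single RDS archive.
#'
#' @param ensemble A `model_ensemble`.
#' @param path Archive path.
#' @return `path` (save) or the restored `model_ensemble` (load).
#' @export
save_ensemble <- function(ensemble, path) {
  saveRDS(ensemble, path)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  e <- readRDS(path)
  if (!inherits(e, "model_ensemble")) stop(path, " is not a saved ensemble")
  e
}
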