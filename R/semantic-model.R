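# Trainable three-class (background / interior / boundary) pixel segmenter.
#
# The model is a per-pixel multilayer perceptron over multi-scale image
# features (intensity, Gaussian pyramid, gradient magnitude,
# difference-of-Gaussians), trained full-batch with Adam on class-weighted
# cross-entropy. No deep-learning framework is available to R in this
# environment; this proposal-free design keeps the semantic-model contract
# (deterministic prediction, non-increasing loss trend, reproducibility)
# while remaining CPU-friendly.

# multi-scale per-pixel features of one numeric channel
channel_features <- function(m) {
  m <- matrix(as.numeric(m), nrow(m), ncol(m))
  b1 <- gaussian_blur(m, 1)
  b2 <- gaussian_blur(m, 2)
  b4 <- gaussian_blur(m, 4)
  gradmag <- function(x) {
    gx <- x[, c(2:ncol(x), ncol(x))] - x[, c(1, 1:(ncol(x) - 1L))]
    gy <- x[c(2:nrow(x), nrow(x)), ] - x[c(1, 1:(nrow(x) - 1L)), ]
    sqrt(gx^2 + gy^2)
  }
  list(m, b1, b2, b4, gradmag(b1), gradmag(b2), b1 - b2, b2 - b4)
}

# feature matrix (n_pixels x d) for a single- or multi-channel input
pixel_features <- function(channels) {
  if (is.matrix(channels)) channels <- list(channels)
  feats <- unlist(lapply(channels, channel_features), recursive = FALSE)
  do.call(cbind, lapply(feats, as.vector))
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

mlp_init <- function(d, hidden, seed) {
  with_seed(seed, {
    list(W1 = matrix(stats::rnorm(d * hidden, 0, sqrt(2 / d)), d, hidden),
         b1 = rep(0, hidden),
         W2 = matrix(stats::rnorm(hidden * 3L, 0, sqrt(2 / hidden)),
                     hidden, 3L),
         b2 = rep(0, 3L))
  })
}

# one full-batch Adam training run; y in {0,1,2}; returns params + loss log
mlp_train <- function(params, X, y, epochs, lr = 0.01, class_weights = NULL,
                      grad_clip = 5.0, heads_only = FALSE, adam_state = NULL) {
  n <- nrow(X)
  Y <- matrix(0, n, 3L)
  Y[cbind(seq_len(n), y + 1L)] <- 1
  if (is.null(class_weights)) class_weights <- rep(1, 3L)
  wvec <- class_weights[y + 1L]
  wvec <- wvec / mean(wvec)
  st <- if (is.null(adam_state))
    list(t = 0, m = NULL, v = NULL) else adam_state
  loss_log <- numeric(epochs)
  p <- params
  for (ep in seq_len(epochs)) {
    H <- pmax(sweep(X %*% p$W1, 2L, p$b1, "+"), 0)
    P <- softmax_rows(sweep(H %*% p$W2, 2L, p$b2, "+"))
    loss_log[ep] <- -mean(wvec * log(pmax(P[cbind(seq_len(n), y + 1L)],
                                          1e-12)))
    G <- (P - Y) * (wvec / n)
    gW2 <- t(H) %*% G
    gb2 <- colSums(G)
    if (heads_only) {
      grads <- list(W2 = gW2, b2 = gb2)
    } else {
      D <- (G %*% t(p$W2)) * (H > 0)
      grads <- list(W1 = t(X) %*% D, b1 = colSums(D), W2 = gW2, b2 = gb2)
    }
    # global-norm gradient clipping
    gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
    if (is.finite(grad_clip) && gn > grad_clip)
      grads <- lapply(grads, function(g) g * (grad_clip / gn))
    # Adam
    st$t <- st$t + 1
    if (is.null(st$m)) {
      st$m <- lapply(grads, function(g) g * 0)
      st$v <- lapply(grads, function(g) g * 0)
    }
    b1a <- 0.9; b2a <- 0.999; eps <- 1e-8
    for (nm in names(grads)) {
      st$m[[nm]] <- b1a * st$m[[nm]] + (1 - b1a) * grads[[nm]]
      st$v[[nm]] <- b2a * st$v[[nm]] + (1 - b2a) * grads[[nm]]^2
      mhat <- st$m[[nm]] / (1 - b1a^st$t)
      vhat <- st$v[[nm]] / (1 - b2a^st$t)
      p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = p, loss_log = loss_log, adam_state = st)
}

#' Create a trainable three-class semantic segmentation model
#'
#' @param hidden hidden layer width (default 16).
#' @param lr Adam learning rate used by [train_three_class()] (default
#'   0.01).
#' @param grad_clip global gradient-norm clip (default 5).
#' @return an untrained `SemanticModel`.
#' @export
semantic_model <- function(hidden = 16L, lr = 0.01, grad_clip = 5.0) {
  structure(list(hidden = as.integer(hidden), lr = lr,
                 grad_clip = grad_clip, params = NULL,
                 feat_mean = NULL, feat_sd = NULL,
                 class_weights = NULL, loss_log = numeric(0),
                 trained = FALSE),
            class = "SemanticModel")
}

#' @export
print.SemanticModel <- function(x, ...) {
  cat(sprintf("<SemanticModel: hidden %d, %s>\n", x$hidden,
              if (x$trained) sprintf("trained (%d epoch(s), final loss %.4f)",
                                     length(x$loss_log),
                                     utils::tail(x$loss_log, 1))
              else "untrained"))
  invisible(x)
}

model_input_matrix <- function(raster) {
  if (is_raster(raster)) raster$pixels / (2^raster$bit_depth - 1)
  else matrix(as.numeric(raster), nrow(raster), ncol(raster))
}

#' Train a three-class semantic model
#'
#' Full-batch training on per-pixel class-weighted cross-entropy (weights
#' are inverse class frequencies over the pool, so rare boundary pixels are
#' not drowned out). The per-epoch loss is logged on the model; prediction
#' after training is deterministic.
#'
#' @param model a [semantic_model()] (untrained or trained; training always
#'   restarts from a fresh seeded initialization for reproducibility).
#' @param pairs list of `list(raster =, map =)` items: input raster (or
#'   numeric matrix) plus aligned three-class map (codes 0/1/2).
#' @param epochs number of full-batch gradient steps.
#' @param seed integer seed controlling the initialization.
#' @return the trained model (with `loss_log`).
#' @export
train_three_class <- function(model, pairs, epochs = 200L, seed = 1L) {
  if (!length(pairs)) stop("empty training set")
  Xs <- list(); ys <- list()
  for (p in pairs) {
    m <- model_input_matrix(p$raster)
    if (!all(dim(m) == dim(p$map)))
      stop("label map dimensions do not match the raster")
    Xs[[length(Xs) + 1L]] <- pixel_features(m)
    ys[[length(ys) + 1L]] <- as.integer(as.vector(p$map))
  }
  X <- do.call(rbind, Xs)
  y <- unlist(ys)
  model$feat_mean <- colMeans(X)
  # population sd: invariant under duplicating the training pool, which the
  # full-batch gradient-equivalence contract requires
  model$feat_sd <- pmax(sqrt(colMeans(sweep(X, 2L, model$feat_mean)^2)),
                        1e-8)
  X <- sweep(sweep(X, 2L, model$feat_mean), 2L, model$feat_sd, "/")
  freq <- tabulate(y + 1L, nbins = 3L)
  w <- ifelse(freq > 0, sum(freq) / (3 * pmax(freq, 1)), 0)
  model$class_weights <- w
  params <- mlp_init(ncol(X), model$hidden, seed)
  fit <- mlp_train(params, X, y, epochs, lr = model$lr,
                   class_weights = w, grad_clip = model$grad_clip)
  model$params <- fit$params
  model$loss_log <- fit$loss_log
  model$trained <- TRUE
  model
}

#' Predict a three-class map with a trained semantic model
#'
#' @param model a trained [semantic_model()].
#' @param raster input raster or numeric matrix.
#' @return list with `scores` (H x W x 3 probability array, class order
#'   background/interior/boundary) and `map` (argmax three-class matrix;
#'   ties resolved to the lowest class code).
#' @export
predict_three_class <- function(model, raster) {
  if (!isTRUE(model$trained)) stop("model is not trained")
  m <- model_input_matrix(raster)
  X <- pixel_features(m)
  X <- sweep(sweep(X, 2L, model$feat_mean), 2L, model$feat_sd, "/")
  H <- pmax(sweep(X %*% model$params$W1, 2L, model$params$b1, "+"), 0)
  P <- softmax_rows(sweep(H %*% model$params$W2, 2L, model$params$b2, "+"))
  scores <- array(P, dim = c(nrow(m), ncol(m), 3L))
  map <- matrix(max.col(P, ties.method = "first") - 1L, nrow(m), ncol(m))
  list(scores = scores, map = map)
}

#' Serialize a semantic model to a JSON checkpoint
#' @param model a `SemanticModel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_semantic_model <- function(model, path) {
  obj <- list(hidden = model$hidden, lr = model$lr,
              grad_clip = model$grad_clip,
              feat_mean = model$feat_mean, feat_sd = model$feat_sd,
              class_weights = model$class_weights,
              loss_log = model$loss_log, trained = model$trained,
              params = lapply(model$params, function(p)
                if (is.matrix(p)) list(dim = dim(p), data = as.vector(p))
                else list(dim = NULL, data = p)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a semantic model from a JSON checkpoint
#' @param path checkpoint path.
#' @return a `SemanticModel`.
#' @export
read_semantic_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- semantic_model(obj$hidden, obj$lr, obj$grad_clip)
  model$feat_mean <- obj$feat_mean
  model$feat_sd <- obj$feat_sd
  model$class_weights <- obj$class_weights
  model$loss_log <- obj$loss_log
  model$trained <- obj$trained
  model$params <- lapply(obj$params, function(p) {
    if (!is.null(p$dim) && length(p$dim)) matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  model
}
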