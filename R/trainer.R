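# Image classifier with the screening pipeline's training controls: learning
# rate, batch size, a 30-epoch default budget, early stopping on validation
# loss, and checkpoint restoration from the lowest-validation-loss epoch.
#
# There is no deep-learning framework in the package's dependency stack, so
# the two desk-scale architectures (a linear softmax over pixels and a small
# one-block CNN) and their SGD-with-momentum training loop are implemented
# directly in base R matrix code. Exact GoogLeNet-scale fidelity is a
# non-goal; the architecture slot is a registry so alternatives can be added.

#' Hyperparameters for image-classifier training
#'
#' @param learning_rate Positive SGD learning rate (constant; no decay --
#'   early stopping bounds the epoch budget instead).
#' @param batch_size Positive integer mini-batch size.
#' @param max_epochs Maximum number of epochs (default 30).
#' @param patience Early stopping: stop after this many consecutive epochs
#'   without a validation-loss improvement; `0` disables early stopping.
#' @param momentum SGD momentum coefficient.
#' @param class_weights `"balanced"` for inverse-frequency class weights in
#'   the cross-entropy loss (the active class is typically <6% of a screening
#'   library), or `"none"`.
#' @return A list of class `hyperparams`.
#' @export
hyperparams <- function(learning_rate = 1e-3, batch_size = 16L,
                        max_epochs = 30L, patience = 5L, momentum = 0.9,
                        class_weights = c("balanced", "none")) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            patience >= 0, momentum >= 0, momentum < 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 momentum = momentum,
                 class_weights = match.arg(class_weights)),
            class = "hyperparams")
}

#' Bundle images and labels into a training dataset
#'
#' @param x Numeric array `n x h x w x 3` with values in `[0, 1]`.
#' @param y Character or factor labels (`"active"` / `"inactive"`), length
#'   `n`.
#' @param ids Optional per-image molecule ids (for per-molecule aggregation).
#' @return A list of class `image_dataset`.
#' @export
image_dataset <- function(x, y, ids = NULL) {
  stopifnot(length(dim(x)) == 4, dim(x)[4] == 3, dim(x)[1] == length(y))
  y <- as.character(y)
  stopifnot(all(y %in% c("active", "inactive")))
  if (!is.null(ids)) stopifnot(length(ids) == dim(x)[1])
  structure(list(x = x, y = y, ids = ids), class = "image_dataset")
}

#' Load PNG images into an array
#'
#' Reads RGB PNGs and resizes them to `size x size` (block-mean pooling when
#' the source side is an integer multiple of `size`, nearest-neighbor
#' otherwise).
#'
#' @param paths Character vector of PNG paths.
#' @param size Target side length in pixels.
#' @return Numeric array `n x size x size x 3`.
#' @export
load_images <- function(paths, size = 32L) {
  n <- length(paths)
  out <- array(0, c(n, size, size, 3))
  for (i in seq_len(n)) {
    img <- png::readPNG(paths[i])
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    img <- img[, , 1:3, drop = FALSE]
    out[i, , , ] <- resize_image(img, size)
  }
  out
}

resize_image <- function(img, size) {
  h <- dim(img)[1]
  if (h == size) return(img)
  if (h %% size == 0) {
    f <- h %/% size
    out <- array(0, c(size, size, 3))
    for (ch in 1:3) {
      m <- img[, , ch]
      # block mean: average f x f tiles
      m <- matrix(colMeans(matrix(m, f)), h %/% f)     # pool rows
      m <- t(matrix(colMeans(matrix(t(m), f)), size))  # pool cols
      out[, , ch] <- m
    }
    out
  } else {
    idx <- pmin(h, pmax(1, round((seq_len(size) - 0.5) * h / size + 0.5)))
    img[idx, idx, , drop = FALSE]
  }
}

# --- architecture registry ---------------------------------------------------
# Each architecture supplies init(input_size, seed) -> params and
# forward(params, x4d, grad_y = NULL) which returns list(prob, loss terms are
# computed by the caller) and, when grad_y (n x 2 matrix of dLoss/dlogit) is
# given, the parameter gradients.

arch_registry <- new.env(parent = emptyenv())

register_arch <- function(name, init, forward, backward,
                          calibrate = NULL) {
  assign(name, list(init = init, forward = forward, backward = backward,
                    calibrate = calibrate), envir = arch_registry)
}

get_arch <- function(name) {
  if (!exists(name, envir = arch_registry, inherits = FALSE)) {
    stop("unknown architecture '", name, "'; available: ",
         paste(ls(arch_registry), collapse = ", "))
  }
  get(name, envir = arch_registry, inherits = FALSE)
}

#' List registered classifier architectures
#' @return Character vector of architecture names.
#' @export
list_architectures <- function() ls(arch_registry)

# images are stored in [0, 1]; both architectures center them at 0 so the
# background does not bias the first-layer statistics
center_pixels <- function(x) x - 0.5

flatten4d <- function(x) {
  n <- dim(x)[1]
  matrix(x, nrow = n)
}

softmax2 <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# pixelnet: linear softmax over flattened pixels
init_pixelnet <- function(input_size, seed) {
  d <- input_size * input_size * 3
  set.seed(seed)
  list(W = matrix(stats::rnorm(d * 2, sd = sqrt(1 / d)), d, 2),
       b = rep(0, 2))
}

forward_pixelnet <- function(params, x, keep_cache = FALSE) {
  X <- flatten4d(center_pixels(x))
  z <- sweep(X %*% params$W, 2, params$b, `+`)
  list(prob = softmax2(z), cache = if (keep_cache) list(X = X))
}

backward_pixelnet <- function(params, cache, grad_y) {
  list(W = crossprod(cache$X, grad_y), b = colSums(grad_y))
}

# tinycnn: conv 5x5x3 -> 64 filters (stride 2), ReLU, global mean pooling
# per filter, linear softmax head. Global pooling makes the features
# position-invariant color/texture statistics (e.g. "how much blue-next-to-
# red is in the image"), which is the right inductive bias for CPK-colored
# snapshots and keeps the head small enough to fit from a handful of active
# examples. The first eight filters are initialized with deterministic
# color-opponent and luminance kernels (R-G, B-G, ... -- the basis early
# vision layers converge to anyway), so a discriminative color statistic is
# representable from the first SGD step regardless of the random draw; the
# remaining filters start from He noise and everything is refined by
# training. Per-filter scales are calibrated on a training sample before the
# first epoch (LSUV-style) so that pre-activations and pooled features start
# near unit variance, which places learning rates around 1e-3 in the
# effective regime. Implemented with im2col so everything is matrix algebra.
conv_geometry <- function(input_size, k = 5L, stride = 2L) {
  o <- (input_size - k) %/% stride + 1L
  pos <- (seq_len(o) - 1L) * stride + 1L
  # index map: for each of the o*o output positions, the k*k*3 input offsets
  grid <- expand.grid(r = pos, c = pos)
  off <- expand.grid(dr = 0:(k - 1L), dc = 0:(k - 1L), ch = 0:2)
  idx <- matrix(0L, nrow(grid), nrow(off))
  for (j in seq_len(nrow(off))) {
    idx[, j] <- (grid$r + off$dr[j]) +
      (grid$c + off$dc[j] - 1L) * input_size +
      off$ch[j] * input_size * input_size
  }
  list(o = o, k = k, idx = idx)
}

# fixed color-opponent / luminance kernel basis over a k x k window
opponent_kernels <- function(kk) {
  ones <- rep(1, kk)
  zero <- rep(0, kk)
  cbind(c(ones, -ones, zero),    # R-G
        c(-ones, ones, zero),    # G-R
        c(zero, -ones, ones),    # B-G
        c(zero, ones, -ones),    # G-B
        c(ones, zero, -ones),    # R-B
        c(-ones, zero, ones),    # B-R
        c(ones, ones, ones),     # luminance+
        c(-ones, -ones, -ones)) / kk
}

init_tinycnn <- function(input_size, seed, n_filter = 64L) {
  geo <- conv_geometry(input_size)
  set.seed(seed)
  d_in <- geo$k * geo$k * 3
  K <- matrix(stats::rnorm(d_in * n_filter, sd = sqrt(2 / d_in)),
              d_in, n_filter)
  K[, 1:8] <- opponent_kernels(geo$k * geo$k)
  list(K = K,
       bK = rep(0, n_filter),
       W = matrix(stats::rnorm(n_filter * 2, sd = 0.05 / sqrt(n_filter)),
                  n_filter, 2),
       b = rep(0, 2),
       f_mu = rep(0, n_filter), f_sd = rep(1, n_filter),
       geo = geo)
}

# pre-training calibration on a sample of training images: rescale each
# filter to unit pre-activation variance, center it, and standardize the
# pooled features; deterministic given the data
calibrate_tinycnn <- function(params, x) {
  geo <- params$geo
  npos <- nrow(geo$idx)
  n <- min(64L, dim(x)[1])
  Ms <- lapply(seq_len(n), function(i) {
    v <- as.numeric(center_pixels(x[i, , , ]))
    matrix(v[geo$idx], npos)
  })
  # the SD floors bound the gain for filters that are nearly silent on the
  # calibration sample (e.g. a color-opponent kernel when the sampled images
  # barely contain that color): without them a near-zero variance blows the
  # filter scale up by orders of magnitude and saturates the head
  A <- do.call(rbind, lapply(Ms, function(M) M %*% params$K))
  params$K <- sweep(params$K, 2, pmax(apply(A, 2, stats::sd), 0.02), "/")
  A <- do.call(rbind, lapply(Ms, function(M) M %*% params$K))
  params$bK <- -colMeans(A)
  pooled <- t(vapply(Ms, function(M) {
    A <- sweep(M %*% params$K, 2, params$bK, `+`)
    colMeans(A * (A > 0))
  }, numeric(ncol(params$K))))
  params$f_mu <- colMeans(pooled)
  params$f_sd <- pmax(apply(pooled, 2, stats::sd), 0.02)
  params
}

forward_tinycnn <- function(params, x, keep_cache = FALSE) {
  geo <- params$geo
  n <- dim(x)[1]
  nf <- ncol(params$K)
  npos <- nrow(geo$idx)
  feats <- matrix(0, n, nf)
  caches <- if (keep_cache) vector("list", n) else NULL
  for (i in seq_len(n)) {
    v <- as.numeric(center_pixels(x[i, , , ]))
    M <- matrix(v[geo$idx], npos)                  # (o*o) x (k*k*3)
    A <- sweep(M %*% params$K, 2, params$bK, `+`)  # (o*o) x nf
    relu_mask <- A > 0
    # global mean pool, then the calibrated standardization
    feats[i, ] <- (colMeans(A * relu_mask) - params$f_mu) / params$f_sd
    if (keep_cache) caches[[i]] <- list(M = M, mask = relu_mask)
  }
  z <- sweep(feats %*% params$W, 2, params$b, `+`)
  list(prob = softmax2(z),
       cache = if (keep_cache) list(per_image = caches, feats = feats,
                                    npos = npos))
}

backward_tinycnn <- function(params, cache, grad_y) {
  npos <- cache$npos
  dfeat <- sweep(grad_y %*% t(params$W), 2, params$f_sd, "/")  # n x nf
  dK <- matrix(0, nrow(params$K), ncol(params$K))
  dbK <- rep(0, ncol(params$K))
  for (i in seq_len(nrow(grad_y))) {
    # global mean pool spreads the gradient uniformly over positions
    dA <- matrix(dfeat[i, ] / npos, npos, length(dfeat[i, ]),
                 byrow = TRUE) * cache$per_image[[i]]$mask
    dK <- dK + crossprod(cache$per_image[[i]]$M, dA)
    dbK <- dbK + colSums(dA)
  }
  list(K = dK, bK = dbK,
       W = crossprod(cache$feats, grad_y), b = colSums(grad_y))
}

register_arch("pixelnet", init_pixelnet, forward_pixelnet,
              backward_pixelnet)
register_arch("tinycnn", init_tinycnn, forward_tinycnn, backward_tinycnn,
              calibrate_tinycnn)

#' Initialize an untrained classifier
#'
#' @param arch Architecture name (see [list_architectures()]).
#' @param input_size Image side length the model expects.
#' @param seed Integer seed for weight initialization.
#' @return A `snap_model` object.
#' @export
new_model <- function(arch = "tinycnn", input_size = 32L, seed = 1L) {
  a <- get_arch(arch)
  structure(list(arch = arch, input_size = as.integer(input_size),
                 params = a$init(input_size, seed),
                 classes = c("inactive", "active"),
                 selected_epoch = NA_integer_),
            class = "snap_model")
}

#' @export
print.snap_model <- function(x, ...) {
  cat("<snap_model> arch=", x$arch, ", input ", x$input_size, "x",
      x$input_size, "x3", sep = "")
  if (!is.na(x$selected_epoch)) {
    cat(", checkpoint from epoch ", x$selected_epoch, sep = "")
  }
  cat("\n")
  invisible(x)
}

# weighted mean cross-entropy of P(active) against labels
weighted_ce <- function(p_active, y, w) {
  p <- pmin(1 - 1e-12, pmax(1e-12, p_active))
  ll <- ifelse(y == "active", log(p), log(1 - p))
  -sum(w * ll) / sum(w)
}

#' Train an image classifier
#'
#' Stochastic gradient descent with momentum on mean cross-entropy, for at
#' most `max_epochs` epochs. After every epoch the full training and
#' validation losses are recorded; training stops early once the validation
#' loss has failed to improve for `patience` consecutive epochs
#' (`patience = 0` disables early stopping), and the returned model's weights
#' are restored from the epoch with the lowest validation loss. A fixed seed
#' reproduces the whole history exactly.
#'
#' @param train,valid [image_dataset()] objects; both must contain both
#'   classes.
#' @param hp A [hyperparams()] object.
#' @param arch Architecture name (see [list_architectures()]).
#' @param seed Integer seed controlling weight initialization and batch
#'   shuffling.
#' @return List of class `train_result` with elements `model` (a
#'   `snap_model`), `history` (`data.frame` of `epoch`, `loss_train`,
#'   `loss_valid`) and `selected_epoch` (1-based arg-min of `loss_valid`).
#' @export
train <- function(train, valid, hp = hyperparams(), arch = "tinycnn",
                  seed = 1L) {
  stopifnot(inherits(train, "image_dataset"), inherits(valid, "image_dataset"),
            inherits(hp, "hyperparams"))
  if (length(unique(train$y)) < 2) {
    stop("training partition contains a single class")
  }
  if (length(unique(valid$y)) < 2) {
    stop("validation partition contains a single class")
  }
  a <- get_arch(arch)
  input_size <- dim(train$x)[2]
  n <- dim(train$x)[1]

  w_class <- if (hp$class_weights == "balanced") {
    tab <- table(factor(train$y, levels = c("inactive", "active")))
    n / (2 * as.numeric(tab))
  } else {
    c(1, 1)
  }
  names(w_class) <- c("inactive", "active")
  w_train <- unname(w_class[train$y])
  y_onehot <- cbind(inactive = as.numeric(train$y == "inactive"),
                    active = as.numeric(train$y == "active"))

  params <- a$init(input_size, seed)
  if (!is.null(a$calibrate)) params <- a$calibrate(params, train$x)
  learnable <- setdiff(names(params), c("geo", "f_mu", "f_sd"))
  velocity <- lapply(params[learnable], function(p) p * 0)

  history <- data.frame(epoch = integer(0), loss_train = numeric(0),
                        loss_valid = numeric(0))
  best <- list(loss = Inf, params = params, epoch = NA_integer_)
  since_best <- 0L

  for (epoch in seq_len(hp$max_epochs)) {
    set.seed(seed + 1000L * epoch)  # per-epoch shuffle, reproducible
    ord <- sample(n)
    for (start in seq(1, n, by = hp$batch_size)) {
      bi <- ord[start:min(start + hp$batch_size - 1, n)]
      xb <- train$x[bi, , , , drop = FALSE]
      wb <- w_train[bi]
      fwd <- a$forward(params, xb, keep_cache = TRUE)
      # dL/dlogits for weighted softmax CE, normalized by batch weight
      gy <- (fwd$prob - y_onehot[bi, , drop = FALSE]) * wb / sum(wb)
      grads <- a$backward(params, fwd$cache, gy)
      for (nm in learnable) {
        velocity[[nm]] <- hp$momentum * velocity[[nm]] -
          hp$learning_rate * grads[[nm]]
        params[[nm]] <- params[[nm]] + velocity[[nm]]
      }
    }
    # the recorded history is plain mean cross-entropy: class weights shape
    # the optimization objective, while checkpoint selection and early
    # stopping monitor the unweighted validation loss
    p_tr <- a$forward(params, train$x)$prob[, 2]
    p_va <- a$forward(params, valid$x)$prob[, 2]
    l_tr <- weighted_ce(p_tr, train$y, rep(1, length(train$y)))
    l_va <- weighted_ce(p_va, valid$y, rep(1, length(valid$y)))
    history <- rbind(history, data.frame(epoch = epoch, loss_train = l_tr,
                                         loss_valid = l_va))
    if (l_va < best$loss) {
      best <- list(loss = l_va, params = params, epoch = epoch)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
    }
    if (hp$patience > 0 && since_best >= hp$patience) break
  }

  model <- structure(list(arch = arch, input_size = input_size,
                          params = best$params,
                          classes = c("inactive", "active"),
                          selected_epoch = best$epoch, hp = hp, seed = seed),
                     class = "snap_model")
  structure(list(model = model, history = history,
                 selected_epoch = best$epoch),
            class = "train_result")
}

#' Predict the active-class probability of images
#'
#' Deterministic at inference: the same model and images always give the same
#' probabilities.
#'
#' @param object A `snap_model`.
#' @param x Numeric array `n x h x w x 3`, or an [image_dataset()]; `h`/`w`
#'   must match the model's input size.
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]`, one per image.
#' @export
predict.snap_model <- function(object, x, ...) {
  if (inherits(x, "image_dataset")) x <- x$x
  stopifnot(length(dim(x)) == 4)
  if (dim(x)[2] != object$input_size || dim(x)[3] != object$input_size) {
    stop("image size ", dim(x)[2], "x", dim(x)[3],
         " does not match model input ", object$input_size)
  }
  a <- get_arch(object$arch)
  a$forward(object$params, x)$prob[, 2]
}
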