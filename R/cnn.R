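#' Convolutional architecture for the tubule patch classifier
#'
#' The classifier is a stack of conv/ReLU/max-pool blocks followed by two
#' fully connected layers ending in a 2-way softmax that emits the tubule
#' class-membership probability. Convolutions are valid (no padding),
#' stride 1; pooling is non-overlapping with trailing rows/columns dropped.
#'
#' The default -- three blocks with 6/12/24 filters of size 3 x 3, pool 2,
#' then a 32-unit hidden layer -- is sized to train in seconds on a single
#' CPU while easily separating tubule from non-tubule nuclei; every
#' dimension is configurable.
#'
#' @param conv_blocks list of `(n_filters, kernel_size, pool_size)`
#'   triplets, at least one.
#' @param fc_widths widths of the two fully connected layers; the last must
#'   be 2 (the two class logits).
#' @param input_size input patch side length; the classifier operates on
#'   64 x 64 patches.
#' @param in_channels input channels (3 for RGB).
#' @return a list of class `cnn_architecture`.
#' @export
cnn_architecture <- function(conv_blocks = list(c(6, 3, 2), c(12, 3, 2),
                                                c(24, 3, 2)),
                             fc_widths = c(32, 2),
                             input_size = 64, in_channels = 3) {
  if (length(conv_blocks) < 1) abort("at least one conv block is required")
  for (b in conv_blocks) {
    if (length(b) != 3 || any(b < 1)) {
      abort("each conv block must be (n_filters, kernel_size, pool_size)")
    }
  }
  if (length(fc_widths) != 2 || fc_widths[2] != 2) {
    abort("`fc_widths` must be two widths ending in 2 output units")
  }
  arch <- structure(
    list(conv_blocks = lapply(conv_blocks, as.integer),
         fc_widths = as.integer(fc_widths),
         input_size = as.integer(input_size),
         in_channels = as.integer(in_channels)),
    class = "cnn_architecture"
  )
  arch_dims(arch)  # errors if a feature map collapses
  arch
}

# spatial size and channel count after each block, plus the flat length
arch_dims <- function(arch) {
  s <- arch$input_size
  ch <- arch$in_channels
  sizes <- list()
  for (b in arch$conv_blocks) {
    conv <- s - b[2] + 1
    if (conv < b[3]) abort("feature map collapses: check kernel/pool sizes")
    s <- conv %/% b[3]
    ch <- b[1]
    sizes[[length(sizes) + 1]] <- c(size = s, channels = ch)
  }
  list(blocks = sizes, flat = s * s * ch)
}

conv_matrix <- function(arch) {
  do.call(rbind, arch$conv_blocks)
}

#' Number of trainable parameters
#'
#' @param x a `cnn_architecture` or `tubule_classifier`.
#' @return integer parameter count (weights plus biases).
#' @export
n_parameters <- function(x) {
  arch <- if (inherits(x, "tubule_classifier")) x$architecture else x
  dims <- arch_dims(arch)
  ch <- arch$in_channels
  total <- 0
  for (i in seq_along(arch$conv_blocks)) {
    b <- arch$conv_blocks[[i]]
    total <- total + b[2]^2 * ch * b[1] + b[1]
    ch <- b[1]
  }
  total <- total + dims$flat * arch$fc_widths[1] + arch$fc_widths[1]
  total <- total + arch$fc_widths[1] * arch$fc_widths[2] + arch$fc_widths[2]
  as.integer(total)
}

#' Build an (untrained) tubule patch classifier
#'
#' Initialises weights with He-scaled Gaussians (sd `sqrt(2 / fan_in)`),
#' biases at zero; identical seeds give identical weights. A forward pass
#' on `n` patches yields `n` probability pairs each summing to one.
#'
#' @param arch a [cnn_architecture()]; the input size must be 64.
#' @param seed integer seed for weight initialisation.
#' @return an object of class `tubule_classifier`.
#' @export
build_model <- function(arch = cnn_architecture(), seed = 1L) {
  if (!inherits(arch, "cnn_architecture")) abort("`arch` must be a cnn_architecture")
  if (arch$input_size != 64) abort("the patch classifier requires 64 x 64 inputs")
  withr::local_seed(seed)
  weights <- init_weights(arch)
  structure(
    list(architecture = arch, weights = weights, decision_threshold = 0.5,
         trained = FALSE, history = NULL),
    class = "tubule_classifier"
  )
}

init_weights <- function(arch) {
  weights <- list()
  ch <- arch$in_channels
  for (b in arch$conv_blocks) {
    fan_in <- b[2]^2 * ch
    weights[[length(weights) + 1]] <-
      matrix(rnorm(fan_in * b[1], 0, sqrt(2 / fan_in)), fan_in, b[1])
    weights[[length(weights) + 1]] <- rep(0, b[1])
    ch <- b[1]
  }
  flat <- arch_dims(arch)$flat
  h <- arch$fc_widths[1]
  weights[[length(weights) + 1]] <- matrix(rnorm(flat * h, 0, sqrt(2 / flat)), flat, h)
  weights[[length(weights) + 1]] <- rep(0, h)
  weights[[length(weights) + 1]] <- matrix(rnorm(h * 2, 0, sqrt(2 / h)), h, 2)
  weights[[length(weights) + 1]] <- rep(0, 2)
  weights
}

#' @export
print.tubule_classifier <- function(x, ...) {
  blocks <- vapply(x$architecture$conv_blocks,
                   function(b) sprintf("%dx%dx%d/pool%d", b[2], b[2], b[1], b[3]),
                   "")
  cat(sprintf("<tubule_classifier> %s -> fc(%s), %d parameters, %s\n",
              paste(blocks, collapse = " -> "),
              paste(x$architecture$fc_widths, collapse = ", "),
              n_parameters(x),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Training configuration
#'
#' Hyper-parameters of the patch classifier fit. Defaults (Adam, learning
#' rate 1e-3, batch 32, 3 epochs, minority oversampling, lossless flip
#' augmentation, at most 1500 training patches) are modest CPU-scale
#' settings; the task the synthetic generator poses is nearly separable so
#' short training suffices.
#'
#' @param epochs,batch_size,learning_rate optimiser settings.
#' @param optimizer_name `"adam"` or `"sgd"`.
#' @param class_balance one of `"oversample_minority"` (each epoch presents
#'   equal class counts by resampling the minority class), `"class_weights"`
#'   (inverse-frequency loss weights) or `"none"`.
#' @param augmentation subset of `"flip_h"`, `"flip_v"`, `"rot90"`; label
#'   semantics are invariant under these.
#' @param max_train_patches optional cap on the number of training patches
#'   (a uniform subsample is taken before balancing); `Inf` to use all.
#' @param seed integer seed covering subsampling, balancing, shuffling and
#'   augmentation draws.
#' @return a list of class `train_config`.
#' @export
train_config <- function(epochs = 3, batch_size = 32, learning_rate = 1e-3,
                         optimizer_name = c("adam", "sgd"),
                         class_balance = c("oversample_minority",
                                           "class_weights", "none"),
                         augmentation = c("flip_h", "flip_v"),
                         max_train_patches = 1500,
                         seed = 1L) {
  if (epochs < 1 || batch_size < 1 || learning_rate <= 0) {
    abort("epochs, batch_size and learning_rate must be positive")
  }
  optimizer_name <- match.arg(optimizer_name)
  class_balance <- match.arg(class_balance)
  bad <- setdiff(augmentation, c("flip_h", "flip_v", "rot90"))
  if (length(bad)) abort(sprintf("unknown augmentation: %s", bad[1]))
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, optimizer_name = optimizer_name,
         class_balance = class_balance, augmentation = augmentation,
         max_train_patches = max_train_patches, seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Train the tubule patch classifier
#'
#' Minimises the mean cross-entropy by mini-batch backpropagation. All
#' stochastic steps (subsampling, oversampling, shuffling, augmentation)
#' are driven by `cfg$seed`, so a fixed seed and data give identical final
#' weights on one device.
#'
#' @param model a [build_model()] result.
#' @param patches `n x 64 x 64 x 3` array, values in `[0, 255]`.
#' @param labels character vector (`"tubule"` / `"non_tubule"`), length n;
#'   both classes must be present.
#' @param cfg a [train_config()].
#' @return the trained `tubule_classifier`, with a `history` tibble
#'   (`epoch`, `loss`) recording the mean per-epoch training loss.
#' @export
train_classifier <- function(model, patches, labels, cfg = train_config()) {
  stopifnot(inherits(model, "tubule_classifier"))
  y <- label_to_int(labels)
  if (length(unique(y)) < 2) {
    abort("training set must contain both classes",
          class = "tubulequant_single_class")
  }
  if (dim(patches)[1] != length(y)) abort("patches and labels differ in length")
  withr::local_seed(cfg$seed)

  n <- length(y)
  if (is.finite(cfg$max_train_patches) && n > cfg$max_train_patches) {
    keep <- sample.int(n, cfg$max_train_patches)
    patches <- patches[keep, , , , drop = FALSE]
    y <- y[keep]
    if (length(unique(y)) < 2) {
      abort("training subsample lost one class; raise `max_train_patches`")
    }
    n <- length(y)
  }

  arch <- model$architecture
  conv <- conv_matrix(arch)
  fc <- arch$fc_widths
  wts <- model$weights
  opt <- optimizer_state(wts)

  sample_weights <- rep(1, n)
  if (cfg$class_balance == "class_weights") {
    tab <- table(y)
    sample_weights <- (n / (2 * tab))[as.character(y)]
  }

  history <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    idx <- if (cfg$class_balance == "oversample_minority") {
      balance_indices(y)
    } else {
      seq_len(n)
    }
    idx <- sample(idx)
    losses <- numeric(0)
    for (start in seq(1, length(idx), by = cfg$batch_size)) {
      bi <- idx[start:min(start + cfg$batch_size - 1, length(idx))]
      xb <- patches[bi, , , , drop = FALSE]
      xb <- augment_batch(xb, cfg$augmentation)
      lg <- cpp_cnn_loss_grad(xb, y[bi], wts, conv, fc,
                              w = sample_weights[bi], scale = 255)
      opt <- optimizer_step(opt, lg$grads, cfg)
      wts <- purrr::map2(wts, opt$update, `-`)
      losses <- c(losses, lg$loss)
    }
    history[epoch] <- mean(losses)
  }

  model$weights <- wts
  model$trained <- TRUE
  model$history <- tibble(epoch = seq_len(cfg$epochs), loss = history)
  model$train_config <- cfg
  model
}

# epoch index set with the minority class resampled up to the majority size
balance_indices <- function(y) {
  pos <- which(y == 1L)
  neg <- which(y == 0L)
  if (length(pos) < length(neg)) {
    c(neg, sample(pos, length(neg), replace = TRUE))
  } else if (length(neg) < length(pos)) {
    c(pos, sample(neg, length(pos), replace = TRUE))
  } else {
    seq_along(y)
  }
}

label_to_int <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  lab <- as.character(labels)
  bad <- setdiff(unique(lab), c("tubule", "non_tubule"))
  if (length(bad)) abort(sprintf("unknown label '%s'", bad[1]))
  as.integer(lab == "tubule")
}

optimizer_state <- function(weights) {
  zeros <- purrr::map(weights, ~ .x * 0)
  list(m = zeros, v = zeros, t = 0, update = zeros)
}

optimizer_step <- function(opt, grads, cfg) {
  lr <- cfg$learning_rate
  if (cfg$optimizer_name == "sgd") {
    opt$update <- purrr::map(grads, ~ lr * .x)
    return(opt)
  }
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  opt$t <- opt$t + 1
  opt$m <- purrr::map2(opt$m, grads, ~ b1 * .x + (1 - b1) * .y)
  opt$v <- purrr::map2(opt$v, grads, ~ b2 * .x + (1 - b2) * .y^2)
  mh <- purrr::map(opt$m, ~ .x / (1 - b1^opt$t))
  vh <- purrr::map(opt$v, ~ .x / (1 - b2^opt$t))
  opt$update <- purrr::map2(mh, vh, ~ lr * .x / (sqrt(.y) + eps))
  opt
}

# lossless geometric augmentation, drawn per sample
augment_batch <- function(x, augmentation) {
  if (length(augmentation) == 0) return(x)
  n <- dim(x)[1]
  if ("flip_h" %in% augmentation) {
    sel <- runif(n) < 0.5
    if (any(sel)) x[sel, , , ] <- x[sel, , 64:1, , drop = FALSE]
  }
  if ("flip_v" %in% augmentation) {
    sel <- runif(n) < 0.5
    if (any(sel)) x[sel, , , ] <- x[sel, 64:1, , , drop = FALSE]
  }
  if ("rot90" %in% augmentation) {
    sel <- runif(n) < 0.5
    if (any(sel)) {
      rotated <- aperm(x[sel, , , , drop = FALSE], c(1, 3, 2, 4))
      x[sel, , , ] <- rotated[, 64:1, , , drop = FALSE]
    }
  }
  x
}

#' Tubule-membership probabilities for patches
#'
#' One probability per patch, in input order; batching does not affect the
#' per-patch result.
#'
#' @param model a `tubule_classifier` (trained or not).
#' @param patches `n x 64 x 64 x 3` array (or a single `64 x 64 x 3`
#'   patch), values in `[0, 255]`.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_tubule_prob <- function(model, patches) {
  stopifnot(inherits(model, "tubule_classifier"))
  d <- dim(patches)
  if (length(d) == 3) {
    dim(patches) <- c(1, d)
    d <- dim(patches)
  }
  if (length(d) != 4 || d[2] != 64 || d[3] != 64 || d[4] != 3) {
    abort("patches must be n x 64 x 64 x 3")
  }
  probs <- cpp_cnn_forward(patches, model$weights,
                           conv_matrix(model$architecture),
                           model$architecture$fc_widths, scale = 255)
  probs[, 2]
}

#' Threshold a tubule probability into a class label
#'
#' A patch is assigned to the tubule class iff its probability strictly
#' exceeds the threshold (a probability of exactly 0.5 at the default
#' threshold is non-tubule).
#'
#' @param prob numeric vector of probabilities in `[0, 1]`.
#' @param threshold decision threshold (default 0.5).
#' @return character vector of `"tubule"` / `"non_tubule"`.
#' @export
classify_tubule <- function(prob, threshold = 0.5) {
  if (any(!is.finite(prob)) || any(prob < 0) || any(prob > 1)) {
    abort("probabilities must lie in [0, 1]")
  }
  ifelse(prob > threshold, "tubule", "non_tubule")
}

#' @export
glance.tubule_classifier <- function(x, ...) {
  tibble(
    n_parameters = n_parameters(x),
    n_conv_blocks = length(x$architecture$conv_blocks),
    trained = x$trained,
    epochs = if (is.null(x$history)) 0L else nrow(x$history),
    final_loss = if (is.null(x$history)) NA_real_ else
      x$history$loss[nrow(x$history)],
    decision_threshold = x$decision_threshold
  )
}

#' Serialise / restore a classifier as a self-describing JSON checkpoint
#'
#' The checkpoint embeds the architecture, the decision threshold and all
#' weights as plain JSON, so it is portable text.
#'
#' @param model a `tubule_classifier`.
#' @param path file path.
#' @return `write_classifier()` returns `path` invisibly;
#'   `read_classifier()` returns the restored `tubule_classifier`.
#' @export
write_classifier <- function(model, path) {
  arch <- model$architecture
  payload <- list(
    architecture = list(conv_blocks = arch$conv_blocks,
                        fc_widths = arch$fc_widths,
                        input_size = arch$input_size,
                        in_channels = arch$in_channels),
    decision_threshold = model$decision_threshold,
    trained = model$trained,
    weights = lapply(model$weights, function(w) {
      if (is.matrix(w)) list(dim = dim(w), data = as.numeric(w))
      else list(dim = length(w), data = as.numeric(w))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  arch <- cnn_architecture(
    conv_blocks = lapply(p$architecture$conv_blocks, unlist),
    fc_widths = unlist(p$architecture$fc_widths),
    input_size = p$architecture$input_size,
    in_channels = p$architecture$in_channels)
  weights <- lapply(p$weights, function(w) {
    d <- unlist(w$dim)
    data <- as.numeric(unlist(w$data))
    if (length(d) == 2) matrix(data, d[1], d[2]) else data
  })
  structure(
    list(architecture = arch, weights = weights,
         decision_threshold = p$decision_threshold,
         trained = isTRUE(p$trained), history = NULL),
    class = "tubule_classifier"
  )
}
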