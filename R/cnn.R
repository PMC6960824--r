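#' Classifier configuration
#'
#' Hyperparameters for the fall/not-fall convolutional network. Two modes
#' exist. `"compact"` (default) is a small CNN trained from scratch: a fixed
#' bilinear downsampling stem from the 227 x 227 x 3 scalogram image to
#' `stem_size` x `stem_size` x 3, four 3x3 conv + ReLU + 2x2 max-pool
#' blocks, one dense ReLU layer and a 2-node softmax head. It trains on a
#' single CPU in minutes. `"transfer_alexnet"` reproduces the
#' transfer-learning adaptation of AlexNet (backbone kept, final fully
#' connected layer replaced by a 2-node layer feeding a softmax over the
#' classes 'fall' and 'not fall'); it requires a pretrained weights file and
#' errors with a pointer to the compact mode when none is available, since
#' no pretrained weights ship with the package.
#'
#' @param mode `"compact"` or `"transfer_alexnet"`.
#' @param epochs Maximum training epochs.
#' @param learning_rate SGD learning rate.
#' @param momentum SGD momentum.
#' @param batch_size Mini-batch size.
#' @param filters Four conv-block filter counts (compact mode).
#' @param dense_units Width of the dense layer before the softmax head.
#' @param stem_size Side of the internal downsampled input (must be divisible
#'   by 16; default 32).
#' @param patience,min_delta Early stopping: training stops after `patience`
#'   consecutive epochs without the epoch loss improving by `min_delta`.
#' @param weights_path Path to pretrained AlexNet weights (transfer mode).
#' @param seed Integer seed governing weight initialization and batch order.
#' @return Object of class `fall_cnn_config`.
#' @export
fall_cnn_config <- function(mode = c("compact", "transfer_alexnet"),
                            epochs = 20,
                            learning_rate = 0.01,
                            momentum = 0.9,
                            batch_size = 16,
                            filters = c(8, 16, 32, 32),
                            dense_units = 32,
                            stem_size = 32,
                            patience = 5,
                            min_delta = 1e-4,
                            weights_path = NULL,
                            seed = 1) {
  mode <- match.arg(mode)
  stopifnot(
    epochs >= 1, learning_rate > 0, batch_size >= 1,
    length(filters) == 4, all(filters >= 1), dense_units >= 1,
    stem_size %% 16 == 0, stem_size >= 16
  )
  structure(
    list(
      mode = mode, n_classes = 2L, input_shape = c(227L, 227L, 3L),
      epochs = as.integer(epochs), learning_rate = learning_rate,
      momentum = momentum, batch_size = as.integer(batch_size),
      filters = as.integer(filters), dense_units = as.integer(dense_units),
      stem_size = as.integer(stem_size), patience = as.integer(patience),
      min_delta = min_delta, weights_path = weights_path,
      seed = as.integer(seed)
    ),
    class = "fall_cnn_config"
  )
}

# Class order fixed by the manifest schema: index 0 = not_fall, 1 = fall.
.CNN_CLASSES <- c("not_fall", "fall")

# ---- layer geometry ---------------------------------------------------------

# Precompute gather indices for a 3x3 same-padding convolution and a 2x2
# max pool on an H x H grid (column-major linear indices).
conv_geometry <- function(H) {
  P <- H + 2L
  rs <- rep(seq_len(H), H)
  cs <- rep(seq_len(H), each = H)
  interior <- (rs + 1L) + cs * P # position of cell (r, c) in the padded grid
  idx <- matrix(0L, nrow = H * H, ncol = 9L)
  j <- 0L
  for (dc in -1:1) {
    for (dr in -1:1) {
      j <- j + 1L
      idx[, j] <- (rs + 1L + dr) + (cs + dc) * P
    }
  }
  Hh <- H %/% 2L
  pr <- rep(seq_len(Hh), Hh)
  pc <- rep(seq_len(Hh), each = Hh)
  pool <- list(
    (2L * pr - 1L) + (2L * pc - 2L) * H,
    (2L * pr) + (2L * pc - 2L) * H,
    (2L * pr - 1L) + (2L * pc - 1L) * H,
    (2L * pr) + (2L * pc - 1L) * H
  )
  list(H = H, P = P, interior = interior, idx = idx, pool = pool)
}

#' Build an untrained classifier
#'
#' Initializes network weights (He-normal, seeded) for the given
#' configuration without training. Mostly useful for inspecting the
#' architecture and for testing; [fall_cnn()] calls this internally.
#'
#' @param config A [fall_cnn_config()].
#' @return Untrained object of class `fall_cnn`.
#' @export
fall_cnn_init <- function(config = fall_cnn_config()) {
  stopifnot(inherits(config, "fall_cnn_config"))
  if (config$mode == "transfer_alexnet") {
    wp <- config$weights_path
    if (is.null(wp) || !file.exists(wp)) {
      stop(
        "transfer_alexnet mode requires a pretrained AlexNet weights file ",
        "(weights_path), and none is available; use mode = 'compact', ",
        "which trains from scratch"
      )
    }
    stop("loading external AlexNet weights is not implemented in this build")
  }
  set.seed(config$seed)
  S <- config$stem_size
  f <- config$filters
  sizes <- c(S, S / 2L, S / 4L, S / 8L)
  chans <- c(3L, f[1:3])
  he <- function(nr, nc) {
    matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
  }
  conv <- lapply(1:4, function(l) {
    list(W = he(9L * chans[l], f[l]), b = numeric(f[l]))
  })
  flat_n <- (S / 16L)^2 * f[4]
  net <- list(
    config = config,
    classes = .CNN_CLASSES,
    conv = conv,
    fc1 = list(W = he(flat_n, config$dense_units), b = numeric(config$dense_units)),
    fc2 = list(W = he(config$dense_units, 2L), b = numeric(2L)),
    geom = lapply(sizes, conv_geometry),
    trained = FALSE,
    history = NULL
  )
  class(net) <- "fall_cnn"
  net
}

# ---- stem -------------------------------------------------------------------

#' Downsample a scalogram image to the network's internal resolution
#'
#' The compact network's fixed stem: bilinear reduction of the
#' 227 x 227 x 3 image to `stem_size` x `stem_size` x 3 and centring to
#' `[-0.5, 0.5]`. Exposed so batch pipelines can cache stem outputs instead
#' of full-size images.
#'
#' @param image A `scalogram_image` or numeric `227 x 227 x 3` array.
#' @param stem_size Output side length (default 32).
#' @return Numeric array `stem_size x stem_size x 3` with attribute
#'   `stemmed = TRUE`.
#' @export
image_stem <- function(image, stem_size = 32) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3 || d[3] != 3) {
    stop(
      "image shape (", paste(d, collapse = ", "),
      ") does not match expected (227, 227, 3)"
    )
  }
  if (isTRUE(attr(image, "stemmed")) && d[1] == stem_size) {
    return(image)
  }
  out <- array(0, dim = c(stem_size, stem_size, 3))
  for (ch in 1:3) {
    out[, , ch] <- resize_bilinear(unclass(image)[, , ch], stem_size, stem_size)
  }
  out <- out - 0.5
  attr(out, "stemmed") <- TRUE
  attr(out, "record_id") <- attr(image, "record_id")
  out
}

prepare_stem <- function(image, config) {
  d <- dim(image)
  S <- config$stem_size
  if (is.null(d) || length(d) != 3 || d[3] != 3) {
    stop(
      "image shape (", paste(d, collapse = ", "),
      ") does not match expected (",
      paste(config$input_shape, collapse = ", "), ")"
    )
  }
  if (isTRUE(attr(image, "stemmed"))) {
    if (d[1] != S || d[2] != S) {
      stop(
        "stemmed input shape (", paste(d, collapse = ", "),
        ") does not match expected (", S, ", ", S, ", 3)"
      )
    }
    return(image)
  }
  if (d[1] != 227 || d[2] != 227) {
    stop(
      "image shape (", paste(d, collapse = ", "),
      ") does not match expected (",
      paste(config$input_shape, collapse = ", "), ")"
    )
  }
  image_stem(image, S)
}

# ---- forward / backward -----------------------------------------------------

# x: S x S x 3 stem array. Returns list(probs, cache).
cnn_forward <- function(net, x, keep = FALSE) {
  A <- matrix(as.numeric(x), ncol = 3) # H^2 x C, column-major positions
  cache <- if (keep) list(layers = vector("list", 4)) else NULL
  for (l in 1:4) {
    g <- net$geom[[l]]
    C <- ncol(A)
    padded <- matrix(0, g$P * g$P, C)
    padded[g$interior, ] <- A
    cols <- matrix(0, g$H * g$H, 9L * C)
    for (j in 1:9) {
      cols[, ((j - 1L) * C + 1L):(j * C)] <- padded[g$idx[, j], , drop = FALSE]
    }
    z <- cols %*% net$conv[[l]]$W
    z <- sweep(z, 2, net$conv[[l]]$b, `+`)
    a <- z * (z > 0)
    p1 <- a[g$pool[[1]], , drop = FALSE]
    p2 <- a[g$pool[[2]], , drop = FALSE]
    p3 <- a[g$pool[[3]], , drop = FALSE]
    p4 <- a[g$pool[[4]], , drop = FALSE]
    pooled <- pmax(p1, p2, p3, p4)
    if (keep) {
      cache$layers[[l]] <- list(
        cols = cols, relu = z > 0,
        masks = list(p1 == pooled, p2 == pooled, p3 == pooled, p4 == pooled)
      )
    }
    A <- pooled
  }
  flat <- as.numeric(A)
  h_pre <- drop(flat %*% net$fc1$W) + net$fc1$b
  h <- h_pre * (h_pre > 0)
  logits <- drop(h %*% net$fc2$W) + net$fc2$b
  e <- exp(logits - max(logits))
  probs <- e / sum(e)
  if (keep) {
    cache$flat <- flat
    cache$h <- h
    cache$h_relu <- h_pre > 0
    cache$pooled_dim <- dim(A)
  }
  list(probs = probs, cache = cache)
}

# dlogits: length-2 gradient at the softmax input. Returns grads mirroring
# the weight structure.
cnn_backward <- function(net, cache, dlogits) {
  g <- list(conv = vector("list", 4))
  g$fc2 <- list(W = outer(cache$h, dlogits), b = dlogits)
  dh <- drop(net$fc2$W %*% dlogits) * cache$h_relu
  g$fc1 <- list(W = outer(cache$flat, dh), b = dh)
  dA <- matrix(drop(net$fc1$W %*% dh), cache$pooled_dim[1], cache$pooled_dim[2])
  for (l in 4:1) {
    geo <- net$geom[[l]]
    lc <- cache$layers[[l]]
    Fn <- ncol(dA) # filters at this layer
    dact <- matrix(0, geo$H * geo$H, Fn)
    taken <- matrix(FALSE, nrow(dA), Fn)
    for (k in 1:4) {
      mk <- lc$masks[[k]] & !taken
      taken <- taken | mk
      dact[geo$pool[[k]], ] <- dact[geo$pool[[k]], ] + dA * mk
    }
    dz <- dact * lc$relu
    g$conv[[l]] <- list(W = crossprod(lc$cols, dz), b = colSums(dz))
    if (l > 1) {
      dcols <- dz %*% t(net$conv[[l]]$W)
      C <- ncol(dcols) / 9L
      dpad <- matrix(0, geo$P * geo$P, C)
      for (j in 1:9) {
        blk <- dcols[, ((j - 1L) * C + 1L):(j * C), drop = FALSE]
        dpad[geo$idx[, j], ] <- dpad[geo$idx[, j], ] + blk
      }
      dA <- dpad[geo$interior, , drop = FALSE]
    }
  }
  g
}

# ---- fitting ----------------------------------------------------------------

#' Fit the fall/not-fall classifier
#'
#' Trains the compact convolutional network on scalogram images with
#' mini-batch stochastic gradient descent with momentum on the cross-entropy
#' loss. Training is deterministic for a fixed configuration seed (the seed
#' drives both weight initialization and batch shuffling).
#'
#' @param x List of training images: `scalogram_image` (227 x 227 x 3) or
#'   cached [image_stem()] outputs.
#' @param y Labels: character or factor with values `"fall"` / `"not_fall"`,
#'   one per image. Both classes must be present.
#' @param config A [fall_cnn_config()].
#' @param verbose Print the loss once per epoch.
#' @return Object of class `fall_cnn` with the fitted weights and a
#'   `history` data frame (`epoch`, `loss`, `accuracy`).
#' @seealso [predict.fall_cnn()], [fall_cnn_init()]
#' @examples
#' \donttest{
#' sc <- scenario_config(n_subjects = 2, records_per_subject = 6)
#' ds <- generate_dataset(sc)
#' # see run_experiment() for the full pipeline
#' }
#' @export
fall_cnn <- function(x, y, config = fall_cnn_config(), verbose = FALSE) {
  stopifnot(is.list(x), length(x) >= 2)
  y <- as.character(y)
  if (length(y) != length(x)) {
    stop("length(y) (", length(y), ") != number of images (", length(x), ")")
  }
  bad <- setdiff(unique(y), .CNN_CLASSES)
  if (length(bad)) stop("unknown labels: ", toString(bad))
  if (length(unique(y)) < 2) {
    stop("single-class training set: need at least one example of each of ",
         toString(.CNN_CLASSES))
  }
  net <- fall_cnn_init(config)
  stems <- lapply(x, prepare_stem, config = config)
  yi <- match(y, net$classes) # 1 = not_fall, 2 = fall

  lr <- config$learning_rate
  mom <- config$momentum
  vel <- rapply(net[c("conv", "fc1", "fc2")],
    function(w) w * 0,
    how = "replace"
  )
  n <- length(stems)
  history <- data.frame(epoch = integer(), loss = numeric(), accuracy = numeric())
  best <- Inf
  stall <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    ep_correct <- 0L
    b0 <- 1L
    while (b0 <= n) {
      b1 <- min(b0 + config$batch_size - 1L, n)
      ids <- ord[b0:b1]
      acc <- NULL
      for (i in ids) {
        fw <- cnn_forward(net, stems[[i]], keep = TRUE)
        p <- fw$probs
        tgt <- numeric(2)
        tgt[yi[i]] <- 1
        ep_loss <- ep_loss - log(max(p[yi[i]], 1e-12))
        ep_correct <- ep_correct + (which.max(p) == yi[i])
        gr <- cnn_backward(net, fw$cache, p - tgt)
        acc <- if (is.null(acc)) gr else add_grads(acc, gr)
      }
      scale <- 1 / length(ids)
      for (l in 1:4) {
        vel$conv[[l]]$W <- mom * vel$conv[[l]]$W - lr * scale * acc$conv[[l]]$W
        vel$conv[[l]]$b <- mom * vel$conv[[l]]$b - lr * scale * acc$conv[[l]]$b
        net$conv[[l]]$W <- net$conv[[l]]$W + vel$conv[[l]]$W
        net$conv[[l]]$b <- net$conv[[l]]$b + vel$conv[[l]]$b
      }
      for (nm in c("fc1", "fc2")) {
        vel[[nm]]$W <- mom * vel[[nm]]$W - lr * scale * acc[[nm]]$W
        vel[[nm]]$b <- mom * vel[[nm]]$b - lr * scale * acc[[nm]]$b
        net[[nm]]$W <- net[[nm]]$W + vel[[nm]]$W
        net[[nm]]$b <- net[[nm]]$b + vel[[nm]]$b
      }
      b0 <- b1 + 1L
    }
    ep_loss <- ep_loss / n
    history <- rbind(history, data.frame(
      epoch = ep, loss = ep_loss, accuracy = ep_correct / n
    ))
    if (verbose) {
      message(sprintf(
        "epoch %2d  loss %.4f  acc %.3f", ep, ep_loss, ep_correct / n
      ))
    }
    if (best - ep_loss > config$min_delta) {
      best <- ep_loss
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  net$trained <- TRUE
  net$history <- history
  net$n_train <- n
  net
}

add_grads <- function(a, b) {
  for (l in 1:4) {
    a$conv[[l]]$W <- a$conv[[l]]$W + b$conv[[l]]$W
    a$conv[[l]]$b <- a$conv[[l]]$b + b$conv[[l]]$b
  }
  for (nm in c("fc1", "fc2")) {
    a[[nm]]$W <- a[[nm]]$W + b[[nm]]$W
    a[[nm]]$b <- a[[nm]]$b + b[[nm]]$b
  }
  a
}

# ---- prediction and methods -------------------------------------------------

#' Predict fall probabilities for scalogram images
#'
#' @param object A fitted (or untrained) `fall_cnn`.
#' @param newdata A single image array, or a list of images / cached stems.
#' @param type `"prob"` for softmax probabilities, `"class"` for hard labels.
#' @param ... Unused.
#' @return For `"prob"`, a data frame with columns `p_not_fall`, `p_fall`
#'   (rows sum to 1); for `"class"`, a character vector of labels.
#' @export
predict.fall_cnn <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (!is.list(newdata)) newdata <- list(newdata)
  probs <- t(vapply(newdata, function(img) {
    cnn_forward(object, prepare_stem(img, object$config))$probs
  }, numeric(2)))
  colnames(probs) <- paste0("p_", object$classes)
  out <- as.data.frame(probs)
  if (type == "class") {
    return(object$classes[max.col(probs, ties.method = "first")])
  }
  out
}

#' @export
print.fall_cnn <- function(x, ...) {
  cat(sprintf(
    "<fall_cnn> %s mode, %s, classes: %s\n",
    x$config$mode,
    if (x$trained) sprintf("trained on %d images", x$n_train) else "untrained",
    toString(x$classes)
  ))
  if (!is.null(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf(
      "  %d epochs, final loss %.4f, training accuracy %.1f%%\n",
      last$epoch, last$loss, 100 * last$accuracy
    ))
  }
  invisible(x)
}

#' @export
summary.fall_cnn <- function(object, ...) {
  f <- object$config$filters
  S <- object$config$stem_size
  n_par <- sum(vapply(object$conv, function(l) length(l$W) + length(l$b), numeric(1))) +
    length(object$fc1$W) + length(object$fc1$b) +
    length(object$fc2$W) + length(object$fc2$b)
  cat("Compact fall/not-fall CNN\n")
  cat(sprintf("  input 227 x 227 x 3 -> stem %d x %d x 3\n", S, S))
  for (l in 1:4) {
    cat(sprintf(
      "  conv%d: 3x3 x %d + ReLU + 2x2 maxpool (%d x %d)\n",
      l, f[l], S / 2^l, S / 2^l
    ))
  }
  cat(sprintf("  dense %d (ReLU) -> dense 2 -> softmax\n", object$config$dense_units))
  cat(sprintf("  %d trainable parameters; output layer: 2 units\n", n_par))
  invisible(object)
}

#' @export
plot.fall_cnn <- function(x, ...) {
  if (is.null(x$history)) stop("no training history to plot")
  h <- x$history
  graphics::par(mar = c(4, 4, 2, 4))
  graphics::plot(h$epoch, h$loss,
    type = "b", pch = 16, xlab = "epoch",
    ylab = "training loss", main = "fall_cnn training", ...
  )
  graphics::par(new = TRUE)
  graphics::plot(h$epoch, h$accuracy,
    type = "b", pch = 1, col = "grey40",
    axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1)
  )
  graphics::axis(4)
  graphics::mtext("training accuracy", side = 4, line = 2.5)
  invisible(x)
}
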