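#' Network architecture configuration
#'
#' Describes the compact U-Net used for tissue segmentation: an
#' encoder-decoder with skip connections, 3x3 convolutions preceded by
#' reflection padding (so spatial dimensions are preserved at every level),
#' batch normalisation, leaky-ReLU activations and a per-pixel softmax head.
#'
#' @param depth Number of encoder pooling levels. Input tiles must be
#'   divisible by `2^depth`.
#' @param base_channels Feature channels at the first level; doubled at each
#'   deeper level.
#' @param n_classes Number of output classes (10 tissue classes).
#' @param in_channels Input channels (3 for RGB).
#' @param slope Negative slope of the leaky rectifier.
#' @param batch_norm Use batch normalisation after every convolution.
#' @param bn_momentum Running-statistics momentum for batch norm.
#' @param bn_eps Batch-norm variance floor.
#' @param dice_eps Additive smoothing of the soft Dice training objective
#'   (numerator and denominator), so classes absent from a batch contribute a
#'   Dice of 1 without gradient pathology.
#' @param tile_px Nominal training tile size.
#' @return A list of class `unet_config`.
#' @export
unet_config <- function(depth = 5, base_channels = 32, n_classes = 10,
                        in_channels = 3, slope = 0.01, batch_norm = TRUE,
                        bn_momentum = 0.9, bn_eps = 1e-5, dice_eps = 1,
                        tile_px = 512) {
  stopifnot(depth >= 1, base_channels >= 1, n_classes >= 2, slope >= 0)
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 n_classes = as.integer(n_classes),
                 in_channels = as.integer(in_channels),
                 slope = slope, batch_norm = isTRUE(batch_norm),
                 bn_momentum = bn_momentum, bn_eps = bn_eps,
                 dice_eps = dice_eps, tile_px = as.integer(tile_px)),
            class = "unet_config")
}

# channel plan: one row per convolution in fixed topology order
unet_layer_plan <- function(cfg) {
  D <- cfg$depth; F0 <- cfg$base_channels
  ch <- function(d) F0 * 2^d
  plan <- list()
  cin <- cfg$in_channels
  for (d in seq_len(D) - 1L) {
    plan[[length(plan) + 1L]] <- c(cin, ch(d)); cin <- ch(d)
    plan[[length(plan) + 1L]] <- c(cin, ch(d))
  }
  plan[[length(plan) + 1L]] <- c(ch(D - 1), ch(D))
  plan[[length(plan) + 1L]] <- c(ch(D), ch(D))
  for (d in rev(seq_len(D) - 1L)) {
    plan[[length(plan) + 1L]] <- c(ch(d + 1), ch(d))      # after upsample
    plan[[length(plan) + 1L]] <- c(2 * ch(d), ch(d))      # after concat
    plan[[length(plan) + 1L]] <- c(ch(d), ch(d))
  }
  plan[[length(plan) + 1L]] <- c(ch(0), cfg$n_classes)    # 1x1 head
  plan
}

#' Build an untrained segmentation network
#'
#' Initializes all convolution weights with He-normal draws from the current
#' R random stream, so `set.seed()` before calling makes the initialization
#' reproducible.
#'
#' @param config A [unet_config()].
#' @return An object of class `angio_unet`.
#' @export
#' @examples
#' set.seed(1)
#' net <- build_unet(unet_config(depth = 2, base_channels = 4))
build_unet <- function(config = unet_config()) {
  stopifnot(inherits(config, "unet_config"))
  plan <- unet_layer_plan(config)
  nlayer <- length(plan)
  layers <- vector("list", nlayer)
  for (i in seq_len(nlayer)) {
    cin <- plan[[i]][1]; cout <- plan[[i]][2]
    k <- if (i == nlayer) 1L else 3L
    bn <- config$batch_norm && i < nlayer
    fan_in <- cin * k * k
    W <- matrix(rnorm(cout * fan_in, sd = sqrt(2 / fan_in)), cout, fan_in)
    layers[[i]] <- list(W = W, b = numeric(cout), k = k, bn = bn,
                        gamma = rep(1, cout), beta = numeric(cout),
                        rmean = numeric(cout), rvar = rep(1, cout))
  }
  structure(list(config = config, layers = layers, adam = list(), t = 0L,
                 history = tibble::tibble(epoch = integer(), lr = numeric(),
                                          loss = numeric())),
            class = "angio_unet")
}

#' @export
print.angio_unet <- function(x, ...) {
  cfg <- x$config
  npar <- sum(vapply(x$layers, function(l) length(l$W) + length(l$b) +
                       length(l$gamma) + length(l$beta), numeric(1)))
  cat(sprintf("<angio_unet> depth %d, base %d channels, %d classes, %d parameters\n",
              cfg$depth, cfg$base_channels, cfg$n_classes, npar))
  if (nrow(x$history)) {
    cat(sprintf("  trained %d epochs, last loss %.4f\n",
                max(x$history$epoch), utils::tail(x$history$loss, 1)))
  } else cat("  untrained\n")
  invisible(x)
}

#' Predict class probabilities for one tile
#'
#' Runs the network on an RGB array and returns the per-pixel class
#' probability stack (a valid categorical distribution at every pixel).
#'
#' @param object A trained or untrained [build_unet()] network.
#' @param image Numeric array `[H, W, 3]` with values in \[0, 1\]. Both
#'   spatial dimensions must be divisible by `2^depth`.
#' @param ... Unused.
#' @return Array `[H, W, n_classes]` of probabilities.
#' @export
predict.angio_unet <- function(object, image, ...) {
  stopifnot(length(dim(image)) == 3)
  d <- dim(image)
  div <- 2^object$config$depth
  if (d[1] %% div != 0 || d[2] %% div != 0) {
    stop(sprintf("tile size %dx%d not divisible by 2^depth = %d", d[1], d[2], div))
  }
  if (d[3] != object$config$in_channels) stop("wrong number of input channels")
  cpp_unet_forward(object$layers, object$config, image)
}

#' Train the segmentation network
#'
#' Optimizes the class-weighted soft Dice objective with Adam under an
#' exponentially decaying learning rate with cosine warm restarts
#' (`lr_e = lr * decay^(e-1) * (1 + cos(pi * ((e-1) mod T) / T)) / 2`).
#' Augmentation (random flips, rotation with mirror padding, color jitter)
#' is drawn from the R random stream each epoch, so a `set.seed()` call (or
#' the `seed` argument) makes the whole run reproducible.
#'
#' @param net An [build_unet()] network.
#' @param tiles A data frame with list-columns `rgb` (arrays `[H, W, 3]`) and
#'   `mask` (one-hot arrays `[H, W, n_classes]`), optionally `ignore`
#'   (matrices, 1 = use pixel), as produced by [generate_tiles()] or
#'   [extract_tiles()].
#' @param epochs Number of passes over the data.
#' @param batch_size Tiles per gradient step.
#' @param lr,lr_decay Initial learning rate and per-epoch exponential decay.
#' @param restart_period Cosine warm-restart period in epochs.
#' @param class_weights Per-class loss weights, default
#'   [default_class_weights()].
#' @param augment Apply data augmentation.
#' @param seed Optional integer; if given, `set.seed(seed)` is called first.
#' @param verbose Print per-epoch loss.
#' @return The updated `angio_unet` with `history` extended.
#' @export
train_unet <- function(net, tiles, epochs = 20, batch_size = 8, lr = 1e-3,
                       lr_decay = 0.97, restart_period = 25,
                       class_weights = default_class_weights(),
                       augment = TRUE, seed = NULL, verbose = FALSE) {
  stopifnot(inherits(net, "angio_unet"))
  n <- nrow(tiles)
  if (is.null(n) || n == 0) stop("empty training dataset")
  if (!is.null(seed)) set.seed(seed)
  cw <- rep_len(class_weights, net$config$n_classes)
  has_ignore <- "ignore" %in% names(tiles)
  for (e in seq_len(epochs)) {
    lr_e <- lr * lr_decay^(e - 1) *
      0.5 * (1 + cos(pi * ((e - 1) %% restart_period) / restart_period))
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    xs <- vector("list", n); gs <- vector("list", n)
    igns <- rep(list(NULL), n)
    for (i in seq_len(n)) {
      rgb <- tiles$rgb[[i]]; mask <- tiles$mask[[i]]
      if (augment) {
        a <- augment_tile(rgb, mask)
        rgb <- a$rgb; mask <- a$mask
      }
      xs[[i]] <- rgb; gs[[i]] <- mask
      if (has_ignore) igns[i] <- list(tiles$ignore[[i]])
    }
    res <- cpp_unet_train_epoch(net$layers, net$adam, net$config,
                                xs, gs, igns, unname(batches),
                                lr_e, cw, net$t)
    net$layers <- res$layers
    net$adam <- res$adam
    net$t <- res$t
    epoch_n <- if (nrow(net$history)) max(net$history$epoch) + 1L else 1L
    net$history <- dplyr::bind_rows(net$history,
      tibble::tibble(epoch = epoch_n, lr = lr_e, loss = mean(res$losses)))
    if (verbose) message(sprintf("epoch %d  lr %.2e  loss %.4f", epoch_n, lr_e,
                                 mean(res$losses)))
  }
  net
}

#' Save / load a trained network
#'
#' @param net An `angio_unet`.
#' @param path File path.
#' @return `load_unet` returns the network.
#' @export
save_unet <- function(net, path) {
  stopifnot(inherits(net, "angio_unet"))
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "angio_unet"))
  net
}
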