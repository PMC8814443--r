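#' Residual-network structure specification
#'
#' Describes the ResNet-34 feature extractor: a 3x3 stem convolution with
#' 64 filters and stride 2, four residual stages of two-convolution basic
#' blocks repeated \{3, 4, 6, 3\} times at widths \{64, 128, 256, 512\},
#' global average pooling, and a classification head used only during
#' pretraining. The input is a 64x64 single-channel image. Spatial
#' downsampling happens at the stem and at the first block of stages 2-4;
#' the first block of stage 1 downsamples through a parameter-free
#' subsampled identity shortcut (widths are unchanged there), while the
#' three width-changing transitions use 1x1 projection shortcuts. This
#' yields exactly 36 convolutions (1 stem + 32 block + 3 projection) and 36
#' batch normalizations, with a 512-wide penultimate (post-pooling) layer.
#'
#' @param widths Stage widths (default `c(64, 128, 256, 512)`).
#' @param blocks Blocks per stage (default `c(3, 4, 6, 3)`).
#' @param stem_filters Stem width (default 64).
#' @param input_size Input side length in pixels (default 64).
#' @param in_channels Input channels (default 1, grayscale).
#' @param n_classes Classification-head width for pretraining (default 200,
#'   the class count of a Tiny-ImageNet-style corpus).
#' @return Object of class `resnet_spec`.
#' @export
resnet_spec <- function(widths = c(64L, 128L, 256L, 512L),
                        blocks = c(3L, 4L, 6L, 3L),
                        stem_filters = 64L, input_size = 64L,
                        in_channels = 1L, n_classes = 200L) {
  stopifnot(length(widths) == length(blocks), all(widths >= 1),
            all(blocks >= 1), input_size >= 8, n_classes >= 2)
  structure(list(widths = as.integer(widths), blocks = as.integer(blocks),
                 stem_filters = as.integer(stem_filters),
                 input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes)),
            class = "resnet_spec")
}

# Per-block layout table: input/output channels, stride, projection flag.
# Stage transitions downsample by 2; a width change requires a 1x1
# projection shortcut, an equal-width downsample uses subsampled identity.
resnet_layout <- function(spec) {
  out <- list()
  in_ch <- spec$stem_filters
  for (s in seq_along(spec$widths)) {
    for (b in seq_len(spec$blocks[s])) {
      stride <- if (b == 1L) 2L else 1L
      # stage 1 keeps the stem width; later first-blocks change width
      if (s == 1L && b == 1L) stride <- 2L
      out_ch <- spec$widths[s]
      proj <- (b == 1L) && (out_ch != in_ch)
      out[[length(out) + 1L]] <- list(in_ch = in_ch, out_ch = out_ch,
                                      stride = stride, proj = proj)
      in_ch <- out_ch
    }
  }
  out
}

init_bn <- function(n, prefix) {
  out <- list(rep(1, n), rep(0, n), rep(0, n), rep(1, n))
  names(out) <- paste0(prefix, c("gamma", "beta", "rmean", "rvar"))
  out
}

#' Build an untrained residual network
#'
#' Initializes all convolution weights with He-normal scaling
#' (`sd = sqrt(2 / fan_in)`), batch-norm scale 1 / shift 0, and running
#' statistics at (0, 1).
#'
#' @param spec A [resnet_spec()].
#' @param seed Integer seed for the weight initialization.
#' @return Object of class `resnet_net` with fields `spec` and `params`.
#' @export
build_network <- function(spec = resnet_spec(), seed = 1L) {
  stopifnot(inherits(spec, "resnet_spec"))
  set.seed(seed)
  he <- function(fan_in, nr, nc) matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  stem <- c(list(W = he(9 * spec$in_channels, 9 * spec$in_channels, spec$stem_filters)),
            init_bn(spec$stem_filters, ""))
  blocks <- lapply(resnet_layout(spec), function(b) {
    bl <- c(b,
            list(W1 = he(9 * b$in_ch, 9 * b$in_ch, b$out_ch)),
            init_bn(b$out_ch, "bn1_"),
            list(W2 = he(9 * b$out_ch, 9 * b$out_ch, b$out_ch)),
            init_bn(b$out_ch, "bn2_"))
    if (b$proj)
      bl <- c(bl, list(Wp = he(b$in_ch, b$in_ch, b$out_ch)),
              init_bn(b$out_ch, "bnp_"))
    bl
  })
  feat_dim <- spec$widths[length(spec$widths)]
  fc <- list(W = he(feat_dim, feat_dim, spec$n_classes),
             b = rep(0, spec$n_classes))
  params <- list(stem = stem, blocks = blocks, fc = fc,
                 in_ch = spec$in_channels, input_size = spec$input_size)
  net <- structure(list(spec = spec, params = params, seed = as.integer(seed)),
                   class = "resnet_net")
  net$fingerprint <- digest::digest(params, algo = "md5")
  net
}

#' Structural audit of a built network
#'
#' Counts convolution and batch-normalization operations and reports the
#' penultimate feature width, for automated verification of the printed
#' architecture (36 convolutions, 36 batch normalizations, 512 features).
#'
#' @param net A [build_network()] result (or a `pretrain_state`).
#' @return List with `n_conv`, `n_bn`, `feature_dim`, `n_params`.
#' @export
network_audit <- function(net) {
  net <- as_network(net)
  p <- net$params
  n_conv <- 1L + sum(vapply(p$blocks, function(b) 2L + as.integer(b$proj),
                            integer(1)))
  n_bn <- n_conv  # every convolution is followed by exactly one batch norm
  wmats <- c(list(p$stem$W, p$fc$W),
             unlist(lapply(p$blocks, function(b)
               Filter(Negate(is.null), list(b$W1, b$W2, b$Wp))),
               recursive = FALSE))
  bn_n <- sum(vapply(p$blocks, function(b)
    length(b$bn1_gamma) * 2 * (2L + as.integer(b$proj)), numeric(1)))
  list(n_conv = n_conv, n_bn = n_bn,
       feature_dim = net$spec$widths[length(net$spec$widths)],
       n_params = sum(vapply(wmats, length, numeric(1))) +
         length(p$fc$b) + 2 * length(p$stem$gamma) + bn_n)
}

# the C++ training loop returns batch-norm vectors and the fc bias as n x 1
# matrices; strip the dims so parameter sets compare identically across the
# R/C++ boundary
canonicalize_params <- function(p) {
  fix_bn <- function(l) {
    for (k in grep("gamma|beta|rmean|rvar|^b$", names(l), value = TRUE))
      l[[k]] <- as.numeric(l[[k]])
    l
  }
  p$stem <- fix_bn(p$stem)
  p$blocks <- lapply(p$blocks, fix_bn)
  p$fc$b <- as.numeric(p$fc$b)
  p
}

as_network <- function(x) {
  if (inherits(x, "pretrain_state")) return(x$network)
  if (inherits(x, "resnet_net")) return(x)
  stop("expected a resnet_net or pretrain_state", call. = FALSE)
}

#' Fingerprint of a network's weights
#'
#' @param net A `resnet_net` or `pretrain_state`.
#' @return MD5 string over the serialized parameters.
#' @export
network_fingerprint <- function(net) {
  net <- as_network(net)
  if (!is.null(net$fingerprint)) return(net$fingerprint)
  digest::digest(net$params, algo = "md5")
}

#' Convert a colour image to grayscale
#'
#' ITU-R BT.601 luminance: `0.299 R + 0.587 G + 0.114 B`. The value range
#' is preserved (the weights sum to 1).
#'
#' @param image H x W x 3 numeric array.
#' @return H x W matrix.
#' @export
grayscale <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("contract error: grayscale expects an H x W x 3 array", call. = FALSE)
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

#' Pretrain the backbone on a labelled grayscale image corpus
#'
#' Cross-entropy classification training with SGD (momentum 0.9, cosine
#' learning-rate decay, weight decay on convolution/linear weights).
#' Deterministic for a fixed seed. The classification head is used only
#' here; feature extraction discards it.
#'
#' @param net A [build_network()] result.
#' @param images Either an N x 64 x 64 array or a list of 64x64 matrices,
#'   values on a common finite scale (typically `[0, 1]`).
#' @param labels Integer or factor class labels, at least 2 classes.
#' @param epochs Training epochs (default 30; 0 returns the initial
#'   weights unchanged).
#' @param batch_size Minibatch size (default 128).
#' @param lr Initial learning rate (default 0.1, cosine-decayed to 0).
#' @param momentum SGD momentum (default 0.9).
#' @param weight_decay L2 penalty on conv/linear weights (default 1e-4).
#' @param seed Seed for shuffling (default 1).
#' @param corpus_tag Identifier recorded in the returned state.
#' @return Object of class `pretrain_state`: fields `network`, `history`
#'   (per-epoch loss and training accuracy), `corpus_tag`, `seed`,
#'   `epochs`, `schedule`.
#' @export
pretrain <- function(net, images, labels, epochs = 30L, batch_size = 128L,
                     lr = 0.1, momentum = 0.9, weight_decay = 1e-4,
                     seed = 1L, corpus_tag = "corpus") {
  stopifnot(inherits(net, "resnet_net"))
  if (is.list(images)) images <- simplify2array(images)  # 64 x 64 x N
  hw <- net$spec$input_size
  d <- dim(images)
  if (length(d) != 3L) stop("images must be a 3-D array or list of matrices",
                            call. = FALSE)
  if (d[1] != hw && d[2] == hw && d[3] == hw)
    images <- aperm(images, c(2, 3, 1))  # N x H x W -> H x W x N
  stopifnot(dim(images)[1] == hw, dim(images)[2] == hw)
  n <- dim(images)[3]
  if (n != length(labels)) stop("images and labels lengths differ", call. = FALSE)
  y <- as.integer(factor(labels)) - 1L
  k <- length(unique(y))
  if (k < 2L) stop("validation error: pretraining corpus must have >= 2 classes",
                   call. = FALSE)
  if (k > net$spec$n_classes)
    stop("more classes than the classification head width", call. = FALSE)
  if (!all(is.finite(images))) stop("images must be finite", call. = FALSE)
  x <- matrix(as.numeric(images), nrow = hw * hw, ncol = n)
  if (epochs == 0L) {
    # no-op training: the initial weights are returned untouched
    return(structure(list(network = net,
                          history = data.frame(epoch = integer(0),
                                               loss = numeric(0),
                                               train_acc = numeric(0)),
                          corpus_tag = corpus_tag, seed = as.integer(seed),
                          epochs = 0L, schedule = numeric(0)),
                     class = "pretrain_state"))
  }
  sched <- lr * 0.5 * (1 + cos(pi * (seq_len(epochs) - 1) / epochs))
  res <- cpp_resnet_train(net$params, x, y, as.integer(epochs),
                          as.integer(batch_size), sched, momentum, 0.1,
                          weight_decay, as.integer(seed))
  trained <- net
  trained$params <- canonicalize_params(res$params)
  trained$fingerprint <- digest::digest(trained$params, algo = "md5")
  structure(list(network = trained,
                 history = data.frame(epoch = seq_len(length(res$loss)),
                                      loss = unlist(res$loss),
                                      train_acc = unlist(res$train_acc)),
                 corpus_tag = corpus_tag, seed = as.integer(seed),
                 epochs = as.integer(epochs), schedule = sched),
            class = "pretrain_state")
}

#' @export
print.pretrain_state <- function(x, ...) {
  cat(sprintf("<pretrain_state> corpus %s, %d epochs, seed %d\n",
              x$corpus_tag, x$epochs, x$seed))
  if (nrow(x$history)) print(utils::tail(x$history, 3))
  invisible(x)
}

#' Save / load a pretraining checkpoint
#'
#' Serialized with an embedded spec and weight fingerprint so a mismatched
#' checkpoint is detected on load.
#'
#' @param state A `pretrain_state` or `resnet_net`.
#' @param path Checkpoint file path.
#' @return `path` (save) or the restored object (load).
#' @export
save_checkpoint <- function(state, path) {
  obj <- list(state = state,
              fingerprint = digest::digest(as_network(state)$params,
                                           algo = "md5"))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  # re-hash the stored parameters; a corrupted or tampered file is refused
  if (!identical(obj$fingerprint,
                 digest::digest(as_network(obj$state)$params, algo = "md5")))
    stop("checkpoint fingerprint mismatch", call. = FALSE)
  obj$state
}

# views: list of 64x64 matrices -> model input (1 x n*4096), plus forward
forward_views <- function(net, views) {
  hw <- net$spec$input_size
  for (v in views) {
    if (!is.matrix(v) || !all(dim(v) == hw))
      stop("contract error: each view must be ", hw, "x", hw, call. = FALSE)
    if (any(is.na(v)) || !all(is.finite(v)))
      stop("validation error: view contains non-finite values", call. = FALSE)
  }
  x <- matrix(unlist(lapply(views, as.vector)), nrow = 1)
  t(cpp_resnet_features(net$params, x, length(views)))  # n x feat_dim
}

#' Extract 512-d deep features for one view
#'
#' Forward pass in inference mode (batch normalization uses its running
#' statistics); the post-average-pool activations are returned. Weights are
#' never mutated.
#'
#' @param extractor A `pretrain_state` or `resnet_net`.
#' @param view 64x64 numeric matrix.
#' @return Numeric vector of length 512.
#' @export
extract_view_features <- function(extractor, view) {
  net <- as_network(extractor)
  as.vector(forward_views(net, list(view)))
}

#' Extract the 4,608-d per-modality feature vector for one case
#'
#' The nine per-view 512-d vectors are concatenated in the fixed view
#' order, giving 9 x 512 = 4,608 features.
#'
#' @param extractor A `pretrain_state` or `resnet_net`.
#' @param views A [extract_nine_views()] `view_stack`.
#' @return Numeric vector of length 4,608.
#' @export
extract_case_features <- function(extractor, views) {
  if (!inherits(views, "view_stack") || length(views$views) != 9L)
    stop("contract error: expected a view_stack with exactly 9 views", call. = FALSE)
  net <- as_network(extractor)
  as.vector(t(forward_views(net, views$views)))
}
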