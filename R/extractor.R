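# VGG16 conv widths, scaled by the width multiplier
.vgg16_widths <- c(64, 64, 128, 128, 256, 256, 256, 512, 512, 512, 512, 512, 512)

#' Configuration of the perceptive-feature extractor
#'
#' A two-channel VGG16-style network: 13 3x3 convolution layers in five
#' blocks with 2x2 max-pooling, three fully connected layers (the last one
#' 128 units wide — the perceptive features) and a linear 5-unit regression
#' head trained with mean squared error against the quantified descriptor
#' codes using Adam with a piecewise-constant learning-rate schedule.
#'
#' @param input_side Input side in px (divisible by 32); 288 is the
#'   full-resolution contract, 64 the desk-scale profile.
#' @param width_mult Multiplier on the VGG16 conv widths (1 = full size).
#' @param fc_sizes Three fully connected widths; the last is the feature
#'   dimension and defaults to 128.
#' @param dropout_rate Dropout probability after the first two fc layers.
#' @param output_dim Regression head width (5 descriptor codes).
#' @param lr_init Initial Adam learning rate.
#' @param lr_decay_gamma Multiplicative decay factor.
#' @param lr_decay_epochs Epochs at which the decay applies (must lie in
#'   [1, max_epochs]).
#' @param max_epochs Training epochs; the weights are frozen at the last
#'   epoch by default.
#' @param batch_size Minibatch size.
#' @param init_scheme "scaled" (variance-scaled Gaussian, default) or
#'   "paper_normal" (standard-normal init; kept as an option, but deep
#'   nets rarely train under it).
#' @param seed Integer seed governing init, shuffling and dropout.
#' @return An `extractor_config` list.
#' @export
extractor_config <- function(input_side = 288L, width_mult = 1,
                             fc_sizes = c(1024L, 256L, 128L),
                             dropout_rate = 0.5, output_dim = 5L,
                             lr_init = 1e-4, lr_decay_gamma = 0.1,
                             lr_decay_epochs = c(30L, 60L), max_epochs = 70L,
                             batch_size = 16L, init_scheme = c("scaled", "paper_normal"),
                             seed = 1L) {
  init_scheme <- match.arg(init_scheme)
  if (input_side %% 32 != 0)
    stop("input_side must be divisible by 32", call. = FALSE)
  if (length(fc_sizes) != 3L)
    stop("fc_sizes must have length 3", call. = FALSE)
  if (length(lr_decay_epochs) &&
      (any(lr_decay_epochs < 1) || any(lr_decay_epochs > max_epochs)))
    stop("lr_decay_epochs must lie in [1, max_epochs]", call. = FALSE)
  widths <- pmax(1L, as.integer(round(.vgg16_widths * width_mult)))
  structure(list(input_side = as.integer(input_side), width_mult = width_mult,
                 conv_widths = widths, fc_sizes = as.integer(fc_sizes),
                 dropout_rate = dropout_rate, output_dim = as.integer(output_dim),
                 lr_init = lr_init, lr_decay_gamma = lr_decay_gamma,
                 lr_decay_epochs = as.integer(lr_decay_epochs),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 init_scheme = init_scheme, seed = as.integer(seed)),
            class = "extractor_config")
}

#' Desk-scale extractor profile
#'
#' A CPU-trainable downsizing of the extractor that preserves the feature
#' contract (128-unit penultimate layer): 64-px input, conv widths at 1/8,
#' fc (256, 128, 128), Adam at 1e-3 decayed by 0.1 at epoch 18, 24 epochs.
#'
#' @param ... Overrides passed to [extractor_config()].
#' @return An `extractor_config`.
#' @export
extractor_test_profile <- function(...) {
  defaults <- list(input_side = 64L, width_mult = 1 / 8,
                   fc_sizes = c(256L, 128L, 128L), lr_init = 1e-3,
                   lr_decay_epochs = 18L, max_epochs = 24L)
  args <- utils::modifyList(defaults, list(...))
  if (!"lr_decay_epochs" %in% names(list(...)))   # keep defaults consistent
    args$lr_decay_epochs <- args$lr_decay_epochs[args$lr_decay_epochs <= args$max_epochs]
  do.call(extractor_config, args)
}

#' Per-epoch learning-rate schedule of a configuration
#'
#' Piecewise constant: lr(e) = lr_init * gamma^(number of decay epochs <= e).
#'
#' @param config An `extractor_config`.
#' @return Numeric vector of length `max_epochs`.
#' @export
lr_schedule <- function(config) {
  e <- seq_len(config$max_epochs)
  drops <- vapply(e, function(x) sum(x >= config$lr_decay_epochs), 0)
  config$lr_init * config$lr_decay_gamma^drops
}

arch_list <- function(config) {
  list(input_side = config$input_side, in_channels = 2L,
       conv_widths = config$conv_widths, fc_sizes = config$fc_sizes,
       output_dim = config$output_dim)
}

#' Build the two-channel network input from a lesion patch
#'
#' Channel 1 is the image min-max normalized to [0, 1]; channel 2 the
#' binary ROI mask. Patches whose side differs from the configured input
#' side are resampled (bilinear for the image, nearest neighbour for the
#' mask so it stays binary).
#'
#' @param patch A `lesion_patch`.
#' @param config An `extractor_config`.
#' @return Numeric array (side, side, 2).
#' @export
build_input <- function(patch, config = extractor_config()) {
  stopifnot(inherits(patch, "lesion_patch"))
  s <- config$input_side
  img <- patch$image
  msk <- patch$mask
  if (nrow(img) != s || ncol(img) != s) {
    img <- ebi_mat(EBImage::resize(EBImage::Image(img), w = s, h = s))
    msk <- ebi_mat(EBImage::resize(EBImage::Image(msk), w = s, h = s,
                                     filter = "none"))
    msk <- (msk > 0.5) * 1
  }
  if (!identical(dim(img), c(s, s)) || !identical(dim(msk), c(s, s)))
    stop("shape mismatch after resample", call. = FALSE)
  rng <- range(img)
  if (rng[2] > rng[1]) img <- (img - rng[1]) / (rng[2] - rng[1])
  array(c(img, msk), dim = c(s, s, 2L))
}

# Stack cases (one sample per view) into the tensors the C++ core consumes;
# every view of a case carries the case's shared descriptor codes as target.
cases_to_tensors <- function(cases, config) {
  samples <- list()
  targets <- list()
  meta <- list()
  for (cs in cases)
    for (v in names(cs$patches)) {
      samples[[length(samples) + 1L]] <- build_input(cs$patches[[v]], config)
      targets[[length(targets) + 1L]] <- as.numeric(cs$descriptors)
      meta[[length(meta) + 1L]] <- data.frame(case_id = cs$case_id, view = v,
                                              label = cs$label %||% NA_character_,
                                              stringsAsFactors = FALSE)
    }
  n <- length(samples)
  s <- config$input_side
  X <- array(unlist(samples, use.names = FALSE), dim = c(s, s, 2L, n))
  Y <- do.call(rbind, targets)
  list(X = X, Y = Y, meta = do.call(rbind, meta))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train the perceptive-feature extractor
#'
#' Trains the regression network on all views of the training cases (both
#' views of a case share the case's descriptor codes), minimizing the mean
#' squared error of the 5-unit head. After training the weights are frozen
#' and the network is used as a feature extractor.
#'
#' @param cases List of `cad_case` training cases (>= 2).
#' @param config An `extractor_config`.
#' @param validation_cases Optional held-out cases; per-epoch validation
#'   MSE is then recorded in the history.
#' @return A `trained_extractor`: weights, config, per-epoch history
#'   (epoch, lr, train_mse, val_mse) and `frozen = TRUE`.
#' @export
train_extractor <- function(cases, config = extractor_config(),
                            validation_cases = NULL) {
  if (length(cases) < 1L)
    stop("need at least one training case", call. = FALSE)
  tr <- cases_to_tensors(cases, config)
  Xv <- NULL; Yv <- NULL
  if (!is.null(validation_cases)) {
    va <- cases_to_tensors(validation_cases, config)
    Xv <- as.numeric(va$X); Yv <- va$Y
  }
  set.seed(config$seed)
  w0 <- cpp_cnn_init(arch_list(config), config$init_scheme)
  lrs <- lr_schedule(config)
  fit <- cpp_cnn_train(as.numeric(tr$X), tr$Y, w0, arch_list(config),
                       lrs, config$batch_size, config$dropout_rate, Xv, Yv)
  history <- data.frame(epoch = seq_along(lrs), lr = lrs,
                        train_mse = fit$train_mse, val_mse = fit$val_mse)
  structure(list(weights = fit$weights, config = config, history = history,
                 frozen = TRUE),
            class = "trained_extractor")
}

#' @export
print.trained_extractor <- function(x, ...) {
  cat(sprintf("<trained_extractor> side %d, widths x%.3g, %d epochs, final train MSE %.4f\n",
              x$config$input_side, x$config$width_mult, nrow(x$history),
              x$history$train_mse[nrow(x$history)]))
  invisible(x)
}

forward_patches <- function(model, patches) {
  config <- model$config
  s <- config$input_side
  X <- array(unlist(lapply(patches, build_input, config = config),
                    use.names = FALSE),
             dim = c(s, s, 2L, length(patches)))
  cpp_cnn_forward(as.numeric(X), length(patches), model$weights,
                  arch_list(config))
}

#' Extract perceptive features from a lesion patch
#'
#' Returns the post-activation values of the last fully connected layer
#' (128 units under the default configuration). Inference is deterministic:
#' dropout is disabled and the model must be frozen.
#'
#' @param model A `trained_extractor`.
#' @param patch A `lesion_patch`, or a list of patches (then a matrix with
#'   one row per patch is returned).
#' @return Numeric vector of length `fc_sizes[3]`, or a matrix.
#' @export
extract_features <- function(model, patch) {
  if (!isTRUE(model$frozen))
    stop("state error: extractor weights are not frozen", call. = FALSE)
  patches <- if (inherits(patch, "lesion_patch")) list(patch) else patch
  out <- forward_patches(model, patches)$features
  if (inherits(patch, "lesion_patch")) drop(out[1L, ]) else out
}

#' Predict descriptor codes for a lesion patch
#'
#' Returns the 5-unit regression head output (the predicted quantified
#' descriptions); retained for diagnostics even though classification uses
#' only the 128 features.
#'
#' @inheritParams extract_features
#' @return Numeric vector of length 5, or a matrix.
#' @export
predict_descriptors <- function(model, patch) {
  patches <- if (inherits(patch, "lesion_patch")) list(patch) else patch
  out <- forward_patches(model, patches)$head
  colnames(out) <- c("shape_code", "margin_sharpness_code",
                     "microlobulated_code", "spiculated_code", "density_code")
  if (inherits(patch, "lesion_patch")) drop(out[1L, ]) else out
}

#' Save / load an extractor checkpoint (config + weights + history)
#'
#' @param model A `trained_extractor`.
#' @param path File path.
#' @return `path` (save) or the model (load).
#' @export
save_extractor <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_extractor
#' @export
load_extractor <- function(path) readRDS(path)
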