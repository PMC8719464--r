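#' Configuration for the synthetic lesion phantom generator
#'
#' The phantom emulates mammographic mass patches: a lesion whose shape,
#' margin sharpness, microlobulation, spiculation and density are
#' independently controlled by the five descriptor codes, rendered on a
#' correlated-noise background, with the pathology label drawn from a
#' logistic model of the codes so that malignant-looking descriptions are
#' (stochastically) malignant.
#'
#' @param n_cases Number of cases to generate.
#' @param patch_side Patch side length in pixels (>= 32). Lesion geometry
#'   and blur scale with it; 64 is the desk-scale default, 288 matches the
#'   full-resolution input contract.
#' @param malignancy_logit_weights Numeric length 6: intercept then weights
#'   on the (shape, margin, microlobulated, spiculated, density) codes.
#'   The default gives ~50% malignant prevalence and a descriptor-ceiling
#'   AUC of ~0.95 under uniform descriptor marginals.
#' @param blur_sigmas Edge blur sigma (px) per margin-sharpness code
#'   (0, 0.5, 1); strictly increasing — circumscribed margins are sharpest.
#' @param n_lobes_range,n_spicules_range Integer ranges (length 2) for the
#'   number of microlobulations / spicules.
#' @param contrast_levels Lesion-over-background contrast per density code
#'   (0, 0.5, 1), on the [0,1] intensity scale.
#' @param lesion_radius_frac Base lesion radius as a fraction of the patch
#'   side; the default 0.18 guarantees every descriptor combination fits
#'   the patch, larger lesions may raise a geometry error.
#' @param background_noise_scale Standard deviation of the correlated
#'   background texture.
#' @param descriptor_probs Optional list of categorical marginals with
#'   elements shape (length 2, codes 0/1), margin (length 3), micro
#'   (length 2), spic (length 2), density (length 3); default uniform.
#' @param split Optional named vector `c(train = , test = )` of counts
#'   (integers) or fractions summing to <= 1.
#' @param stratify Stratify the split by pathology label (default TRUE).
#' @param seed Integer seed; every case's RNG stream is derived from
#'   (seed, case index) so generation is reproducible case by case.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(n_cases = 100L,
                           patch_side = 64L,
                           malignancy_logit_weights = c(-9, 4.5, 4.5, 3, 3, 3),
                           blur_sigmas = c(0.5, 1.5, 3.0) * patch_side / 64,
                           n_lobes_range = c(8L, 12L),
                           n_spicules_range = c(6L, 12L),
                           contrast_levels = c(0.18, 0.32, 0.48),
                           lesion_radius_frac = 0.18,
                           background_noise_scale = 0.04,
                           descriptor_probs = NULL,
                           split = NULL,
                           stratify = TRUE,
                           seed = 1L) {
  if (patch_side < 32L)
    stop("patch_side must be >= 32", call. = FALSE)
  if (length(malignancy_logit_weights) != 6L)
    stop("malignancy_logit_weights must have length 6 (intercept + 5 codes)",
         call. = FALSE)
  if (length(blur_sigmas) != 3L || any(diff(blur_sigmas) <= 0))
    stop("blur_sigmas must be 3 values strictly increasing in margin code",
         call. = FALSE)
  if (length(contrast_levels) != 3L)
    stop("contrast_levels must have 3 values (one per density code)",
         call. = FALSE)
  if (lesion_radius_frac <= 0)
    stop("lesion_radius_frac must be positive", call. = FALSE)
  for (r in list(n_lobes_range, n_spicules_range))
    if (length(r) != 2L || r[2] < r[1] || r[1] < 1)
      stop("lobe/spicule ranges must be nonempty increasing pairs",
           call. = FALSE)
  if (is.null(descriptor_probs))
    descriptor_probs <- list(shape = c(0.5, 0.5),
                             margin = rep(1 / 3, 3),
                             micro = c(0.5, 0.5),
                             spic = c(0.5, 0.5),
                             density = rep(1 / 3, 3))
  lens <- c(shape = 2L, margin = 3L, micro = 2L, spic = 2L, density = 3L)
  for (nm in names(lens)) {
    p <- descriptor_probs[[nm]]
    if (is.null(p) || length(p) != lens[[nm]] || any(p < 0) || sum(p) <= 0)
      stop(sprintf("descriptor_probs$%s must be %d nonnegative weights",
                   nm, lens[[nm]]), call. = FALSE)
  }
  if (!is.null(split)) {
    if (is.null(names(split)) || !all(c("train", "test") %in% names(split)))
      stop("split must be a named vector with 'train' and 'test'", call. = FALSE)
    if (all(split <= 1) && sum(split) > 1 + 1e-9)
      stop("split fractions must sum to <= 1", call. = FALSE)
    if (any(split > 1) && sum(split) > n_cases)
      stop("split counts exceed n_cases", call. = FALSE)
  }
  structure(list(n_cases = as.integer(n_cases), patch_side = as.integer(patch_side),
                 malignancy_logit_weights = malignancy_logit_weights,
                 blur_sigmas = blur_sigmas, n_lobes_range = as.integer(n_lobes_range),
                 n_spicules_range = as.integer(n_spicules_range),
                 contrast_levels = contrast_levels,
                 lesion_radius_frac = lesion_radius_frac,
                 background_noise_scale = background_noise_scale,
                 descriptor_probs = descriptor_probs,
                 split = split, stratify = isTRUE(stratify),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Draw a descriptor vector from the configured marginals
#'
#' Each code is drawn independently from its categorical distribution over
#' \{0, 0.5, 1\} (shape, microlobulation and spiculation over \{0, 1\}).
#' Uses the current R RNG stream.
#'
#' @param config A [phantom_config()].
#' @return A `descriptor_vector`.
#' @export
sample_descriptors <- function(config = phantom_config()) {
  p <- config$descriptor_probs
  draw <- function(vals, w) sample(vals, 1L, prob = w)
  descriptor_vector(c(draw(c(0, 1), p$shape),
                      draw(c(0, 0.5, 1), p$margin),
                      draw(c(0, 1), p$micro),
                      draw(c(0, 1), p$spic),
                      draw(c(0, 0.5, 1), p$density)))
}

#' Draw a pathology label from the logistic descriptor model
#'
#' label ~ Bernoulli(plogis(w0 + w . codes)); with the default weights all
#' five malignancy-associated codes push toward "malignant".
#'
#' @param descriptors A `descriptor_vector`.
#' @param config A [phantom_config()].
#' @return "benign" or "malignant".
#' @export
assign_label <- function(descriptors, config = phantom_config()) {
  w <- config$malignancy_logit_weights
  stopifnot(all(is.finite(w)))
  p <- stats::plogis(w[1] + sum(w[-1] * as.numeric(descriptors)))
  if (stats::rbinom(1L, 1L, p) == 1L) "malignant" else "benign"
}

#' Construct a lesion patch object
#'
#' @param image Numeric matrix, intensities in [0, 1].
#' @param mask Binary (0/1) matrix, same shape, the pre-blur lesion support.
#' @param view "CC" or "MLO".
#' @return A `lesion_patch`.
#' @export
lesion_patch <- function(image, mask, view) {
  if (!identical(dim(image), dim(mask)))
    stop("image and mask shapes differ", call. = FALSE)
  if (sum(mask) < 1)
    stop("mask must have at least one foreground pixel", call. = FALSE)
  if (!view %in% c("CC", "MLO"))
    stop("view must be CC or MLO", call. = FALSE)
  structure(list(image = image, mask = mask, view = view),
            class = "lesion_patch")
}

# Plain-matrix view of an EBImage Image
ebi_mat <- function(x) {
  m <- EBImage::imageData(x)
  dim(m) <- dim(m)[1:2]
  m
}

# Radial boundary function of a lesion, polar around the patch centre.
# All geometric randomness is drawn unconditionally so that the same RNG
# state yields the same base geometry whatever the descriptor codes —
# each code then switches its own physical effect on or off.
lesion_radius_fun <- function(descriptors, config) {
  s <- config$patch_side
  # worst-case boundary = r0 * (1 + harmonic excursion) + spike amplitude;
  # the default fraction 0.18 keeps that inside the half-side for every
  # descriptor combination
  r0 <- config$lesion_radius_frac * s * stats::runif(1, 0.9, 1.1)
  # ellipse (shape code 0): mild eccentricity
  q <- stats::runif(1, 1.0, 1.15)
  phi <- stats::runif(1, 0, pi)
  # irregular (shape code 1): random low-order harmonics
  kmax <- 6L
  ck <- stats::rnorm(kmax - 1L) ; sk <- stats::rnorm(kmax - 1L)
  amp <- sqrt(ck^2 + sk^2)
  ck <- ck / max(sum(amp), 1e-9) ; sk <- sk / max(sum(amp), 1e-9)
  # microlobulation: one sinusoidal undulation
  n_lobes <- sample(seq(config$n_lobes_range[1], config$n_lobes_range[2]), 1L)
  lobe_phase <- stats::runif(1, 0, 2 * pi)
  # spiculation: narrow radial Gaussian spikes
  n_sp <- sample(seq(config$n_spicules_range[1], config$n_spicules_range[2]), 1L)
  sp_theta <- stats::runif(n_sp, 0, 2 * pi)
  sp_amp <- stats::runif(n_sp, 0.30, 0.50) * r0
  # keep the spike arc >= ~2 px wide at its tip so the rasterized mask
  # stays one connected component at small patch sides
  sp_width <- pmax(stats::runif(n_sp, 0.07, 0.11), 1.1 / (r0 * 1.5))

  d <- as.numeric(descriptors)
  a <- r0 * sqrt(q) ; b <- r0 / sqrt(q)
  function(theta) {
    t2 <- theta - phi
    base <- a * b / sqrt((b * cos(t2))^2 + (a * sin(t2))^2)
    if (d[1] >= 1) {                       # irregular: jagged radii
      h <- rep(0, length(theta))
      for (k in 2:kmax)
        h <- h + ck[k - 1] * cos(k * theta) + sk[k - 1] * sin(k * theta)
      base <- base * pmax(1 + 0.45 * h, 0.5)
    }
    if (d[3] >= 1)                         # microlobulated undulations
      # amplitude 0.12 r0 keeps the undulation >= ~1 px at the 64-px desk
      # scale (sub-pixel undulations would make the code invisible) while
      # staying far below the spicule scale
      base <- base + 0.12 * r0 * sin(n_lobes * theta + lobe_phase)
    if (d[4] >= 1) {                       # spicules
      spike <- rep(0, length(theta))
      for (i in seq_len(n_sp)) {
        dth <- abs(((theta - sp_theta[i] + pi) %% (2 * pi)) - pi)
        spike <- spike + sp_amp[i] * exp(-0.5 * (dth / sp_width[i])^2)
      }
      base <- base + pmin(spike, 0.55 * r0)   # overlapping spikes saturate
    }
    base
  }
}

#' Render one synthetic case (two views) from a descriptor vector
#'
#' The lesion boundary is a star-shaped radial function around the patch
#' centre: a mild ellipse for shape code 0 or a jagged harmonic polygon for
#' code 1; microlobulation adds a sinusoidal undulation; spiculation adds
#' narrow radial spikes. The margin code selects the edge blur sigma (code 0
#' sharpest), the density code the lesion-to-background contrast. The mask
#' is the pre-blur lesion support, mirroring radiologist-drawn ROIs that
#' outline the lesion regardless of edge conspicuity. The two views are two
#' independent renders sharing one descriptor vector.
#'
#' @param descriptors A `descriptor_vector` shared by both views.
#' @param config A [phantom_config()].
#' @param case_id Identifier for the case.
#' @param label Optional pathology label; drawn from the logistic model
#'   when NULL.
#' @return A `cad_case` with elements case_id, patches (CC, MLO),
#'   descriptors, label.
#' @export
render_case <- function(descriptors, config = phantom_config(),
                        case_id = "case_0001", label = NULL) {
  patches <- lapply(c(CC = "CC", MLO = "MLO"), function(v)
    render_view(descriptors, config, v))
  if (is.null(label)) label <- assign_label(descriptors, config)
  structure(list(case_id = case_id, patches = patches,
                 descriptors = descriptors, label = label),
            class = "cad_case")
}

render_view <- function(descriptors, config, view) {
  s <- config$patch_side
  scale <- s / 64
  rfun <- lesion_radius_fun(descriptors, config)
  theta_grid <- seq(0, 2 * pi, length.out = 721L)
  if (max(rfun(theta_grid)) >= s / 2 - 1)
    stop("geometry error: lesion larger than patch", call. = FALSE)

  ctr <- (s + 1) / 2
  xs <- matrix(rep(seq_len(s), s), s) - ctr        # column index -> x
  ys <- matrix(rep(seq_len(s), each = s), s) - ctr
  rr <- sqrt(xs^2 + ys^2)
  th <- atan2(ys, xs)
  mask <- (rr <= matrix(rfun(as.vector(th)), s)) * 1
  # rasterization can shear off sub-pixel spicule-tip fragments; the ROI is
  # a single outline, so keep the dominant connected component
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
  if (max(lab) > 1) {
    keep <- as.integer(names(which.max(table(lab[lab > 0]))))
    mask <- (lab == keep) * 1
  }
  dim(mask) <- c(s, s)

  d <- as.numeric(descriptors)
  bg_level <- 0.35
  noise <- matrix(stats::rnorm(s * s), s)
  noise <- ebi_mat(EBImage::gblur(EBImage::Image(noise), sigma = 3 * scale))
  noise <- noise / max(stats::sd(noise), 1e-9) * config$background_noise_scale
  contrast <- config$contrast_levels[round(2 * d[5]) + 1L]
  sigma <- config$blur_sigmas[round(2 * d[2]) + 1L]
  lesion <- ebi_mat(EBImage::gblur(EBImage::Image(mask), sigma = max(sigma, 0.01)))
  img <- bg_level + noise + contrast * lesion
  img <- pmin(pmax(img, 0), 1)
  lesion_patch(img, mask, view)
}

# Deterministic per-case RNG seed from (seed, index): a Weyl/LCG-style
# integer mix kept below 2^31.
case_seed <- function(seed, i) {
  x <- (as.double(seed) * 2654435761 + as.double(i) * 40503 + 97) %% 2147483647
  as.integer(x)
}

#' Generate a synthetic dataset of phantom cases
#'
#' Draws descriptors, renders both views and assigns labels for
#' `config$n_cases` cases, each from its own RNG stream derived from
#' (seed, case index). Optionally applies a (stratified) train/test split.
#'
#' @param config A [phantom_config()].
#' @return A list of class `phantom_dataset`: `cases` (list of `cad_case`)
#'   and `manifest` (one row per case x view with descriptor codes, label
#'   and split).
#' @export
generate_dataset <- function(config = phantom_config()) {
  if (config$n_cases < 2L)
    stop("n_cases must be >= 2", call. = FALSE)
  ids <- sprintf("case_%04d", seq_len(config$n_cases))
  cases <- vector("list", config$n_cases)
  for (i in seq_len(config$n_cases)) {
    set.seed(case_seed(config$seed, i))
    desc <- sample_descriptors(config)
    cases[[i]] <- render_case(desc, config, case_id = ids[i])
  }
  names(cases) <- ids
  split <- rep(NA_character_, config$n_cases)
  if (!is.null(config$split)) {
    sp <- config$split
    n_train <- if (all(sp <= 1)) round(sp[["train"]] * config$n_cases)
               else as.integer(sp[["train"]])
    n_test <- if (all(sp <= 1)) round(sp[["test"]] * config$n_cases)
              else as.integer(sp[["test"]])
    set.seed(case_seed(config$seed, 0L))
    labels <- vapply(cases, `[[`, "", "label")
    idx_train <- integer(0)
    if (config$stratify) {
      for (lv in unique(labels)) {
        pool <- which(labels == lv)
        k <- round(n_train * length(pool) / config$n_cases)
        idx_train <- c(idx_train, sample(pool, min(k, length(pool))))
      }
      # top up / trim to the exact requested size
      short <- n_train - length(idx_train)
      if (short > 0)
        idx_train <- c(idx_train, sample(setdiff(seq_along(cases), idx_train), short))
      if (short < 0)
        idx_train <- sample(idx_train, n_train)
    } else {
      idx_train <- sample(seq_along(cases), n_train)
    }
    idx_test <- sample(setdiff(seq_along(cases), idx_train), n_test)
    split[idx_train] <- "train"
    split[idx_test] <- "test"
  }
  manifest <- do.call(rbind, lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    d <- as.numeric(cs$descriptors)
    data.frame(case_id = cs$case_id, view = c("CC", "MLO"),
               image_path = NA_character_, mask_path = NA_character_,
               shape_code = d[1], margin_sharpness_code = d[2],
               microlobulated_code = d[3], spiculated_code = d[4],
               density_code = d[5], label = cs$label, split = split[i],
               stringsAsFactors = FALSE)
  }))
  structure(list(cases = cases, manifest = manifest, config = config),
            class = "phantom_dataset")
}

#' Write a phantom dataset to disk as PNG pairs plus a manifest CSV
#'
#' Files are named `{case_id}_{view}_{img|mask}.png`; the manifest gains
#' image_path/mask_path columns pointing at them. Intensities are stored at
#' 8-bit depth: the quantization error (at most 1/510) sits well below the
#' phantom's background-noise level.
#'
#' @param dataset A `phantom_dataset`.
#' @param dir Output directory (created if needed).
#' @return The updated manifest (invisibly); side effect: files on disk.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- dataset$manifest
  for (i in seq_len(nrow(man))) {
    cs <- dataset$cases[[man$case_id[i]]]
    patch <- cs$patches[[man$view[i]]]
    ip <- file.path(dir, sprintf("%s_%s_img.png", man$case_id[i], man$view[i]))
    mp <- file.path(dir, sprintf("%s_%s_mask.png", man$case_id[i], man$view[i]))
    EBImage::writeImage(EBImage::Image(patch$image), ip, type = "png")
    EBImage::writeImage(EBImage::Image(patch$mask), mp, type = "png")
    man$image_path[i] <- ip
    man$mask_path[i] <- mp
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
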