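# Shared oracles and small fixtures, built in code at test time.

# O(n^2) Mann-Whitney AUC with half credit for ties — independent of the
# package's trapezoidal construction.
mw_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos)
    for (q in neg)
      tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# 4-neighbourhood boundary of a binary mask
mask_boundary <- function(m) {
  up <- rbind(0, m[-nrow(m), ]); down <- rbind(m[-1, ], 0)
  left <- cbind(0, m[, -ncol(m)]); right <- cbind(m[, -1], 0)
  m == 1 & (up == 0 | down == 0 | left == 0 | right == 0)
}

# mean finite-difference gradient magnitude over the mask boundary
boundary_gradient <- function(image, mask) {
  gx <- image[-1, ] - image[-nrow(image), ]
  gy <- image[, -1] - image[, -ncol(image)]
  g <- sqrt(gx[, -1]^2 + gy[-1, ]^2)
  b <- mask_boundary(mask)[-1, -1]
  mean(g[b])
}

# area / convex-hull area
mask_solidity <- function(m) {
  pts <- which(m == 1, arr.ind = TRUE)
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  x <- hp[, 1]; y <- hp[, 2]
  hull_area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  nrow(pts) / max(hull_area, 1)
}

mask_perimeter2_over_area <- function(m) sum(mask_boundary(m))^2 / sum(m)

# a tiny trained extractor shared across classifier tests (32 px, 1/16
# widths, 2 epochs) — enough structure to exercise the contracts
tiny_extractor_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(777)
      cfg <- phantom_config(patch_side = 32L)
      cases <- lapply(1:6, function(i) {
        set.seed(700 + i)
        render_case(sample_descriptors(cfg), cfg, sprintf("fix_%02d", i))
      })
      ecfg <- extractor_config(input_side = 32L, width_mult = 1 / 16,
                               fc_sizes = c(64L, 64L, 128L), dropout_rate = 0.2,
                               lr_init = 1e-3, lr_decay_epochs = integer(0),
                               max_epochs = 2L, batch_size = 4L, seed = 7L)
      cache <<- list(cases = cases, config = ecfg,
                     model = train_extractor(cases, ecfg))
    }
    cache
  }
})

# exhaustive best-subset RSS search of a fixed size (tiny p only)
best_subset_rss <- function(X, y, size) {
  combs <- utils::combn(ncol(X), size, simplify = FALSE)
  rss <- vapply(combs, function(s) {
    fit <- stats::lm.fit(cbind(1, X[, s, drop = FALSE]), y)
    sum(fit$residuals^2)
  }, 0)
  sort(combs[[which.min(rss)]])
}

# reader records for a synthetic two-session observer study
make_observer_records <- function(n_cases = 40L, n_readers = 3L,
                                  sd_unaided = 0.45, sd_aided = 0.18,
                                  seed = 1L) {
  set.seed(seed)
  ids <- sprintf("case_%02d", seq_len(n_cases))
  truth <- stats::setNames(
    sample(c("benign", "malignant"), n_cases, TRUE), ids)
  y <- as.numeric(truth == "malignant")
  out <- list()
  for (r in seq_len(n_readers))
    for (s in c("unaided", "aided")) {
      sdv <- if (s == "unaided") sd_unaided else sd_aided
      pom <- pmin(pmax(y + stats::rnorm(n_cases, 0, sdv), 0), 1)
      out[[length(out) + 1L]] <- data.frame(
        reader_id = paste0("R", r), session = s, case_id = ids,
        birads = sample(c("2", "3", "4a", "4b", "5"), n_cases, TRUE),
        call = ifelse(pom > 0.5, "malignant", "benign"),
        pom = pom, time_s = stats::runif(n_cases, 20, 90),
        stringsAsFactors = FALSE)
    }
  list(records = do.call(rbind, out), truth = truth)
}
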