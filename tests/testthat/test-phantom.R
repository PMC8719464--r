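cfg64 <- phantom_config()

test_that("descriptor sampling is reproducible and follows its marginals", {
  set.seed(3); a <- sample_descriptors(cfg64)
  set.seed(3); b <- sample_descriptors(cfg64)
  expect_identical(a, b)
  degenerate <- phantom_config(descriptor_probs = list(
    shape = c(1, 0), margin = c(1, 0, 0), micro = c(1, 0), spic = c(1, 0),
    density = c(1, 0, 0)))
  set.seed(1)
  for (i in 1:5)
    expect_equal(as.numeric(sample_descriptors(degenerate)), rep(0, 5))
  set.seed(11)
  shapes <- replicate(10000, sample_descriptors(cfg64)[["shape_code"]])
  expect_lt(abs(mean(shapes == 0) - 0.5), 0.02)
  set.seed(12)
  margins <- replicate(10000, sample_descriptors(cfg64)[["margin_sharpness_code"]])
  for (lev in c(0, 0.5, 1))
    expect_lt(abs(mean(margins == lev) - 1 / 3), 0.02)
})

test_that("rendering is deterministic and the mask honours the patch contract", {
  set.seed(5)
  c1 <- render_case(descriptor_vector(c(1, 0.5, 1, 1, 1)), cfg64, "x")
  set.seed(5)
  c2 <- render_case(descriptor_vector(c(1, 0.5, 1, 1, 1)), cfg64, "x")
  expect_identical(c1$patches$CC$image, c2$patches$CC$image)
  expect_identical(c1$patches$MLO$mask, c2$patches$MLO$mask)
  for (v in c("CC", "MLO")) {
    p <- c1$patches[[v]]
    expect_identical(dim(p$image), dim(p$mask))
    expect_gte(sum(p$mask), 1)
    expect_true(all(p$image >= 0 & p$image <= 1))
    expect_true(all(p$mask %in% c(0, 1)))
  }
  # two views are independent renders sharing one descriptor vector
  expect_false(identical(c1$patches$CC$mask, c1$patches$MLO$mask))
})

test_that("generated patches satisfy the invariants over random configurations", {
  set.seed(99)
  for (rep in 1:200) {
    cfg <- phantom_config(
      patch_side = sample(c(32L, 64L), 1),
      blur_sigmas = sort(stats::runif(3, 0.1, 3)),
      contrast_levels = stats::runif(3, 0.1, 0.5),
      background_noise_scale = stats::runif(1, 0.01, 0.08))
    d <- sample_descriptors(cfg)
    p <- render_case(d, cfg, "r")$patches$CC
    expect_identical(dim(p$image), dim(p$mask))
    expect_gte(sum(p$mask), 1)
    # single connected component
    expect_equal(max(EBImage::bwlabel(EBImage::Image(p$mask))), 1)
  }
})

test_that("an all-benign lesion with minimal blur is nearly circular", {
  cfg <- phantom_config(blur_sigmas = c(0.01, 0.02, 0.03))
  set.seed(8)
  m <- render_case(descriptor_vector(rep(0, 5)), cfg, "c")$patches$CC$mask
  f <- EBImage::computeFeatures.shape(EBImage::Image(m))
  circularity <- 4 * pi * f[1, "s.area"] / f[1, "s.perimeter"]^2
  expect_gte(circularity, 0.9)
})

test_that("spiculation roughens the boundary and margin code softens the edge", {
  for (s in 1:10) {
    set.seed(s)
    plain <- render_case(descriptor_vector(c(0, 0, 0, 0, 0)), cfg64, "a")
    set.seed(s)
    spic <- render_case(descriptor_vector(c(0, 0, 0, 1, 0)), cfg64, "a")
    expect_gt(mask_perimeter2_over_area(spic$patches$CC$mask),
              mask_perimeter2_over_area(plain$patches$CC$mask))
    set.seed(s)
    lobed <- render_case(descriptor_vector(c(0, 0, 1, 0, 0)), cfg64, "a")
    expect_gt(mask_perimeter2_over_area(lobed$patches$CC$mask),
              mask_perimeter2_over_area(plain$patches$CC$mask))
    set.seed(s)
    soft <- render_case(descriptor_vector(c(0, 0.5, 0, 0, 0)), cfg64, "a")
    expect_lt(boundary_gradient(soft$patches$CC$image, soft$patches$CC$mask),
              boundary_gradient(plain$patches$CC$image, plain$patches$CC$mask))
  }
})

test_that("physics is monotone in the descriptor codes on seed averages", {
  n_seeds <- 50
  grad <- matrix(0, n_seeds, 3)
  sol <- matrix(0, n_seeds, 2)
  contrast <- matrix(0, n_seeds, 3)
  for (s in seq_len(n_seeds)) {
    for (i in 1:3) {
      set.seed(1000 + s)
      p <- render_case(descriptor_vector(c(0, (i - 1) / 2, 0, 0, 0)), cfg64,
                       "m")$patches$CC
      grad[s, i] <- boundary_gradient(p$image, p$mask)
      set.seed(2000 + s)
      q <- render_case(descriptor_vector(c(0, 0, 0, 0, (i - 1) / 2)), cfg64,
                       "m")$patches$CC
      contrast[s, i] <- mean(q$image[q$mask == 1]) - mean(q$image[q$mask == 0])
    }
    for (i in 1:2) {
      set.seed(3000 + s)
      p <- render_case(descriptor_vector(c(0, 0, 0, i - 1, 0)), cfg64,
                       "m")$patches$CC
      sol[s, i] <- mask_solidity(p$mask)
    }
  }
  expect_true(all(diff(colMeans(grad)) < 0))       # blur grows with margin code
  expect_lt(mean(sol[, 2]), mean(sol[, 1]))        # spiculation cuts solidity
  expect_true(all(diff(colMeans(contrast)) > 0))   # density raises contrast
})

test_that("the label model is balanced and strongly descriptor-driven", {
  set.seed(21)
  labels <- replicate(2000, {
    d <- sample_descriptors(cfg64)
    assign_label(d, cfg64)
  })
  expect_lt(abs(mean(labels == "malignant") - 0.5), 0.05)
  set.seed(22)
  p1 <- mean(replicate(2000, assign_label(descriptor_vector(rep(1, 5)), cfg64)) == "malignant")
  p0 <- mean(replicate(2000, assign_label(descriptor_vector(rep(0, 5)), cfg64)) == "malignant")
  expect_gt(p1 - p0, 0.5)
  # degenerate weights
  flat <- phantom_config(malignancy_logit_weights = rep(0, 6))
  set.seed(23)
  p <- mean(replicate(2000, assign_label(descriptor_vector(rep(0, 5)), flat)) == "malignant")
  expect_lt(abs(p - 0.5), 0.04)
})

test_that("dataset generation reproduces itself and honours exact split sizes", {
  cfg <- phantom_config(n_cases = 416L, seed = 30L,
                        split = c(train = 214L, test = 202L))
  ds <- generate_dataset(cfg)
  sizes <- table(ds$manifest$split[!duplicated(ds$manifest$case_id)])
  expect_equal(unname(sizes[["train"]]), 214L)
  expect_equal(unname(sizes[["test"]]), 202L)
  ds2 <- generate_dataset(cfg)
  expect_identical(ds$manifest, ds2$manifest)
  expect_error(phantom_config(split = c(train = 0.7, test = 0.6)),
               "sum")
  expect_error(generate_dataset(phantom_config(n_cases = 1L)), "n_cases")
})

test_that("oversize lesions raise a geometry error", {
  big <- phantom_config(lesion_radius_frac = 0.45)
  set.seed(4)
  expect_error(render_case(descriptor_vector(c(1, 0, 1, 1, 1)), big, "g"),
               "geometry error")
  expect_error(phantom_config(lesion_radius_frac = -1), "positive")
})
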