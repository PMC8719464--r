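test_that("stepwise selection recovers a planted support and rejects pure noise", {
  set.seed(31)
  n <- 200; p <- 20
  X <- matrix(rnorm(n * p), n)
  beta <- c(rep(1, 5), rep(0, p - 5))
  y <- drop(X %*% beta) + rnorm(n, 0, 0.1)
  sel <- stepwise_select(X, y)
  expect_true(all(1:5 %in% sel$selected))
  # replay: the trace reconstructs the same subset
  replay <- integer(0)
  for (i in seq_len(nrow(sel$trace))) {
    if (sel$trace$action[i] == "add") replay <- c(replay, sel$trace$index[i])
    else replay <- setdiff(replay, sel$trace$index[i])
  }
  expect_equal(sort(replay), sel$selected)
  # pure noise: selections stay near the p_enter * p false-entry rate
  set.seed(32)
  ynoise <- rnorm(n)
  seln <- stepwise_select(X, ynoise)
  expect_lte(length(seln$selected), 3L)
  # zero-variance features can never enter
  sel0 <- stepwise_select(matrix(1, 50, 4), rnorm(50))
  expect_length(sel0$selected, 0L)
  expect_error(stepwise_select(X, y, p_enter = 0.2, p_remove = 0.1), "p_enter")
  expect_error(stepwise_select(X[1:3, ], y[1:3]), "rank error")
})

test_that("stepwise agrees with exhaustive best-subset search on easy instances", {
  for (s in 1:5) {
    set.seed(50 + s)
    n <- 80
    X <- matrix(rnorm(n * 6), n)
    y <- X[, 2] + 0.8 * X[, 5] + rnorm(n, 0, 0.15)
    sel <- stepwise_select(X, y)$selected
    expect_equal(sel, best_subset_rss(X, y, length(sel)))
  }
})

test_that("LDA matches the analytic equal-variance Gaussian posterior", {
  set.seed(41)
  n <- 4000
  x <- c(rnorm(n, 0, 1), rnorm(n, 1, 1))
  y <- rep(c(0, 1), each = n)
  m <- fit_lda(matrix(x, ncol = 1), y)
  grid <- matrix(seq(-2, 3, by = 0.25), ncol = 1)
  expect_lt(max(abs(predict_lda(m, grid) - stats::plogis(grid[, 1] - 0.5))),
            0.02)
  # equidistant point with equal priors
  mu <- fit_lda(matrix(c(rnorm(500, -1), rnorm(500, 1)), ncol = 1),
                rep(c(0, 1), each = 500), priors = "uniform")
  expect_equal(predict_lda(mu, matrix(mean(mu$means))), 0.5, tolerance = 1e-9)
})

test_that("LDA agrees with the reference implementation and handles degeneracy", {
  skip_if_not_installed("MASS")
  set.seed(42)
  X <- matrix(rnorm(300 * 3), 300)
  y <- rbinom(300, 1, stats::plogis(X[, 1]))
  m <- fit_lda(X, y)
  ref <- MASS::lda(X, grouping = y)
  post <- predict(ref, X)$posterior[, "1"]
  expect_lt(max(abs(predict_lda(m, X) - post)), 1e-8)
  # linearly separable toy data: training AUC 1
  Xs <- matrix(c(rnorm(40, -4), rnorm(40, 4)), ncol = 1)
  ys <- rep(c(0, 1), each = 40)
  ms <- fit_lda(Xs, ys)
  expect_equal(roc_from_poms(predict_lda(ms, Xs), ys)$auc, 1.0)
  # singular covariance gets regularized rather than failing
  Xd <- cbind(rnorm(100), 0)
  Xd[, 2] <- Xd[, 1]                       # perfectly collinear
  expect_s3_class(fit_lda(Xd, rep(c(0, 1), 50)), "lda_model")
  expect_error(fit_lda(X, rep(1, 300)), "class error")
  expect_error(predict_lda(m, matrix(0, 1, 2)), "contract error")
})

test_that("view POMs average into case POMs", {
  expect_equal(case_pom(c(0.4, 0.6))$pom, 0.5)
  expect_equal(case_pom(0.7)$pom, 0.7)
  expect_equal(case_pom(c(0.2, 0.2))$pom, 0.2)
  expect_error(case_pom(numeric(0)), "at least one")
})

test_that("fold assignment is balanced, case-level and reproducible", {
  labels <- rep(c("benign", "malignant"), c(109, 105))
  set.seed(60)
  f <- make_folds(labels, 10)
  expect_setequal(unique(f), 1:10)
  expect_true(all(table(f) %in% c(21, 22)))
  # stratification: class balance within each fold off by at most 2
  tab <- table(f, labels)
  expect_true(all(abs(tab[, 1] - 109 / 10) < 2))
  set.seed(60)
  expect_identical(make_folds(labels, 10), f)
  expect_error(make_folds(labels, 1), "K")
  expect_error(make_folds(labels[1:5], 10), "exceeds")
})

test_that("cross-validation trains one member per fold without leaking views", {
  set.seed(70)
  cfgp <- phantom_config(patch_side = 32L)
  cases <- lapply(1:12, function(i) {
    set.seed(900 + i)
    cs <- render_case(sample_descriptors(cfgp), cfgp, sprintf("cv%02d", i))
    # ensure both labels occur
    cs$label <- if (i %% 2 == 0) "malignant" else "benign"
    cs
  })
  ecfg <- extractor_config(input_side = 32L, width_mult = 1 / 16,
                           fc_sizes = c(64L, 64L, 128L), dropout_rate = 0.2,
                           lr_init = 1e-3, lr_decay_epochs = integer(0),
                           max_epochs = 2L, batch_size = 4L, seed = 8L)
  ens <- crossval_train(cases, K = 3, extractor_cfg = ecfg, seed = 12L)
  expect_length(ens$members, 3L)
  expect_setequal(names(ens$fold_assignment),
                  vapply(cases, `[[`, "", "case_id"))
  expect_setequal(unique(ens$fold_assignment), 1:3)
  # determinism of the fold assignment
  ens2 <- crossval_train(cases[1:6], K = 2, extractor_cfg = ecfg, seed = 12L)
  ens3 <- crossval_train(cases[1:6], K = 2, extractor_cfg = ecfg, seed = 12L)
  expect_identical(ens2$fold_assignment, ens3$fold_assignment)
  expect_error(crossval_train(cases[1:2], K = 5, extractor_cfg = ecfg), "K")

  # fused POM is the member mean and never widens the member range
  cs <- cases[[1]]
  member_poms <- vapply(ens$members, function(m)
    mean(vapply(cs$patches, function(p) score_lesion(m, p), 0)), 0)
  fused <- fused_pom(ens, cs)
  expect_equal(fused$pom, mean(member_poms))
  expect_gte(fused$pom, min(member_poms))
  expect_lte(fused$pom, max(member_poms))
  expect_gte(fused$pom, 0); expect_lte(fused$pom, 1)

  # a broken member is reported by index
  broken <- ens
  broken$members[[2]]$selection$selected <- 999L
  expect_error(fused_pom(broken, cs), "member 2")

  # ensembles round-trip through their on-disk layout
  dir <- file.path(tempdir(), "ens_rt")
  save_ensemble(ens, dir)
  back <- load_ensemble(dir)
  expect_equal(back$K, ens$K)
  expect_equal(back$fold_assignment, ens$fold_assignment)
  expect_equal(fused_pom(back, cs)$pom, fused$pom)
})

test_that("lesion scoring is deterministic and monotone in the discriminant", {
  fix <- tiny_extractor_fixture()
  feats <- t(vapply(fix$cases, function(cs)
    extract_features(fix$model, cs$patches$CC), numeric(128)))
  y <- rep(c(0, 1), 3)
  sel <- structure(list(selected = 1:4,
                        trace = data.frame()), class = "selection_result")
  lda <- fit_lda(feats[, 1:4], y)
  member <- list(extractor = fix$model, selection = sel, lda = lda)
  p1 <- score_lesion(member, fix$cases[[1]]$patches$CC)
  expect_identical(p1, score_lesion(member, fix$cases[[1]]$patches$CC))
  expect_gte(p1, 0); expect_lte(p1, 1)
  # POM ordering follows the linear discriminant score
  set.seed(90)
  Z <- matrix(rnorm(100 * 4), 100)
  w <- drop(lda$cov_inv %*% (lda$means["malignant", ] - lda$means["benign", ]))
  expect_equal(order(predict_lda(lda, Z)), order(Z %*% w))
})
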