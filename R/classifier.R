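#' Forward-backward stepwise feature selection by partial-F tests
#'
#' Classical stepwise regression of the 0/1 label on the feature columns
#' (MATLAB stepwisefit semantics): a candidate enters when the partial-F
#' p-value of adding it to the current linear model is below `p_enter`
#' (ties broken by lowest p, then lowest column index); an included
#' variable leaves when its removal p-value exceeds `p_remove`. Terminates
#' when no move is possible. Deterministic given its inputs.
#'
#' @param features Numeric matrix (n x p).
#' @param labels Binary labels (0/1, logical, or "benign"/"malignant"), or a
#'   continuous response for plain stepwise regression.
#' @param p_enter Entry threshold (default 0.05).
#' @param p_remove Removal threshold (default 0.10); must be >= p_enter.
#' @return A `selection_result`: `selected` (sorted unique indices) and
#'   `trace` (step, action, index, p_value) replayable to the same subset.
#' @export
stepwise_select <- function(features, labels, p_enter = 0.05, p_remove = 0.10) {
  X <- as.matrix(features)
  y <- if (is.numeric(labels) && !all(labels %in% c(0, 1)))
    as.numeric(labels)                  # continuous response: plain regression
  else as_binary_label(labels)
  n <- nrow(X); p <- ncol(X)
  if (p_enter > p_remove)
    stop("p_enter must be <= p_remove", call. = FALSE)
  if (n < 4L)
    stop("rank error: too few samples for stepwise selection", call. = FALSE)
  sel <- integer(0)
  trace <- list()
  step_i <- 0L
  repeat {
    moved <- FALSE
    # ---- forward: project candidates off the current model ----
    df <- n - length(sel) - 2L
    if (df >= 1L && length(sel) < p) {
      Q <- qr.Q(qr(cbind(1, X[, sel, drop = FALSE])))
      r <- y - Q %*% crossprod(Q, y)
      rss <- sum(r^2)
      cand <- setdiff(seq_len(p), sel)
      Xc <- X[, cand, drop = FALSE]
      Xt <- Xc - Q %*% crossprod(Q, Xc)
      ss <- colSums(Xt^2)
      num <- drop(crossprod(Xt, r))^2 / pmax(ss, 1e-300)
      rss_new <- pmax(rss - num, 0)
      ok <- ss > max(1e-10 * n, 1e-12)       # constant/aliased columns never enter
      pv <- rep(1, length(cand))
      fstat <- num / (rss_new / df)
      pv[ok] <- stats::pf(fstat[ok], 1, df, lower.tail = FALSE)
      if (any(pv < p_enter)) {
        best <- which(pv == min(pv))[1L]      # lowest p, then lowest index
        sel <- c(sel, cand[best])
        step_i <- step_i + 1L
        trace[[step_i]] <- data.frame(step = step_i, action = "add",
                                      index = cand[best], p_value = pv[best])
        moved <- TRUE
      }
    }
    # ---- backward: removal p-values from the current fit ----
    if (length(sel) > 0L) {
      fit <- stats::lm.fit(cbind(1, X[, sel, drop = FALSE]), y)
      dfres <- n - length(sel) - 1L
      if (dfres >= 1L) {
        rss <- sum(fit$residuals^2)
        R <- qr.R(fit$qr)
        xtx_inv_diag <- diag(chol2inv(R))[-1L]
        se <- sqrt(pmax(xtx_inv_diag, 0) * rss / dfres)
        tstat <- fit$coefficients[-1L] / se
        pv_out <- 2 * stats::pt(abs(tstat), dfres, lower.tail = FALSE)
        pv_out[!is.finite(pv_out)] <- 1
        if (any(pv_out > p_remove)) {
          worst <- which(pv_out == max(pv_out))[1L]
          idx <- sel[worst]
          sel <- sel[-worst]
          step_i <- step_i + 1L
          trace[[step_i]] <- data.frame(step = step_i, action = "drop",
                                        index = idx, p_value = pv_out[worst])
          moved <- TRUE
        }
      }
    }
    if (!moved || step_i > 10L * p) break
  }
  structure(list(selected = sort(unique(sel)),
                 trace = if (length(trace)) do.call(rbind, trace)
                         else data.frame(step = integer(), action = character(),
                                         index = integer(), p_value = numeric())),
            class = "selection_result")
}

as_binary_label <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- setdiff(unique(labels), c("benign", "malignant"))
    if (length(bad))
      stop("labels must be benign/malignant or 0/1", call. = FALSE)
    return(as.numeric(labels == "malignant"))
  }
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1)))
    stop("labels must be benign/malignant or 0/1", call. = FALSE)
  labels
}

#' Fit a two-class linear discriminant model
#'
#' Equal-covariance Gaussian discriminant on lesion-wise (view-level)
#' samples: class means, pooled covariance and class priors. A singular
#' pooled covariance is regularized by adding eps * I with
#' eps = 1e-6 * trace / d.
#'
#' @param features Numeric matrix (n x d) of selected features.
#' @param labels Binary labels (see [stepwise_select()]); "malignant" / 1
#'   is the positive class.
#' @param priors "empirical" (class frequencies, default) or "uniform".
#' @return An `lda_model`: means (2 x d), pooled covariance, priors.
#' @export
fit_lda <- function(features, labels, priors = c("empirical", "uniform")) {
  priors <- match.arg(priors)
  X <- as.matrix(features)
  y <- as_binary_label(labels)
  if (length(unique(y)) < 2L)
    stop("class error: both classes must be present", call. = FALSE)
  d <- ncol(X); n <- nrow(X)
  mu0 <- colMeans(X[y == 0, , drop = FALSE])
  mu1 <- colMeans(X[y == 1, , drop = FALSE])
  c0 <- X[y == 0, , drop = FALSE]; c0 <- sweep(c0, 2, mu0)
  c1 <- X[y == 1, , drop = FALSE]; c1 <- sweep(c1, 2, mu1)
  Sp <- (crossprod(c0) + crossprod(c1)) / (n - 2)
  pri <- if (priors == "uniform") c(0.5, 0.5)
         else c(mean(y == 0), mean(y == 1))
  Sinv <- tryCatch(solve(Sp), error = function(e) NULL)
  if (is.null(Sinv) || !all(is.finite(Sinv)) || rcond(Sp) < 1e-12) {
    eps <- 1e-6 * sum(diag(Sp)) / d
    if (eps <= 0) eps <- 1e-6
    Sp <- Sp + diag(eps, d)
    Sinv <- solve(Sp)
  }
  structure(list(means = rbind(benign = mu0, malignant = mu1),
                 cov = Sp, cov_inv = Sinv,
                 priors = stats::setNames(pri, c("benign", "malignant")),
                 classes = c("benign", "malignant")),
            class = "lda_model")
}

#' Posterior probability of malignancy under an LDA model
#'
#' @param model An `lda_model`.
#' @param features Numeric matrix (n x d) or vector (length d).
#' @return Numeric vector of POMs in [0, 1].
#' @export
predict_lda <- function(model, features) {
  X <- if (is.null(dim(features))) matrix(features, nrow = 1L)
       else as.matrix(features)
  if (ncol(X) != ncol(model$means))
    stop("contract error: feature length does not match the model", call. = FALSE)
  disc <- function(mu, prior)
    drop(X %*% (model$cov_inv %*% mu)) -
      0.5 * drop(t(mu) %*% model$cov_inv %*% mu) + log(prior)
  d0 <- disc(model$means["benign", ], model$priors[["benign"]])
  d1 <- disc(model$means["malignant", ], model$priors[["malignant"]])
  stats::plogis(d1 - d0)
}

#' Score one lesion view with an ensemble member
#'
#' Extracts perceptive features from the patch, subsets them to the
#' member's selected indices and returns the LDA posterior probability of
#' malignancy.
#'
#' @param member A list with elements `extractor` (a `trained_extractor`),
#'   `selection` (a `selection_result`) and `lda` (an `lda_model`).
#' @param patch A `lesion_patch`.
#' @return POM in [0, 1].
#' @export
score_lesion <- function(member, patch) {
  feats <- extract_features(member$extractor, patch)
  sel <- member$selection$selected
  if (length(sel) == 0L || max(sel) > length(feats))
    stop("contract error: selection does not fit the feature vector",
         call. = FALSE)
  unname(predict_lda(member$lda, feats[sel]))
}

#' Case-level probability of malignancy from view-level POMs
#'
#' The malignancy probabilities of the available views (CC, MLO) of one
#' case are averaged for case-wise evaluation.
#'
#' @param view_poms Numeric vector of per-view POMs (>= 1).
#' @param case_id Optional identifier.
#' @return A `pom_score`: case_id and pom.
#' @export
case_pom <- function(view_poms, case_id = NA_character_) {
  if (length(view_poms) == 0L)
    stop("case_pom needs at least one view POM", call. = FALSE)
  structure(list(case_id = case_id, pom = mean(view_poms)),
            class = "pom_score")
}

#' Assign cases to cross-validation folds
#'
#' Case-level assignment (both views of a case share a fold). Stratified by
#' label by default: within each class, fold counts differ by at most one,
#' and extra cases go to the currently smallest folds so the overall fold
#' sizes also differ by at most one.
#'
#' @param labels Per-case labels (used for stratification), or a bare count
#'   via `rep(NA, n)` when `stratify = FALSE`.
#' @param K Number of folds (>= 2, <= number of cases).
#' @param stratify Stratify by label (default TRUE).
#' @return Integer vector of fold ids in 1..K.
#' @export
make_folds <- function(labels, K = 10L, stratify = TRUE) {
  n <- length(labels)
  if (K < 2L) stop("K must be >= 2", call. = FALSE)
  if (K > n) stop("K exceeds the number of cases", call. = FALSE)
  fold <- integer(n)
  totals <- numeric(K)
  groups <- if (stratify) split(seq_len(n), as.character(labels))
            else list(all = seq_len(n))
  for (g in groups) {
    g <- sample(g)                       # random order within class
    base <- length(g) %/% K
    extra <- length(g) %% K
    counts <- rep(base, K)
    if (extra > 0) {
      # extras to the smallest folds so overall sizes stay within 1
      ord <- order(totals + stats::runif(K) * 1e-9)
      counts[ord[seq_len(extra)]] <- base + 1L
    }
    fold[g] <- rep.int(seq_len(K), counts)
    totals <- totals + counts
  }
  fold
}

#' Train the k-fold cross-validation ensemble
#'
#' Randomly divides the training cases into K folds (case level, stratified
#' by pathology label by default). For each fold, Stage 1 (the feature
#' extractor) is trained on the other K-1 folds, features of the training
#' views are extracted, Stage 2 (stepwise selection + LDA) is fitted on
#' them lesion-wise, and the held-out fold serves as validation. After K
#' repetitions every case was validation exactly once and K member models
#' are obtained.
#'
#' @param cases List of `cad_case` training cases.
#' @param K Number of folds (default 10).
#' @param extractor_cfg An `extractor_config`; each member trains with seed
#'   `extractor_cfg$seed + fold`.
#' @param p_enter,p_remove Stepwise thresholds.
#' @param priors LDA priors ("empirical" or "uniform").
#' @param stratify Stratify folds by label (default TRUE).
#' @param seed Seed for the fold assignment.
#' @return An `ensemble_model`: `members` (K lists of extractor, selection,
#'   lda, fold), `fold_assignment` (named by case id), `K`.
#' @export
crossval_train <- function(cases, K = 10L, extractor_cfg = extractor_test_profile(),
                           p_enter = 0.05, p_remove = 0.10,
                           priors = "empirical", stratify = TRUE, seed = 1L) {
  if (K > length(cases))
    stop("K exceeds the number of cases", call. = FALSE)
  labels <- vapply(cases, `[[`, "", "label")
  set.seed(seed)
  fold <- make_folds(labels, K, stratify = stratify)
  names(fold) <- vapply(cases, `[[`, "", "case_id")
  members <- vector("list", K)
  for (k in seq_len(K)) {
    tr_cases <- cases[fold != k]
    cfg <- extractor_cfg
    cfg$seed <- extractor_cfg$seed + k
    extractor <- train_extractor(tr_cases, cfg,
                                 validation_cases = cases[fold == k])
    tt <- cases_to_tensors(tr_cases, cfg)
    feats <- cpp_cnn_forward(as.numeric(tt$X), nrow(tt$meta),
                             extractor$weights, arch_list(cfg))$features
    y <- tt$meta$label
    selection <- stepwise_select(feats, y, p_enter, p_remove)
    sel <- selection$selected
    if (length(sel) == 0L)               # degenerate fold: keep the single
      sel <- selection$selected <- which.max(apply(feats, 2, stats::var))
    lda <- fit_lda(feats[, sel, drop = FALSE], y, priors = priors)
    members[[k]] <- list(extractor = extractor, selection = selection,
                         lda = lda, fold = k)
  }
  structure(list(members = members, fold_assignment = fold, K = K),
            class = "ensemble_model")
}

#' Fused (ensemble-averaged) probability of malignancy for a case
#'
#' Each member scores both views of the case; the view POMs are averaged
#' per member (case-wise score), then the member scores are averaged.
#'
#' @param ensemble An `ensemble_model`.
#' @param case A `cad_case`.
#' @return A `pom_score`.
#' @export
fused_pom <- function(ensemble, case) {
  member_poms <- vapply(seq_along(ensemble$members), function(k) {
    member <- ensemble$members[[k]]
    tryCatch({
      vp <- vapply(case$patches, function(p) score_lesion(member, p), 0)
      case_pom(vp, case$case_id)$pom
    }, error = function(e)
      stop(sprintf("ensemble member %d failed: %s", k, conditionMessage(e)),
           call. = FALSE))
  }, 0)
  case_pom(member_poms, case$case_id)
}

#' Score a list of cases with a fused ensemble
#'
#' @param ensemble An `ensemble_model`.
#' @param cases List of `cad_case`.
#' @return data.frame(case_id, label, pom).
#' @export
ensemble_scores <- function(ensemble, cases) {
  do.call(rbind, lapply(cases, function(cs)
    data.frame(case_id = cs$case_id, label = cs$label %||% NA_character_,
               pom = fused_pom(ensemble, cs)$pom, stringsAsFactors = FALSE)))
}

#' Save / load an ensemble as a directory of member archives + fold map
#'
#' @param ensemble An `ensemble_model`.
#' @param dir Directory (created if needed).
#' @return `dir` (save) or the ensemble (load).
#' @export
save_ensemble <- function(ensemble, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(ensemble$members))
    saveRDS(ensemble$members[[k]], file.path(dir, sprintf("member_%02d.rds", k)))
  jsonlite::write_json(as.list(ensemble$fold_assignment),
                       file.path(dir, "fold_map.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  files <- sort(list.files(dir, pattern = "^member_\\d+\\.rds$",
                           full.names = TRUE))
  members <- lapply(files, readRDS)
  fm <- unlist(jsonlite::read_json(file.path(dir, "fold_map.json")))
  structure(list(members = members,
                 fold_assignment = stats::setNames(as.integer(fm), names(fm)),
                 K = length(members)),
            class = "ensemble_model")
}
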