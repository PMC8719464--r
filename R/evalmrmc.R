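# Observer-study (multi-reader multi-case) analytics: per-reader ROC/AUC
# from probability-of-malignancy scores, reader-averaged AUC comparison,
# binary metrics with confusion reconstruction from printed rates, BI-RADS
# change tabulation, and diagnosis-time comparison.

#' Round half-up to a fixed number of decimals
#'
#' Matches the rounding convention of printed clinical tables (0.8505 ->
#' 0.851), unlike base `round()`'s round-half-even.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Numeric.
#' @export
round_half_up <- function(x, digits = 3L) {
  floor(x * 10^digits + 0.5 + 1e-12) / 10^digits
}

as_truth <- function(truth) {
  y <- as_binary_label(truth)
  if (length(unique(y)) < 2L)
    stop("undefined-ROC error: both classes must be present", call. = FALSE)
  y
}

#' ROC curve and AUC from probability-of-malignancy scores
#'
#' Threshold sweep over the ranked POMs: at the threshold of each ranked
#' unique POM, cases at or above it are called malignant, giving one
#' (FPR, TPR) point; the curve runs from (0, 0) to (1, 1) and the AUC is
#' the trapezoidal area. Tied scores contribute half credit, so the AUC
#' equals the Mann-Whitney U statistic.
#'
#' @param poms Numeric scores (any monotone scale).
#' @param truth Binary labels ("benign"/"malignant", 0/1 or logical).
#' @return A `roc_curve`: thresholds (ascending ranked unique POMs), fpr,
#'   tpr (nondecreasing 0 -> 1, ordered by descending threshold), auc.
#' @export
roc_from_poms <- function(poms, truth) {
  y <- as_truth(truth)
  if (any(!is.finite(poms)))
    stop("POMs must be finite", call. = FALSE)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  thr_desc <- sort(unique(poms), decreasing = TRUE)
  tp <- vapply(thr_desc, function(t) sum(poms >= t & y == 1), 0)
  fp <- vapply(thr_desc, function(t) sum(poms >= t & y == 0), 0)
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = rev(thr_desc), fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d thresholds, AUC %.3f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

check_crossed <- function(records, session, case_ids) {
  rec <- records[records$session == session, , drop = FALSE]
  readers <- unique(rec$reader_id)
  gaps <- character(0)
  for (r in readers) {
    have <- rec$case_id[rec$reader_id == r]
    miss <- setdiff(case_ids, have)
    if (length(miss))
      gaps <- c(gaps, sprintf("reader %s misses cases %s in session %s",
                              r, paste(miss, collapse = ","), session))
    if (anyDuplicated(have))
      gaps <- c(gaps, sprintf("reader %s has duplicate cases in session %s",
                              r, session))
  }
  if (length(gaps))
    stop("design error (MRMC must be fully crossed): ",
         paste(gaps, collapse = "; "), call. = FALSE)
  rec
}

#' Per-reader and reader-averaged AUC for one session
#'
#' Every reader must have scored every case of the session (fully crossed
#' MRMC design). The averaged AUC is the arithmetic mean over readers.
#'
#' @param records Reader records: data.frame with reader_id, session,
#'   case_id, pom (percent 0-100 or probability).
#' @param truth Named vector or data.frame(case_id, pathology) of
#'   biopsy-proven labels.
#' @param session "unaided" or "aided".
#' @return List with `per_reader` (named AUCs), `average` and `average_3dp`
#'   (rounded half-up to 3 decimals for reporting).
#' @export
reader_average_auc <- function(records, truth, session = c("unaided", "aided")) {
  session <- match.arg(session)
  truth <- truth_vector(truth)
  rec <- check_crossed(records, session, names(truth))
  readers <- sort(unique(rec$reader_id))
  aucs <- vapply(readers, function(r) {
    rr <- rec[rec$reader_id == r, ]
    roc_from_poms(rr$pom, truth[rr$case_id])$auc
  }, 0)
  names(aucs) <- readers
  list(per_reader = aucs, average = mean(aucs),
       average_3dp = round_half_up(mean(aucs), 3L))
}

truth_vector <- function(truth) {
  if (is.data.frame(truth)) {
    v <- stats::setNames(truth$pathology, truth$case_id)
  } else v <- truth
  if (is.null(names(v)))
    stop("truth must be named by case_id", call. = FALSE)
  v
}

#' Aided-vs-unaided reader-averaged AUC comparison with bootstrap inference
#'
#' Point estimate: aided minus unaided reader-averaged AUC. Uncertainty by
#' case-level bootstrap with readers fixed (cases resampled with
#' replacement, both sessions recomputed on the same resample), percentile
#' interval and a two-sided bootstrap p-value for the null of no
#' difference.
#'
#' @param records Reader records with both sessions (see
#'   [reader_average_auc()]).
#' @param truth Case truth (named vector or data.frame).
#' @param n_boot Bootstrap replicates (a note is emitted below 100).
#' @param seed RNG seed.
#' @return List: difference, per-session averages, ci (2.5/97.5
#'   percentiles), p_value, n_boot.
#' @export
auc_difference_test <- function(records, truth, n_boot = 2000L, seed = 1L) {
  truth <- truth_vector(truth)
  ids <- names(truth)
  un <- reader_average_auc(records, truth, "unaided")
  ai <- reader_average_auc(records, truth, "aided")
  diff_hat <- ai$average - un$average
  if (n_boot < 100L)
    message("note: n_boot < 100; bootstrap inference will be unstable")
  y <- as_truth(truth)
  # index records once per reader x session for fast resampling
  split_rec <- split(records, list(records$reader_id, records$session),
                     drop = TRUE)
  split_rec <- lapply(split_rec, function(d)
    stats::setNames(d$pom, d$case_id))
  sessions <- sub("^.*\\.", "", names(split_rec))
  set.seed(seed)
  boot <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    repeat {
      take <- sample(ids, length(ids), replace = TRUE)
      if (length(unique(y[match(take, ids)])) == 2L) break
    }
    tb <- truth[take]
    means <- c(unaided = 0, aided = 0)
    for (s in c("unaided", "aided")) {
      ks <- which(sessions == s)
      means[s] <- mean(vapply(ks, function(k)
        roc_from_poms(split_rec[[k]][take], tb)$auc, 0))
    }
    boot[b] <- means["aided"] - means["unaided"]
  }
  p <- min(1, 2 * min(mean(boot <= 0), mean(boot >= 0)))
  list(difference = diff_hat, unaided = un$average, aided = ai$average,
       ci = stats::quantile(boot, c(0.025, 0.975), names = FALSE),
       p_value = p, n_boot = n_boot)
}

#' Construct a confusion-count object
#'
#' @param tp,fp,tn,fn Nonnegative integer counts.
#' @return A `confusion_counts` list.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be nonnegative integers", call. = FALSE)
  structure(as.list(counts), class = "confusion_counts")
}

#' Sensitivity, specificity, PPV and NPV from confusion counts
#'
#' Full precision is retained in `raw`; `rounded` is half-up to 3 decimals
#' for report output. A zero denominator yields an NA marker, not an error.
#'
#' @param counts A `confusion_counts` (or list with tp, fp, tn, fn).
#' @return List with `raw` and `rounded` named vectors (sensitivity,
#'   specificity, ppv, npv).
#' @export
binary_metrics <- function(counts) {
  safe_div <- function(a, b) if (b > 0) a / b else NA_real_
  raw <- c(sensitivity = safe_div(counts$tp, counts$tp + counts$fn),
           specificity = safe_div(counts$tn, counts$tn + counts$fp),
           ppv = safe_div(counts$tp, counts$tp + counts$fp),
           npv = safe_div(counts$tn, counts$tn + counts$fn))
  list(raw = raw, rounded = round_half_up(raw, 3L))
}

#' Reconstruct confusion counts from printed sensitivity/specificity
#'
#' Given the printed rates and the class sizes, tp = round(sens * n_pos)
#' and tn = round(spec * n_neg), with the remainder as fn/fp. The
#' reconstruction asserts the implied integer is within half a count of
#' the printed rate; `sens_consistent`/`spec_consistent` additionally flag
#' whether the implied rate reproduces the printed one within 0.001
#' (probable-typo detection; 0.001 absorbs truncated rounding).
#'
#' @param sens,spec Printed rates in [0, 1].
#' @param n_pos,n_neg Numbers of positive (malignant) and negative (benign)
#'   cases.
#' @return A `confusion_counts` with attributes `sens_consistent` and
#'   `spec_consistent`.
#' @export
confusion_from_rates <- function(sens, spec, n_pos, n_neg) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1)
  tp <- round_half_up(sens * n_pos, 0L)
  tn <- round_half_up(spec * n_neg, 0L)
  if (abs(tp / n_pos - sens) > 0.5 / n_pos + 1e-9)
    stop("inconsistency error: no integer count matches the printed sensitivity",
         call. = FALSE)
  if (abs(tn / n_neg - spec) > 0.5 / n_neg + 1e-9)
    stop("inconsistency error: no integer count matches the printed specificity",
         call. = FALSE)
  out <- confusion_counts(tp = tp, fp = n_neg - tn, tn = tn, fn = n_pos - tp)
  # 0.001 absorbs printed truncation; anything beyond it marks a cell whose
  # printed rate matches no integer count (probable typo)
  attr(out, "sens_consistent") <- abs(tp / n_pos - sens) <= 0.001 + 1e-9
  attr(out, "spec_consistent") <- abs(tn / n_neg - spec) <= 0.001 + 1e-9
  out
}

# BI-RADS ordinal scale; plain 4 sits between 3 and 4a.
.birads_rank <- c("1" = 1, "2" = 2, "3" = 3, "4" = 3.5,
                  "4a" = 4, "4b" = 5, "4c" = 6, "5" = 7)

birads_rank <- function(x) {
  x <- tolower(trimws(as.character(x)))
  if (any(!x %in% names(.birads_rank)))
    stop("unknown BI-RADS category: ",
         paste(setdiff(x, names(.birads_rank)), collapse = ", "), call. = FALSE)
  unname(.birads_rank[x])
}

#' Tabulate BI-RADS category changes between sessions
#'
#' For each reader, counts aided-vs-unaided category increases and
#' decreases on the ordinal scale 1 < 2 < 3 < 4 < 4a < 4b < 4c < 5, and
#' how many changed cases moved closer to the biopsy result: toward the
#' recall end (>= 4) for malignant truth, toward <= 3 for benign truth.
#'
#' @param unaided,aided Reader records of the two sessions (reader_id,
#'   case_id, birads).
#' @param truth Case truth (named vector or data.frame).
#' @return A `birads_change_table`: `per_reader` data.frame (n_increase,
#'   n_decrease, n_total, n_closer_to_biopsy, n_not_matching) and `totals`.
#' @export
birads_changes <- function(unaided, aided, truth) {
  truth <- truth_vector(truth)
  key_u <- paste(unaided$reader_id, unaided$case_id)
  key_a <- paste(aided$reader_id, aided$case_id)
  if (!setequal(key_u, key_a) || anyDuplicated(key_u) || anyDuplicated(key_a))
    stop("design error: sessions must contain the same reader x case pairs",
         call. = FALSE)
  m <- match(key_u, key_a)
  ru <- birads_rank(unaided$birads)
  ra <- birads_rank(aided$birads[m])
  mal <- as_binary_label(truth[unaided$case_id]) == 1
  delta <- ra - ru
  closer <- (mal & delta > 0) | (!mal & delta < 0)
  per <- do.call(rbind, lapply(sort(unique(unaided$reader_id)), function(r) {
    i <- unaided$reader_id == r
    n_inc <- sum(delta[i] > 0); n_dec <- sum(delta[i] < 0)
    data.frame(reader = r, n_increase = n_inc, n_decrease = n_dec,
               n_total = n_inc + n_dec,
               n_closer_to_biopsy = sum(closer[i] & delta[i] != 0),
               n_not_matching = n_inc + n_dec - sum(closer[i] & delta[i] != 0),
               stringsAsFactors = FALSE)
  }))
  structure(list(per_reader = per,
                 totals = colSums(per[, -1, drop = FALSE])),
            class = "birads_change_table")
}

#' Grand totals of a per-reader BI-RADS change table
#'
#' @param per_reader data.frame with columns n_increase and n_decrease
#'   (and optionally n_closer_to_biopsy, n_not_matching), one row per
#'   reader.
#' @return Named vector with n_increase, n_decrease, n_total and any other
#'   count columns summed over readers.
#' @export
birads_change_totals <- function(per_reader) {
  cols <- intersect(c("n_increase", "n_decrease", "n_closer_to_biopsy",
                      "n_not_matching"), names(per_reader))
  tot <- colSums(per_reader[, cols, drop = FALSE])
  c(tot, n_total = unname(tot["n_increase"] + tot["n_decrease"]))
}

#' Compare per-reader diagnosis times between sessions
#'
#' Per reader: mean times (2 decimals), difference aided - unaided, percent
#' change relative to unaided, and a two-sided paired t-test on the
#' per-case times.
#'
#' @param unaided,aided Reader records (reader_id, case_id, time_s).
#' @return data.frame per reader: mean_unaided, mean_aided, difference,
#'   pct_change, p_value, n_cases.
#' @export
time_comparison <- function(unaided, aided) {
  readers <- sort(unique(unaided$reader_id))
  do.call(rbind, lapply(readers, function(r) {
    u <- unaided[unaided$reader_id == r, ]
    a <- aided[aided$reader_id == r, ]
    if (!setequal(u$case_id, a$case_id))
      stop("design error: case sets differ between sessions for reader ", r,
           call. = FALSE)
    if (nrow(u) < 2L)
      stop("need >= 2 paired cases for reader ", r, call. = FALSE)
    tu <- u$time_s
    ta <- a$time_s[match(u$case_id, a$case_id)]
    mu <- round_half_up(mean(tu), 2L)
    ma <- round_half_up(mean(ta), 2L)
    ch <- time_change(mu, ma)
    p <- if (stats::sd(ta - tu) == 0) {
      if (all(ta == tu)) 1 else 0
    } else stats::t.test(ta, tu, paired = TRUE)$p.value
    data.frame(reader = r, mean_unaided = mu, mean_aided = ma,
               difference = ch[["difference"]], pct_change = ch[["pct_change"]],
               p_value = p, n_cases = nrow(u), stringsAsFactors = FALSE)
  }))
}

#' Difference and percent change between two session mean times
#'
#' @param mean_unaided,mean_aided Mean diagnosis times (seconds).
#' @return Named vector: difference (aided - unaided) and pct_change
#'   (percent relative to unaided; negative = reduction).
#' @export
time_change <- function(mean_unaided, mean_aided) {
  d <- mean_aided - mean_unaided
  c(difference = d, pct_change = 100 * d / mean_unaided)
}

#' Packaged observer-study summary tables
#'
#' Per-reader summaries of the two-session (unaided/aided) observer study
#' shipped with the package: printed per-reader AUCs, binary rates
#' (sensitivity/specificity/PPV/NPV), BI-RADS change counts and mean
#' diagnosis times. The case mix of the observer set was 29 benign and 22
#' malignant masses.
#'
#' @param name One of "reader_aucs", "reader_binary_rates",
#'   "birads_changes", "reader_times".
#' @return data.frame.
#' @export
observer_fixture <- function(name = c("reader_aucs", "reader_binary_rates",
                                      "birads_changes", "reader_times")) {
  name <- match.arg(name)
  path <- system.file("extdata", "observer_study", paste0(name, ".csv"),
                      package = "perceptcad", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Case mix of the packaged observer study
#'
#' @return Named vector: n_benign = 29, n_malignant = 22.
#' @export
observer_case_mix <- function() c(n_benign = 29L, n_malignant = 22L)
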