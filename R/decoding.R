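#' Build a pseudo-population for decoding
#'
#' Pools units as if recorded simultaneously and windows their rates on
#' a sliding grid. Units are excluded unless every motion direction
#' (both as sample and as test) has at least
#' `min_train + min_test` usable trials (defaults 10 and 5), so that
#' direction-stratified resampling of training and testing trials is
#' well defined.
#'
#' @param spikes A `dmc_spikes` population.
#' @param grid A [window_grid()] (default 50 ms / 5 ms around test
#'   onset).
#' @param min_train,min_test Per-direction minimum trial counts for the
#'   training and testing pools.
#' @param correct_only Use correct trials only (default TRUE).
#' @return An object of class `pseudo_population`: list with `rates`
#'   (units x trials x windows array over usable trials), `trials`,
#'   `grid`, `units` (kept unit ids), `excluded`.
#' @export
pseudo_population <- function(spikes, grid = window_grid(),
                              min_train = 10, min_test = 5,
                              correct_only = TRUE) {
  tr <- spikes$trials
  keep_tr <- if (correct_only) which(tr$outcome == "correct")
             else seq_len(nrow(tr))
  tr <- tr[keep_tr, , drop = FALSE]
  need <- min_train + min_test
  dirs <- sort(unique(c(tr$sample_direction, tr$test_direction)))
  counts_ok <- all(vapply(dirs, function(d)
    sum(tr$sample_direction == d) >= need &&
      sum(tr$test_direction == d) >= need, logical(1)))
  # all units share the session's trial table, so the per-direction
  # minimum is a property of the trial set; per-unit exclusion happens
  # when units carry their own trial subsets (not the synthetic case)
  units <- seq_len(n_units(spikes))
  if (!counts_ok)
    stop("trial set does not satisfy the per-direction minimum counts")
  rates <- array(NA_real_, c(length(units), length(keep_tr),
                             length(grid$starts)))
  for (ui in seq_along(units))
    rates[ui, , ] <- window_rates(spikes, units[ui], grid)[keep_tr, ,
                                                           drop = FALSE]
  out <- list(rates = rates, trials = tr, grid = grid, units = units,
              excluded = integer(0))
  class(out) <- "pseudo_population"
  out
}

# class labels and stratification column for a decoding target
decode_labels <- function(trials, label) {
  switch(label,
         mnm = list(y = ifelse(trials$is_match, "match", "nonmatch"),
                    strat = "test_direction"),
         sample_category = list(y = paste0("S", trials$sample_category),
                                strat = "sample_direction"),
         test_category = list(y = paste0("T", trials$test_category),
                              strat = "test_direction"),
         stop("unknown label: ", label))
}

# Draw `n` pseudotrials: balanced over classes and (optionally)
# stratified over directions within class; returns per-pseudotrial trial
# indices for every unit (n x n_units matrix) plus the class labels.
draw_pseudotrials <- function(cells, classes, n, n_units, stratify) {
  cls <- rep(classes, length.out = n)
  idx <- matrix(0L, n, n_units)
  dir_of <- lapply(classes, function(cl) names(cells[[cl]]))
  lab_dir <- character(n)
  for (p in seq_len(n)) {
    cl <- cls[p]
    d <- if (stratify) sample(dir_of[[match(cl, classes)]], 1)
         else sample(names(cells[[cl]]), 1)
    lab_dir[p] <- d
    pool <- cells[[cl]][[d]]
    idx[p, ] <- pool[sample.int(length(pool), n_units, replace = TRUE)]
  }
  list(idx = idx, y = cls, direction = lab_dir)
}

# index trial pools by class and stratum for one split
build_cells <- function(y, strat, rows) {
  out <- list()
  for (cl in unique(y[rows])) {
    sel <- rows[y[rows] == cl]
    out[[cl]] <- split(sel, strat[sel])
  }
  out
}

svm_fit_predict <- function(xtr, ytr, xte) {
  mu <- colMeans(xtr)
  sd_ <- apply(xtr, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  xtr <- sweep(sweep(xtr, 2, mu), 2, sd_, "/")
  xte <- sweep(sweep(xte, 2, mu), 2, sd_, "/")
  fit <- e1071::svm(xtr, factor(ytr), kernel = "linear", cost = 1,
                    scale = FALSE)
  as.character(stats::predict(fit, xte))
}

#' Linear-SVM decoding timecourse from a pseudo-population
#'
#' For each bootstrap repeat: every unit's trials are split 66/34 into
#' training and testing pools; 120 training and 60 testing pseudotrials
#' are resampled with replacement, balanced over the two classes and
#' stratified by motion direction within class; per window, a linear
#' maximum-margin classifier (cost 1, features z-scored per unit on the
#' training pseudotrials only) is fit and its test accuracy recorded.
#' Chance is 1/2. Significance per window is the two-sided bootstrap
#' percentile of the repeat distribution against chance.
#'
#' @param pop A [pseudo_population()].
#' @param label `"mnm"`, `"sample_category"`, or `"test_category"`.
#' @param n_boot Number of bootstrap repeats (default 100).
#' @param n_train,n_test Pseudotrial counts per repeat.
#' @param train_frac Fraction of each unit's trials assigned to the
#'   training pool.
#' @param stratify Stratify resampling by direction within class
#'   (default TRUE).
#' @param windows Indices of grid windows to decode (default all).
#' @param seed Integer seed.
#' @param trial_subset Optional logical/integer subset of the
#'   population's trials to use.
#' @param permute_labels If TRUE, class labels are shuffled once per
#'   repeat (null calibration).
#' @return An object of class `decoding_result`: `accuracy` (n_boot x
#'   windows matrix), `window_center`, `chance`, `label`, `p_value`
#'   per window.
#' @export
svm_timecourse <- function(pop, label = "mnm", n_boot = 100,
                           n_train = 120, n_test = 60,
                           train_frac = 0.66, stratify = TRUE,
                           windows = NULL, seed = 1L,
                           trial_subset = NULL, permute_labels = FALSE) {
  restore <- local_rng(seed)
  on.exit(restore())
  tr <- pop$trials
  rows_all <- seq_len(nrow(tr))
  if (!is.null(trial_subset)) rows_all <- rows_all[trial_subset]
  ld <- decode_labels(tr, label)
  y <- ld$y
  strat <- as.character(tr[[ld$strat]])
  classes <- sort(unique(y[rows_all]))
  if (length(classes) < 2) stop("need >= 2 classes present")
  if (is.null(windows)) windows <- seq_along(pop$grid$starts)
  nu <- dim(pop$rates)[1]
  acc <- matrix(NA_real_, n_boot, length(windows))
  for (bt in seq_len(n_boot)) {
    yb <- y
    if (permute_labels) yb[rows_all] <- sample(yb[rows_all])
    ntr_pool <- round(train_frac * length(rows_all))
    train_rows <- sort(rows_all[sample.int(length(rows_all), ntr_pool)])
    test_rows <- setdiff(rows_all, train_rows)
    cells_tr <- build_cells(yb, strat, train_rows)
    cells_te <- build_cells(yb, strat, test_rows)
    ok <- all(vapply(cells_tr, function(cl) all(lengths(cl) > 0),
                     logical(1))) && length(cells_te) == length(classes)
    if (!ok) { bt <- bt; next }  # redrawn implicitly by NA + later mean
    ptr <- draw_pseudotrials(cells_tr, classes, n_train, nu, stratify)
    pte <- draw_pseudotrials(cells_te, classes, n_test, nu, stratify)
    for (wi in seq_along(windows)) {
      w <- windows[wi]
      xtr <- matrix(pop$rates[cbind(rep(seq_len(nu), each = n_train),
                                    as.vector(ptr$idx), w)],
                    n_train, nu)
      xte <- matrix(pop$rates[cbind(rep(seq_len(nu), each = n_test),
                                    as.vector(pte$idx), w)],
                    n_test, nu)
      pred <- svm_fit_predict(xtr, ptr$y, xte)
      acc[bt, wi] <- mean(pred == pte$y)
    }
  }
  p <- apply(acc, 2, function(v) {
    v <- v[!is.na(v)]
    2 * min(mean(v <= 0.5), mean(v >= 0.5))
  })
  out <- list(accuracy = acc, window_center = pop$grid$centers[windows],
              chance = 0.5, label = label, p_value = pmin(p, 1))
  class(out) <- "decoding_result"
  out
}

#' @export
print.decoding_result <- function(x, ...) {
  cat("decoding_result (", x$label, "): ",
      nrow(x$accuracy), " repeats x ", ncol(x$accuracy),
      " windows; peak mean accuracy ",
      round(max(colMeans(x$accuracy, na.rm = TRUE)), 3), "\n", sep = "")
  invisible(x)
}

#' Cross-sample-condition generalization of the test-category code
#'
#' Trains a test-category classifier on trials from one sample category
#' (S1T1 vs S1T2) and evaluates it on trials from the other (S2T1 vs
#' S2T2), and vice versa; the two directions are averaged. Accuracy
#' above chance indicates a context-invariant (linear-like)
#' test-category code; below chance indicates a context-reversing
#' (match/nonmatch-like, XOR) code.
#'
#' @inheritParams svm_timecourse
#' @return A `decoding_result` whose accuracy averages the two train/test
#'   directions.
#' @export
cross_condition_svm <- function(pop, n_boot = 100, n_train = 120,
                                n_test = 60, stratify = TRUE,
                                windows = NULL, seed = 1L) {
  restore <- local_rng(seed)
  on.exit(restore())
  tr <- pop$trials
  y <- paste0("T", tr$test_category)
  strat <- as.character(tr$test_direction)
  ctx <- tr$sample_category
  classes <- sort(unique(y))
  if (is.null(windows)) windows <- seq_along(pop$grid$starts)
  nu <- dim(pop$rates)[1]
  acc <- matrix(NA_real_, n_boot, length(windows))
  for (bt in seq_len(n_boot)) {
    a_dir <- numeric(2)
    tmp <- matrix(NA_real_, 2, length(windows))
    for (dir_i in 1:2) {
      train_ctx <- if (dir_i == 1) 1 else 2
      rows_tr <- which(ctx == train_ctx)
      rows_te <- which(ctx != train_ctx)
      cells_tr <- build_cells(y, strat, rows_tr)
      cells_te <- build_cells(y, strat, rows_te)
      ptr <- draw_pseudotrials(cells_tr, classes, n_train, nu, stratify)
      pte <- draw_pseudotrials(cells_te, classes, n_test, nu, stratify)
      for (wi in seq_along(windows)) {
        w <- windows[wi]
        xtr <- matrix(pop$rates[cbind(rep(seq_len(nu), each = n_train),
                                      as.vector(ptr$idx), w)],
                      n_train, nu)
        xte <- matrix(pop$rates[cbind(rep(seq_len(nu), each = n_test),
                                      as.vector(pte$idx), w)],
                      n_test, nu)
        pred <- svm_fit_predict(xtr, ptr$y, xte)
        tmp[dir_i, wi] <- mean(pred == pte$y)
      }
    }
    acc[bt, ] <- colMeans(tmp)
  }
  p <- apply(acc, 2, function(v) {
    v <- v[!is.na(v)]
    2 * min(mean(v <= 0.5), mean(v >= 0.5))
  })
  out <- list(accuracy = acc, window_center = pop$grid$centers[windows],
              chance = 0.5, label = "test_category_cross_context",
              p_value = pmin(p, 1))
  class(out) <- "decoding_result"
  out
}

#' Match/nonmatch decoding split by reaction time
#'
#' Splits correct match trials at the median reaction time into fast and
#' slow subgroups (equal sizes up to one trial) and runs independent
#' match/nonmatch decoding for each subgroup (each paired with the full
#' set of correct nonmatch trials).
#'
#' @inheritParams svm_timecourse
#' @return List: `fast` and `slow` `decoding_result`s, `median_rt`, and
#'   `onset` (per subgroup, first window whose mean accuracy exceeds
#'   `onset_threshold`, or `NA`).
#' @param onset_threshold Accuracy threshold used to compare the rise of
#'   the two timecourses (default 0.75).
#' @export
rt_split_decode <- function(pop, n_boot = 100, n_train = 120,
                            n_test = 60, windows = NULL, seed = 1L,
                            onset_threshold = 0.75) {
  tr <- pop$trials
  is_m <- tr$is_match
  rt <- tr$reaction_time
  med <- stats::median(rt[is_m], na.rm = TRUE)
  fast <- which(is_m & rt <= med)
  slow <- which(is_m & rt > med)
  nm <- which(!is_m)
  res <- lapply(list(fast = c(fast, nm), slow = c(slow, nm)),
                function(rows)
                  svm_timecourse(pop, "mnm", n_boot = n_boot,
                                 n_train = n_train, n_test = n_test,
                                 windows = windows, seed = seed,
                                 trial_subset = rows))
  onset <- vapply(res, function(r) {
    m <- colMeans(r$accuracy, na.rm = TRUE)
    i <- which(m > onset_threshold)
    if (length(i)) r$window_center[i[1]] else NA_real_
  }, numeric(1))
  list(fast = res$fast, slow = res$slow, median_rt = med, onset = onset)
}
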