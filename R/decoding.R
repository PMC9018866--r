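#' Decoding analysis configuration
#'
#' @param target `"scene"` (multiclass over chosen scene labels),
#'   `"confidence"` (reported side) or `"state_confidence"` (model side).
#' @param periods decoding periods to evaluate (subset of 0..8).
#' @param n_undersample_repeats undersampling repetitions per fold whose
#'   accuracies are averaged (100 in the full analysis; reduce for quick
#'   runs).
#' @param cv `"LOSO"` (leave-one-session-out) or `"LOGO"`
#'   (leave-one-game-out).
#' @param min_samples_per_label_training minimum training samples required
#'   for every label in every fold; a subject violating it is excluded with
#'   a recorded reason.
#' @param lambda sparsity penalty for the classifiers: `"auto"` selects it
#'   on a split of the training data only, or a fixed numeric value.
#' @param rng_seed integer seed for undersampling and penalty selection.
#' @return an object of class `decoding_config`.
#' @export
decoding_config <- function(target = c("scene", "confidence",
                                       "state_confidence"),
                            periods = 0:8, n_undersample_repeats = 100L,
                            cv = c("LOSO", "LOGO"),
                            min_samples_per_label_training = 3L,
                            lambda = "auto", rng_seed = 1L) {
  stopifnot(all(periods %in% 0:8), n_undersample_repeats >= 1L,
            min_samples_per_label_training >= 1L)
  structure(list(target = match.arg(target), periods = as.integer(periods),
                 n_undersample_repeats = as.integer(n_undersample_repeats),
                 cv = match.arg(cv),
                 min_samples_per_label_training =
                   as.integer(min_samples_per_label_training),
                 lambda = lambda, rng_seed = as.integer(rng_seed)),
            class = "decoding_config")
}

#' Feature vector of one decoding period from a scan time series
#'
#' The decoder at period t uses the per-feature mean of the four consecutive
#' volumes starting t seconds after delay onset (volumes t..t+3, 0-based,
#' i.e. the (t+1)-th to (t+4)-th scans at 1 s spacing).
#'
#' @param scan_series numeric matrix, volumes x features, volume 1 at delay
#'   onset.
#' @param t decoding period (0-based).
#' @return numeric feature vector.
#' @export
period_features <- function(scan_series, t) {
  t <- as.integer(t)
  if (nrow(scan_series) < t + 4L)
    stop(sprintf("scan series too short for period %d: needs %d volumes, has %d",
                 t, t + 4L, nrow(scan_series)))
  colMeans(scan_series[(t + 1L):(t + 4L), , drop = FALSE])
}

#' Exclude the rarest scene label from a pattern dataset
#'
#' Removes all trials of the globally rarest scene label (ties resolved to
#' the lowest label), mirroring the exclusion of a rare scene that leaves six
#' decoder labels out of seven.
#'
#' @param ds a `pattern_dataset`.
#' @return list: `dataset` (trimmed), `excluded_label`, `counts` (original
#'   per-label counts).
#' @export
exclude_rare_label <- function(ds) {
  counts <- table(ds$labels$scene)
  stopifnot(length(counts) >= 2L)
  rare <- as.integer(names(counts)[counts == min(counts)])
  rare <- min(rare)
  keep <- ds$labels$scene != rare
  out <- ds
  out$patterns <- ds$patterns[keep, , , drop = FALSE]
  out$labels <- ds$labels[keep, , drop = FALSE]
  rownames(out$labels) <- NULL
  list(dataset = out, excluded_label = rare, counts = counts)
}

#' Balanced undersampling of a label vector
#'
#' Uniformly samples, without replacement, min-class-count trials from every
#' label.
#'
#' @param labels vector of class labels.
#' @param rng rng stream.
#' @return sorted integer indices of the retained trials.
#' @export
undersample <- function(labels, rng) {
  counts <- table(labels)
  if (any(counts == 0L)) stop("empty class: ", names(counts)[counts == 0L][1L])
  k <- min(counts)
  idx <- unlist(lapply(names(counts), function(l) {
    pool <- which(labels == l)
    pool[rng$sample_int(length(pool), k)]
  }))
  sort(idx)
}

#' Train sparse one-versus-rest probabilistic classifiers
#'
#' One L1-penalized logistic classifier per label (a single binary classifier
#' for two-class targets); the sparsity penalty performs automatic feature
#' selection. With `lambda = "auto"` the penalty is chosen per classifier by
#' log-loss on a held-out quarter of the training data (training data only;
#' test folds never enter). Prediction takes the label with the maximum
#' class probability, ties going to the lowest label.
#'
#' @param x numeric matrix, trials x features.
#' @param y vector of labels (>= 2 classes, each with >= 2 samples).
#' @param lambda `"auto"` or a fixed numeric penalty.
#' @param rng rng stream for the internal validation split.
#' @return an object of class `ovr_sparse` with `classes`, per-class fits,
#'   `lambda` used, and `n_selected_features`.
#' @export
train_ovr_sparse <- function(x, y, lambda = "auto", rng = NULL) {
  # small undersampled classes are routine here; glmnet's class-size warning
  # would otherwise fire on every repeat
  quiet_glmnet <- function(expr) withCallingHandlers(expr,
    warning = function(w) {
      if (grepl("fewer than 8\\s+observations", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need at least two classes")
  sds <- apply(x, 2L, stats::sd)
  if (all(sds == 0)) stop("degenerate features: zero variance everywhere")
  if (is.null(rng)) rng <- make_rng(1L)
  fits <- list(); lambdas <- numeric(length(classes))
  selected <- rep(FALSE, ncol(x))
  for (ci in seq_along(classes)) {
    yy <- as.integer(y == classes[ci])
    lam <- lambda
    if (identical(lambda, "auto")) {
      # stratified 75/25 split of the training data for penalty selection;
      # every class keeps at least one sample on the fitting side
      val <- unlist(lapply(unique(yy), function(v) {
        pool <- which(yy == v)
        n_val <- min(max(1L, floor(length(pool) / 4L)), length(pool) - 2L)
        if (n_val < 1L) return(integer(0))
        pool[rng$sample_int(length(pool), n_val)]
      }))
      trn <- setdiff(seq_along(yy), val)
      if (length(val) == 0L || length(unique(yy[trn])) < 2L) {
        # too few samples to validate: mid-path penalty on the full fit
        path <- quiet_glmnet(glmnet::glmnet(x, yy, family = "binomial",
                                            nlambda = 25L,
                                            lambda.min.ratio = 0.02))
        lam <- path$lambda[ceiling(length(path$lambda) / 2)]
      } else {
        path <- quiet_glmnet(glmnet::glmnet(x[trn, , drop = FALSE], yy[trn],
                                            family = "binomial", nlambda = 25L,
                                            lambda.min.ratio = 0.02))
        pr <- stats::plogis(stats::predict(path, x[val, , drop = FALSE],
                                           type = "link"))
        eps <- 1e-12
        ll <- -colMeans(yy[val] * log(pr + eps) +
                          (1 - yy[val]) * log(1 - pr + eps))
        lam <- path$lambda[which.min(ll)]
      }
    }
    f <- quiet_glmnet(
      glmnet::glmnet(x, yy, family = "binomial",
                     lambda = sort(c(lam * c(8, 4, 2), lam),
                                   decreasing = TRUE)))
    # extract the coefficients at the chosen penalty once; prediction is
    # then plain matrix algebra
    idx <- which.min(abs(f$lambda - lam))
    beta <- as.numeric(f$beta[, idx])
    fits[[ci]] <- list(a0 = unname(f$a0[idx]), beta = beta)
    lambdas[ci] <- lam
    selected <- selected | (beta != 0)
    if (length(classes) == 2L) break  # a single binary classifier suffices
  }
  structure(list(classes = classes, fits = fits, lambda = lambdas,
                 n_selected_features = sum(selected)),
            class = "ovr_sparse")
}

#' @rdname train_ovr_sparse
#' @param object an `ovr_sparse` classifier bundle.
#' @param newx matrix of trials to classify.
#' @param ... unused.
#' @export
predict.ovr_sparse <- function(object, newx, ...) {
  K <- length(object$classes)
  lp_of <- function(f) as.vector(newx %*% f$beta) + f$a0
  if (K == 2L) {
    # the single classifier models P(class = classes[1])
    p1 <- stats::plogis(lp_of(object$fits[[1L]]))
    prob <- cbind(p1, 1 - p1)
  } else {
    prob <- vapply(object$fits, function(f) stats::plogis(lp_of(f)),
                   numeric(nrow(newx)))
    prob <- matrix(prob, nrow = nrow(newx))
  }
  # argmax with ties to the lowest label
  object$classes[apply(prob, 1L, which.max)]
}

target_labels <- function(ds, target) {
  switch(target,
         scene = ds$labels$scene,
         confidence = ds$labels$conf,
         state_confidence = ds$labels$state_conf)
}

#' Cross-validated decoding of a pattern dataset
#'
#' Leave-one-session-out or leave-one-game-out cross-validation. Within each
#' fold the training set is undersampled to balanced classes, a sparse
#' one-versus-rest decoder is trained and evaluated on the untouched test
#' fold; this is repeated `n_undersample_repeats` times and averaged, then
#' averaged over folds. The test fold never enters undersampling, penalty
#' selection or training. A subject whose training folds violate the
#' minimum-samples-per-label rule is excluded with a recorded reason.
#'
#' @param ds a `pattern_dataset`.
#' @param config a `decoding_config`.
#' @return an object of class `decoding_result`: `period_accuracy`
#'   (data.frame period, accuracy), `folds` (per-fold detail),
#'   `n_selected_features` (mean), `excluded`, `reason`.
#' @export
cross_validate <- function(ds, config) {
  y <- target_labels(ds, config$target)
  if (anyNA(y))
    return(excluded_result(ds, config, "missing target labels"))
  groups <- if (config$cv == "LOSO") ds$labels$session else ds$labels$game
  gset <- sort(unique(groups))
  if (length(gset) < 2L)
    return(excluded_result(ds, config, "fewer than two CV groups"))
  # exclusion: every fold's training set must hold enough of every label
  # (at least two regardless of the configured minimum -- the classifiers
  # cannot be trained on single-sample classes)
  min_needed <- max(2L, config$min_samples_per_label_training)
  for (g in gset) {
    cnt <- table(y[groups != g])
    if (length(cnt) < length(unique(y)) || any(cnt < min_needed))
      return(excluded_result(ds, config, sprintf(
        "fewer than %d training samples for a label when leaving out %s %s",
        min_needed,
        if (config$cv == "LOSO") "session" else "game", g)))
  }
  rng <- make_rng(derive_seed(config$rng_seed, paste0("cv", ds$subject_id)))
  fold_rows <- list(); nsel <- c()
  for (t in config$periods) {
    X <- ds$patterns[, t + 1L, , drop = TRUE]
    X <- matrix(X, nrow = dim(ds$patterns)[1L])
    for (g in gset) {
      test <- which(groups == g); train <- which(groups != g)
      accs <- numeric(config$n_undersample_repeats)
      for (r in seq_len(config$n_undersample_repeats)) {
        us <- train[undersample(y[train], rng)]
        fit <- train_ovr_sparse(X[us, , drop = FALSE], y[us],
                                lambda = config$lambda, rng = rng)
        pred <- predict(fit, X[test, , drop = FALSE])
        accs[r] <- mean(pred == y[test])
        nsel <- c(nsel, fit$n_selected_features)
      }
      fold_rows[[length(fold_rows) + 1L]] <- data.frame(
        period = t, fold = g, accuracy = mean(accs), n_test = length(test))
    }
  }
  folds <- do.call(rbind, fold_rows)
  pa <- stats::aggregate(accuracy ~ period, folds, mean)
  structure(list(subject_id = ds$subject_id, target = config$target,
                 cv = config$cv, period_accuracy = pa, folds = folds,
                 n_selected_features = mean(nsel),
                 n_labels = length(unique(y)),
                 excluded = FALSE, reason = NA_character_),
            class = "decoding_result")
}

excluded_result <- function(ds, config, reason) {
  structure(list(subject_id = ds$subject_id, target = config$target,
                 cv = config$cv, period_accuracy = NULL, folds = NULL,
                 n_selected_features = NA_real_, n_labels = NA_integer_,
                 excluded = TRUE, reason = reason),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  if (x$excluded)
    cat(sprintf("<decoding_result %s [%s]: excluded (%s)>\n", x$subject_id,
                x$target, x$reason))
  else
    cat(sprintf("<decoding_result %s [%s, %s]: mean accuracy %.3f over %d periods>\n",
                x$subject_id, x$target, x$cv, mean(x$period_accuracy$accuracy),
                nrow(x$period_accuracy)))
  invisible(x)
}

#' Conditional decoding on a subset of trials
#'
#' Filters the dataset to one condition (correct / incorrect prediction,
#' high / low reported confidence, high / low model state confidence) and
#' cross-validates with leave-one-game-out CV; subjects with fewer than the
#' configured minimum training samples for any scene label in any fold are
#' excluded with a recorded reason.
#'
#' @param ds a `pattern_dataset`.
#' @param condition one of `"correct"`, `"incorrect"`, `"conf_high"`,
#'   `"conf_low"`, `"state_conf_high"`, `"state_conf_low"`.
#' @param config a `decoding_config` (its `cv` is forced to LOGO).
#' @return a `decoding_result` tagged with the condition.
#' @export
conditional_decode <- function(ds, condition = c("correct", "incorrect",
                                                 "conf_high", "conf_low",
                                                 "state_conf_high",
                                                 "state_conf_low"),
                               config) {
  condition <- match.arg(condition)
  keep <- switch(condition,
    correct = ds$labels$correct,
    incorrect = !ds$labels$correct,
    conf_high = ds$labels$conf == 1L,
    conf_low = ds$labels$conf == 0L,
    state_conf_high = ds$labels$state_conf == 1L,
    state_conf_low = ds$labels$state_conf == 0L)
  keep <- which(!is.na(keep) & keep)
  config$cv <- "LOGO"
  if (!length(keep)) {
    res <- excluded_result(ds, config, paste0("no trials in condition ",
                                              condition))
    res$condition <- condition
    return(res)
  }
  sub <- ds
  sub$patterns <- ds$patterns[keep, , , drop = FALSE]
  sub$labels <- ds$labels[keep, , drop = FALSE]
  res <- cross_validate(sub, config)
  res$condition <- condition
  res
}

#' Compare two decoding conditions at one period
#'
#' One-sided Wilcoxon rank-sum test on the per-subject accuracies of two
#' condition decoders at a given period (alternative: first > second).
#'
#' @param results_a,results_b lists of `decoding_result` (one per subject);
#'   excluded subjects are dropped.
#' @param period decoding period to compare.
#' @return list: `p`, `n_a`, `n_b`, `acc_a`, `acc_b`, `testable`.
#' @export
compare_conditions <- function(results_a, results_b, period) {
  pull <- function(res) {
    v <- vapply(res, function(r) {
      if (r$excluded) return(NA_real_)
      i <- match(period, r$period_accuracy$period)
      if (is.na(i)) NA_real_ else r$period_accuracy$accuracy[i]
    }, numeric(1))
    v[!is.na(v)]
  }
  a <- pull(results_a); b <- pull(results_b)
  if (length(a) < 3L || length(b) < 3L)
    return(list(p = NA_real_, n_a = length(a), n_b = length(b),
                acc_a = a, acc_b = b, testable = FALSE))
  pv <- stats::wilcox.test(a, b, alternative = "greater",
                           exact = FALSE)$p.value
  list(p = pv, n_a = length(a), n_b = length(b), acc_a = a, acc_b = b,
       testable = TRUE)
}

#' Two-step group permutation test of decoding accuracy
#'
#' Step (i): for each subject, the target labels are randomly permuted within
#' sessions `n_sbj` times and each permutation is re-decoded, giving a
#' per-subject pool of `n_sbj + 1` accuracies (the original included).
#' Steps (ii)-(iii): `n_group` group-level null values are formed by drawing
#' one pool entry per subject and averaging. The original per-subject
#' accuracies are then compared against the group null distribution with a
#' one-sided Wilcoxon rank-sum test.
#'
#' @param datasets list of `pattern_dataset`, one per subject.
#' @param config a `decoding_config`; accuracies are averaged over its
#'   `periods` (typically a single period).
#' @param n_sbj within-subject permutations (150 in the full analysis; the
#'   scaled default here is 30).
#' @param n_group group-level resamples (1000 full; scaled default 200).
#' @param rng_seed seed for permutations and resampling.
#' @return list: `p`, `original` (per-subject accuracies), `null`
#'   (group-level null distribution), `pools`, `n_excluded`.
#' @export
permutation_test_two_step <- function(datasets, config, n_sbj = 30L,
                                      n_group = 200L, rng_seed = 1L) {
  if (n_sbj < 1L || n_group < 1L) stop("n_sbj and n_group must be >= 1")
  if (length(datasets) < 2L) stop("need at least two subjects")
  rng <- make_rng(derive_seed(rng_seed, "permtest"))
  acc_of <- function(res) mean(res$period_accuracy$accuracy)
  pools <- list(); originals <- c(); n_excl <- 0L
  for (ds in datasets) {
    orig <- cross_validate(ds, config)
    if (orig$excluded) { n_excl <- n_excl + 1L; next }
    pool <- numeric(n_sbj + 1L)
    pool[1L] <- acc_of(orig)
    y <- target_labels(ds, config$target)
    for (b in seq_len(n_sbj)) {
      perm <- ds
      yp <- y
      for (sess in unique(ds$labels$session)) {
        i <- which(ds$labels$session == sess)
        yp[i] <- y[i][rng$sample_int(length(i), length(i))]
      }
      perm$labels[[switch(config$target, scene = "scene",
                          confidence = "conf",
                          state_confidence = "state_conf")]] <- yp
      res <- cross_validate(perm, config)
      pool[b + 1L] <- if (res$excluded) NA_real_ else acc_of(res)
    }
    pools[[length(pools) + 1L]] <- pool
    originals <- c(originals, pool[1L])
  }
  if (length(pools) < 2L) stop("fewer than two decodable subjects")
  null_dist <- vapply(seq_len(n_group), function(b) {
    mean(vapply(pools, function(pl) {
      pl2 <- pl[!is.na(pl)]
      pl2[rng$sample_int(length(pl2))]
    }, numeric(1)))
  }, numeric(1))
  pv <- stats::wilcox.test(originals, null_dist, alternative = "greater",
                           exact = FALSE)$p.value
  list(p = pv, original = originals, null = null_dist, pools = pools,
       n_excluded = n_excl)
}
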