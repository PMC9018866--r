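#' Specification of the synthetic trial-wise pattern generator
#'
#' Generates multivariate activity patterns for every prediction trial of a
#' behavior log. Each chosen scene has a fixed multivariate prototype; a
#' trial's pattern at decoding period t is the prototype scaled by a temporal
#' envelope and a global amplitude, plus a per-session additive drift and
#' Gaussian noise whose standard deviation depends on the trial's confidence.
#' Confidence therefore modulates the trial-to-trial variability of the
#' pattern (not its mean), the mechanism hypothesized to make predictions
#' more decodable at high confidence; an alternative amplitude-modulation
#' mode is available since mean-based data cannot distinguish the two.
#'
#' @param n_features pattern dimensionality (emulating an ROI of a few
#'   hundred to a few thousand voxels).
#' @param n_informative number of features carrying scene information.
#' @param amplitude global signal scale.
#' @param sigma_high_conf,sigma_low_conf noise standard deviations for high-
#'   and low-confidence trials (`sigma_low_conf >= sigma_high_conf`).
#' @param envelope 9 nonnegative weights over decoding periods 0..8 (default
#'   ramp peaking at period 6).
#' @param session_drift_sd sd of the per-(session, feature) additive offset.
#' @param incorrect_signal_scale multiplier on the signal of incorrect
#'   trials; at the default 1 incorrect trials carry the chosen scene's
#'   pattern at full strength.
#' @param conf_modulates `"noise"` (default) or `"amplitude"`.
#' @param conf_driver which confidence labels drive the modulation:
#'   `"internal"` (the simulator's hidden binary confidence, falling back to
#'   the reported side when no ground truth is present) or `"reported"`.
#' @param rng_seed integer seed.
#' @return an object of class `pattern_spec`.
#' @export
pattern_spec <- function(n_features = 600L, n_informative = 60L,
                         amplitude = 1, sigma_high_conf = 0.5,
                         sigma_low_conf = 1, envelope = NULL,
                         session_drift_sd = 0.1,
                         incorrect_signal_scale = 1,
                         conf_modulates = c("noise", "amplitude"),
                         conf_driver = c("internal", "reported"),
                         rng_seed = 1L) {
  if (is.null(envelope))
    envelope <- c(0.2, 0.3, 0.4, 0.55, 0.7, 0.85, 1.0, 0.95, 0.9)
  stopifnot(n_informative <= n_features, length(envelope) == 9L,
            all(envelope >= 0), sigma_low_conf >= sigma_high_conf,
            incorrect_signal_scale >= 0, incorrect_signal_scale <= 1)
  structure(list(n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 amplitude = amplitude,
                 sigma_high_conf = sigma_high_conf,
                 sigma_low_conf = sigma_low_conf,
                 envelope = envelope,
                 session_drift_sd = session_drift_sd,
                 incorrect_signal_scale = incorrect_signal_scale,
                 conf_modulates = match.arg(conf_modulates),
                 conf_driver = match.arg(conf_driver),
                 rng_seed = as.integer(rng_seed)),
            class = "pattern_spec")
}

#' Scene prototype patterns
#'
#' One unit-norm pattern per scene label, supported on the informative
#' feature subset (the first `n_informative` features), with all pairwise
#' correlations bounded below 0.3 by redrawing.
#'
#' @param spec a `pattern_spec`.
#' @param n_scene_types number of prototypes (7 scene types in a valid maze).
#' @param max_attempts redraw budget for the correlation bound.
#' @return matrix `n_scene_types x n_features`, rows named by label 1..7.
#' @export
make_prototypes <- function(spec, n_scene_types = 7L, max_attempts = 200L) {
  rng <- make_rng(derive_seed(spec$rng_seed, "prototypes"))
  k <- spec$n_informative
  for (attempt in seq_len(max_attempts)) {
    p <- matrix(rng$rnorm(n_scene_types * k), n_scene_types, k)
    p <- p / sqrt(rowSums(p^2))
    if (n_scene_types < 2L || max(abs(stats::cor(t(p))[upper.tri(diag(n_scene_types))])) < 0.3) {
      out <- matrix(0, n_scene_types, spec$n_features)
      out[, seq_len(k)] <- p
      rownames(out) <- as.character(seq_len(n_scene_types))
      return(out)
    }
  }
  stop("could not satisfy the prototype correlation bound; ",
       "increase n_informative or max_attempts")
}

#' Generate a trial-wise pattern dataset from a behavior log
#'
#' One feature matrix (9 periods x features) per non-missed prediction
#' trial, built as envelope x amplitude x prototype(chosen scene), scaled by
#' `incorrect_signal_scale` on incorrect trials, plus session drift and
#' confidence-dependent Gaussian noise, followed by per-feature z-scoring
#' within each session (pooling trials and periods; emulating run-wise voxel
#' normalization).
#'
#' @param log a `behavior_log` with prediction trials.
#' @param spec a `pattern_spec`.
#' @param state_conf optional integer vector (0/1) of model state-confidence
#'   sides, one per non-missed prediction trial (e.g. `c_hat` from
#'   [filter_log()]); defaults to the simulator's hidden confidence when the
#'   log carries ground truth.
#' @return an object of class `pattern_dataset`: `patterns` (array trials x
#'   9 x features), `labels` (data.frame: scene, conf, state_conf, correct,
#'   session, game, trial_index), `subject_id`, `spec`.
#' @export
generate_patterns <- function(log, spec, state_conf = NULL) {
  p <- pred_trials(log)
  p <- p[!is.na(p$chosen_scene_label), , drop = FALSE]
  if (!nrow(p)) stop("log contains no usable prediction trials")
  n <- nrow(p)
  truth_c <- NULL
  if (!is.null(log$truth)) {
    tk <- paste(log$truth$game, log$truth$trial_index)
    truth_c <- log$truth$true_c[match(paste(p$game, p$trial_index), tk)]
  }
  if (is.null(state_conf)) state_conf <- truth_c
  reported_high <- as.integer(p$confidence_report >= 3L)
  driver <- if (spec$conf_driver == "internal" && !is.null(truth_c)) truth_c
            else reported_high
  labels <- data.frame(
    trial = seq_len(n), scene = p$chosen_scene_label,
    conf = reported_high,
    state_conf = if (is.null(state_conf)) NA_integer_
                 else as.integer(state_conf),
    correct = p$correct, session = p$session, game = p$game,
    trial_index = p$trial_index)
  proto <- make_prototypes(spec)
  rng <- make_rng(derive_seed(spec$rng_seed, "patterns"))
  sessions <- sort(unique(labels$session))
  drift <- matrix(rng$rnorm(length(sessions) * spec$n_features,
                            0, spec$session_drift_sd),
                  length(sessions), spec$n_features)
  arr <- array(0, dim = c(n, 9L, spec$n_features))
  for (i in seq_len(n)) {
    base <- proto[as.character(labels$scene[i]), ]
    scale <- spec$amplitude *
      (if (labels$correct[i]) 1 else spec$incorrect_signal_scale)
    high <- driver[i] == 1L
    sig <- if (high) spec$sigma_high_conf else spec$sigma_low_conf
    if (spec$conf_modulates == "amplitude") {
      # amplitude mode: high confidence strengthens the signal instead of
      # shrinking the noise; noise fixed at the low-confidence sd
      scale <- scale * (if (high) spec$sigma_low_conf / spec$sigma_high_conf
                        else 1)
      sig <- spec$sigma_low_conf
    }
    dr <- drift[match(labels$session[i], sessions), ]
    for (t in seq_len(9L))
      arr[i, t, ] <- spec$envelope[t] * scale * base + dr +
        rng$rnorm(spec$n_features, 0, sig)
  }
  # per-feature z-normalization within session (pooling trials and periods)
  for (sess in sessions) {
    idx <- which(labels$session == sess)
    for (f in seq_len(spec$n_features)) {
      v <- as.vector(arr[idx, , f])
      s <- stats::sd(v)
      arr[idx, , f] <- if (s > 0) (arr[idx, , f] - mean(v)) / s
                       else arr[idx, , f] - mean(v)
    }
  }
  structure(list(patterns = arr, labels = labels,
                 subject_id = if (inherits(log, "behavior_log"))
                   log$subject_id else "s1",
                 spec = spec),
            class = "pattern_dataset")
}

#' @export
print.pattern_dataset <- function(x, ...) {
  cat(sprintf("<pattern_dataset %s: %d trials x 9 periods x %d features>\n",
              x$subject_id, dim(x$patterns)[1L], dim(x$patterns)[3L]))
  invisible(x)
}

#' Read / write a pattern dataset as plain text
#'
#' Long CSV of feature values (`%.17g`, so doubles round-trip exactly) plus
#' a labels CSV and a JSON sidecar for the generator specification.
#'
#' @param ds a `pattern_dataset`.
#' @param stem file stem; writes `<stem>_patterns.csv`, `<stem>_labels.csv`,
#'   `<stem>_meta.json`.
#' @return the reader returns a `pattern_dataset`; the writer returns `stem`
#'   invisibly.
#' @export
write_pattern_dataset <- function(ds, stem) {
  d <- dim(ds$patterns)
  flat <- matrix(sprintf("%.17g", aperm(ds$patterns, c(3L, 2L, 1L))),
                 nrow = d[1L] * d[2L], byrow = TRUE)
  hdr <- c("trial", "period", paste0("f", seq_len(d[3L])))
  idx <- cbind(rep(seq_len(d[1L]), each = d[2L]), rep(seq_len(d[2L]) - 1L, d[1L]))
  con <- file(paste0(stem, "_patterns.csv"), "w")
  writeLines(paste(hdr, collapse = ","), con)
  writeLines(paste(idx[, 1L], idx[, 2L],
                   apply(flat, 1L, paste, collapse = ","), sep = ","), con)
  close(con)
  utils::write.csv(ds$labels, paste0(stem, "_labels.csv"), row.names = FALSE)
  meta <- unclass(ds$spec); meta$subject_id <- ds$subject_id
  jsonlite::write_json(meta, paste0(stem, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname write_pattern_dataset
#' @export
read_pattern_dataset <- function(stem) {
  meta <- jsonlite::fromJSON(paste0(stem, "_meta.json"))
  sid <- meta$subject_id; meta$subject_id <- NULL
  spec <- do.call(pattern_spec, meta)
  labels <- utils::read.csv(paste0(stem, "_labels.csv"))
  raw <- utils::read.csv(paste0(stem, "_patterns.csv"))
  n <- max(raw$trial)
  nf <- ncol(raw) - 2L
  arr <- array(0, dim = c(n, 9L, nf))
  vals <- as.matrix(raw[, -(1:2)])
  for (r in seq_len(nrow(raw)))
    arr[raw$trial[r], raw$period[r] + 1L, ] <- vals[r, ]
  structure(list(patterns = arr, labels = labels, subject_id = sid,
                 spec = spec), class = "pattern_dataset")
}
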