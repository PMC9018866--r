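#' Negative log evidence of a behavior log under the behavioral model
#'
#' Runs the belief filter over every game and sums the negative log of the
#' per-action predictive probabilities (prediction trials contribute no
#' likelihood; the evidence is a product over action selections only).
#'
#' @param log a `behavior_log` (or trials data.frame).
#' @param m the `maze`.
#' @param params a `model_params`.
#' @param variant `"switching"`, `"forward_only"` or `"efficient_only"`;
#'   the single-strategy variants force the corresponding policy regardless
#'   of the confidence state.
#' @param engine `"cpp"` or `"r"` (see [filter_log()]).
#' @return nonnegative scalar.
#' @export
negative_log_evidence <- function(log, m, params, variant = "switching",
                                  engine = "cpp") {
  trials <- if (inherits(log, "behavior_log")) log$trials else log
  nle_seqs(game_sequences(trials), m, params, variant, engine)
}

nle_seqs <- function(seqs, m, params, variant, engine = "cpp") {
  total <- 0
  vcode <- match(variant, c("switching", "forward_only", "efficient_only")) - 1L
  for (gs in seqs) {
    pp <- if (engine == "cpp") {
      # direct call: skips the read-out assembly of the trace path
      out_label <- if (length(gs$pred_outcome_labels))
        gs$pred_outcome_labels[length(gs$pred_outcome_labels)] else -1L
      if (is.na(out_label)) out_label <- -1L
      cpp_filter_game(m$n_rows, m$n_cols, m$doors_ew, m$doors_ns,
                      gs$actions_idx, gs$scene_labels, as.integer(out_label),
                      integer(0), params$alpha, params$beta, params$p_lh,
                      params$p_hl, params$n_history, vcode, 0L, FALSE,
                      1e-8, 1e-10)$pred_probs
    } else {
      filter_game_r(gs, m, params, variant, "window", FALSE,
                    1e-8, 1e-10)$pred_probs
    }
    total <- total - sum(log(pp))
  }
  total
}

#' Optimizer settings for model fitting
#'
#' @param n_max upper end of the exhaustive grid over the backtrack window
#'   length `n_history` (searched over `1..n_max`).
#' @param n_starts multi-start count for the derivative-free search over the
#'   continuous parameters.
#' @param maxit,reltol Nelder-Mead iteration cap and relative tolerance.
#' @param bounds box for all continuous parameters (kept off 0/1 so the log
#'   evidence stays finite).
#' @param seed seed for the start points.
#' @param engine filter engine (see [filter_log()]).
#' @param count_n_as_param whether `n_history` counts as a free parameter in
#'   the AIC (it is fitted, so the default is `TRUE`).
#' @return an object of class `fit_settings`.
#' @export
fit_settings <- function(n_max = 3L, n_starts = 8L, maxit = 400L,
                         reltol = 1e-7, bounds = c(0.01, 0.99), seed = 1L,
                         engine = "cpp", count_n_as_param = TRUE) {
  structure(list(n_max = as.integer(n_max), n_starts = as.integer(n_starts),
                 maxit = as.integer(maxit), reltol = reltol, bounds = bounds,
                 seed = as.integer(seed), engine = engine,
                 count_n_as_param = count_n_as_param),
            class = "fit_settings")
}

variant_free_params <- function(variant) {
  switch(variant,
         switching = c("alpha", "beta", "p_lh", "p_hl"),
         forward_only = "alpha",
         efficient_only = "beta",
         stop("unknown model variant: ", variant))
}

params_from_vector <- function(theta, free, n_history) {
  base <- list(alpha = 0.5, beta = 0.5, p_lh = 0.5, p_hl = 0.5)
  base[free] <- as.list(theta)
  model_params(base$alpha, base$beta, base$p_lh, base$p_hl, n_history)
}

#' Fit the behavioral model to one subject by type-II maximum likelihood
#'
#' Minimizes the negative log evidence over the continuous parameters with a
#' seeded multi-start Nelder-Mead search on a logit-transformed box (Brent's
#' method for single-parameter variants), crossed with an exhaustive grid
#' over the backtrack window length `n_history`; the global best over the
#' grid is returned.
#'
#' @param log a `behavior_log`.
#' @param m the `maze`.
#' @param variant model variant (see [negative_log_evidence()]).
#' @param settings a `fit_settings`.
#' @return an object of class `fit_result`: `params_hat`, `nle`, `aic`,
#'   `n_free_params`, and `diagnostics` (per-start table, evaluation count,
#'   convergence flags).
#' @export
fit_subject <- function(log, m, variant = "switching",
                        settings = fit_settings()) {
  trials <- if (inherits(log, "behavior_log")) log$trials else log
  seqs <- game_sequences(trials)
  if (!length(seqs)) stop("log has no games")
  free <- variant_free_params(variant)
  lo <- settings$bounds[1L]; hi <- settings$bounds[2L]
  to_unit <- function(x) lo + (hi - lo) * stats::plogis(x)
  from_unit <- function(p) stats::qlogis((p - lo) / (hi - lo))
  n_eval <- 0L

  objective <- function(x, n_history) {
    n_eval <<- n_eval + 1L
    p <- params_from_vector(to_unit(x), free, n_history)
    nle_seqs(seqs, m, p, variant, settings$engine)
  }

  rng <- make_rng(settings$seed)
  starts <- matrix(rng$runif(settings$n_starts * length(free)) * 0.9 + 0.05,
                   nrow = settings$n_starts)
  best <- NULL
  diag_rows <- list()
  for (n_hist in seq_len(settings$n_max)) {
    for (i in seq_len(settings$n_starts)) {
      x0 <- from_unit(starts[i, ])
      if (length(free) == 1L) {
        op <- stats::optimize(function(x) objective(x, n_hist),
                              interval = from_unit(c(lo + 1e-6, hi - 1e-6)),
                              tol = 1e-6)
        res <- list(par = op$minimum, value = op$objective, convergence = 0L)
      } else {
        res <- stats::optim(x0, objective, n_history = n_hist,
                            method = "Nelder-Mead",
                            control = list(maxit = settings$maxit,
                                           reltol = settings$reltol))
      }
      start_nle <- objective(x0, n_hist)
      diag_rows[[length(diag_rows) + 1L]] <- data.frame(
        n_history = n_hist, start = i, start_nle = start_nle,
        nle = res$value, converged = res$convergence == 0L)
      if (is.null(best) || res$value < best$value)
        best <- list(value = res$value, par = res$par, n_history = n_hist,
                     converged = res$convergence == 0L)
      if (length(free) == 1L) break  # Brent is global on the interval
    }
  }
  n_free <- length(free) + as.integer(settings$count_n_as_param)
  params_hat <- params_from_vector(to_unit(best$par), free, best$n_history)
  structure(list(
    variant = variant,
    params_hat = params_hat,
    free_params = free,
    nle = best$value,
    aic = 2 * n_free + 2 * best$value,
    n_free_params = n_free,
    diagnostics = list(starts = do.call(rbind, diag_rows),
                       evaluations = n_eval, converged = best$converged)),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result %s: nle=%.2f aic=%.2f k=%d>\n", x$variant, x$nle,
              x$aic, x$n_free_params))
  print(x$params_hat)
  invisible(x)
}

#' Compare model variants on one subject
#'
#' Fits each variant and tabulates negative log evidence, AIC and parameter
#' counts; the AIC winner is flagged.
#'
#' @param log a `behavior_log`.
#' @param m the `maze`.
#' @param variants character vector of variants to fit.
#' @param settings a `fit_settings`.
#' @return data.frame with one row per variant and attribute `fits` holding
#'   the full `fit_result` objects.
#' @export
compare_models <- function(log, m,
                           variants = c("switching", "forward_only",
                                        "efficient_only"),
                           settings = fit_settings()) {
  stopifnot(length(variants) >= 2L)
  fits <- lapply(variants, function(v) fit_subject(log, m, v, settings))
  tab <- data.frame(
    variant = variants,
    nle = vapply(fits, `[[`, numeric(1), "nle"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    n_free_params = vapply(fits, `[[`, integer(1), "n_free_params"))
  tab$winner <- tab$aic == min(tab$aic)
  attr(tab, "fits") <- stats::setNames(fits, variants)
  tab
}
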