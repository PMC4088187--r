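random_stochastic <- function(nr, nc) {
  m <- matrix(runif(nr * nc, 0.05, 1), nr, nc)
  m / rowSums(m)
}

check_sequences <- function(sequences, K) {
  if (!is.list(sequences)) sequences <- list(sequences)
  sequences <- lapply(sequences, as.integer)
  for (s in sequences) {
    if (length(s) == 0) next
    if (any(s < 1 | s > K))
      stopf("symbol outside alphabet 1..%d", K)
  }
  if (sum(lengths(sequences)) == 0) stopf("no symbols to fit")
  sequences
}

#' Fit a discrete-emission hidden Markov model
#'
#' Baum-Welch (EM) over one or more label sequences. Initial distribution,
#' transition and emission rows are drawn from uniform distributions and
#' normalised; the best final log-likelihood over `restarts` seeded
#' restarts is kept. Convergence when the log-likelihood improves by less
#' than `tol` or after `max_iter` iterations. Within each restart the
#' log-likelihood trace is non-decreasing (EM guarantee).
#'
#' @param sequences integer vector or list of integer vectors with symbols
#'   in `1..K`.
#' @param k number of hidden states (>= 1).
#' @param K alphabet size (default: largest observed symbol).
#' @param seed RNG seed for the initialisations.
#' @param restarts number of random restarts (>= 1).
#' @param max_iter,tol EM stopping rule.
#' @return a `discrete_hmm`: list with `pi`, `A` (k x k), `B` (k x K),
#'   `loglik`, `ll_trace`, `k`, `K`, `n_obs`.
#' @export
fit_hmm <- function(sequences, k, K = NULL, seed = 1, restarts = 5,
                    max_iter = 500, tol = 1e-4) {
  if (k < 1) stopf("k must be >= 1")
  if (is.null(K)) K <- max(unlist(sequences))
  sequences <- check_sequences(sequences, K)
  obs <- unlist(sequences) - 1L
  lens <- lengths(sequences)
  best <- NULL
  seeds <- derive_seeds(seed, restarts)
  for (r in seq_len(restarts)) {
    init <- with_seed(seeds[r], {
      list(pi = as.numeric(random_stochastic(1, k)),
           A = random_stochastic(k, k),
           B = random_stochastic(k, K))
    })
    fit <- hmm_baum_welch_cpp(init$pi, init$A, init$B, obs, lens,
                              max_iter, tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  structure(list(pi = as.numeric(best$pi), A = best$A, B = best$B,
                 loglik = best$loglik, ll_trace = best$ll_trace,
                 k = k, K = K, n_obs = length(obs)),
            class = "discrete_hmm")
}

#' @export
print.discrete_hmm <- function(x, ...) {
  cat(sprintf("<discrete_hmm> k = %d states, K = %d symbols, logLik %.3f\n",
              x$k, x$K, x$loglik))
  invisible(x)
}

#' Log-likelihood of sequences under a fitted HMM
#'
#' @param model a `discrete_hmm`.
#' @param sequences integer vector or list of integer vectors.
#' @param normalize divide by the total number of symbols (removes
#'   sequence-length bias when comparing participants).
#' @return log-likelihood (scalar).
#' @export
hmm_loglik <- function(model, sequences, normalize = FALSE) {
  sequences <- check_sequences(sequences, model$K)
  ll <- sum(vapply(sequences, function(s) {
    hmm_loglik_cpp(model$pi, model$A, model$B, s - 1L)
  }, 0))
  if (normalize) ll / sum(lengths(sequences)) else ll
}

# Free-parameter count of a k-state, K-symbol discrete HMM.
hmm_n_params <- function(k, K) (k - 1) + k * (k - 1) + k * (K - 1)

#' Select the HMM state count by AIC + BIC
#'
#' Fits an HMM for every candidate state count and picks the one
#' minimising the sum of Akaike's and the Bayesian information criterion,
#' `AIC + BIC = -4 LL + p (2 + log n)` with `p` the free-parameter count
#' and `n` the total symbol count. Ties go to the smaller state count.
#'
#' @param sequences training sequences (vector or list).
#' @param K alphabet size.
#' @param candidates candidate state counts (default `1:8`).
#' @param seed,restarts,max_iter,tol passed to [fit_hmm()].
#' @return list with `k` (selected), `model` (fit at `k`), and `criteria`
#'   (data.frame: k, loglik, aic, bic, aic_bic).
#' @export
select_states <- function(sequences, K = NULL, candidates = 1:8, seed = 1,
                          restarts = 5, max_iter = 500, tol = 1e-4) {
  if (is.null(K)) K <- max(unlist(sequences))
  sequences <- check_sequences(sequences, K)
  n <- sum(lengths(sequences))
  fits <- vector("list", length(candidates))
  crit <- data.frame(k = candidates, loglik = NA_real_, aic = NA_real_,
                     bic = NA_real_, aic_bic = NA_real_)
  for (i in seq_along(candidates)) {
    k <- candidates[i]
    fits[[i]] <- fit_hmm(sequences, k, K, seed = seed + k,
                         restarts = restarts, max_iter = max_iter, tol = tol)
    p <- hmm_n_params(k, K)
    ll <- fits[[i]]$loglik
    crit$loglik[i] <- ll
    crit$aic[i] <- -2 * ll + 2 * p
    crit$bic[i] <- -2 * ll + p * log(n)
    crit$aic_bic[i] <- crit$aic[i] + crit$bic[i]
  }
  best <- which(crit$aic_bic == min(crit$aic_bic))[1]  # ties: smaller k first
  list(k = candidates[best], model = fits[[best]], criteria = crit)
}

#' Leave-one-out HMM group classification
#'
#' For each held-out participant, one HMM per group is trained on the
#' remaining participants' labelled GPS sequences (state count re-selected
#' per fold by AIC + BIC on the training data), the held-out sequence is
#' scored by its per-symbol-normalised log-likelihood under each model,
#' and assigned to the group with the higher score. Exact ties are broken
#' by a seeded fair coin (and logged via a message).
#'
#' @param sequences named list, one integer symbol sequence (or list of
#'   sequences) per participant.
#' @param groups participant group labels (two levels), aligned with
#'   `sequences`.
#' @param K alphabet size.
#' @param candidates candidate state counts per fold.
#' @param seed RNG seed.
#' @param restarts_select restarts during per-fold state selection.
#' @param restarts_fit restarts for the final per-fold fits (the selection
#'   fit at the chosen state count is refit with this many restarts when it
#'   exceeds `restarts_select`).
#' @param max_iter,tol EM stopping rule.
#' @return list with `accuracy`, `p_value` (exact one-sided binomial tail
#'   against 0.5), and `table` (per participant: truth, assigned, the two
#'   normalised log-likelihoods, `llr` = ll_first_group - ll_second_group,
#'   selected state counts).
#' @export
loo_classify <- function(sequences, groups, K = NULL, candidates = 1:8,
                         seed = 1, restarts_select = 2, restarts_fit = 5,
                         max_iter = 200, tol = 1e-4) {
  stopifnot(length(sequences) == length(groups))
  lv <- unique(groups)
  if (length(lv) != 2) stopf("need exactly two groups")
  if (min(table(groups)) < 2) stopf("need >= 2 participants per group")
  if (is.null(K)) K <- max(unlist(sequences))
  n <- length(sequences)
  ids <- names(sequences)
  if (is.null(ids)) ids <- sprintf("P%02d", seq_len(n))
  fold_seeds <- derive_seeds(seed, n)
  res <- data.frame(participant = ids, truth = groups,
                    assigned = NA_character_, ll_a = NA_real_,
                    ll_b = NA_real_, llr = NA_real_, k_a = NA_integer_,
                    k_b = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    train_g <- lapply(lv, function(g) {
      idx <- setdiff(which(groups == g), i)
      if (length(idx) == 0) stopf("fold with empty training group")
      unlist(lapply(sequences[idx],
                    function(s) if (is.list(s)) s else list(s)),
             recursive = FALSE)
    })
    models <- lapply(seq_along(lv), function(j) {
      sel <- select_states(train_g[[j]], K = K, candidates = candidates,
                           seed = fold_seeds[i] %% 100000L + j,
                           restarts = restarts_select, max_iter = max_iter,
                           tol = tol)
      m <- sel$model
      if (restarts_fit > restarts_select)
        m <- fit_hmm(train_g[[j]], sel$k, K,
                     seed = fold_seeds[i] %% 100000L + 10L + j,
                     restarts = restarts_fit, max_iter = max_iter, tol = tol)
      list(k = sel$k, model = m)
    })
    held <- sequences[[i]]
    ll <- vapply(models, function(m) hmm_loglik(m$model, held,
                                                normalize = TRUE), 0)
    assigned <- if (ll[1] > ll[2]) lv[1] else if (ll[2] > ll[1]) lv[2] else {
      message(sprintf("tied log-likelihoods for %s; seeded coin flip", ids[i]))
      with_seed(fold_seeds[i], sample(lv, 1))
    }
    res$assigned[i] <- assigned
    res$ll_a[i] <- ll[1]; res$ll_b[i] <- ll[2]
    res$llr[i] <- ll[1] - ll[2]
    res$k_a[i] <- models[[1]]$k; res$k_b[i] <- models[[2]]$k
  }
  acc <- mean(res$assigned == res$truth)
  list(accuracy = acc,
       p_value = classification_significance(acc, n),
       groups = lv, table = res)
}

#' Exact binomial significance of a classification accuracy
#'
#' One-sided exact tail probability `P(X >= round(accuracy * n))` for
#' `X ~ Binomial(n, 0.5)`: the null hypothesis of equal probability of
#' either class label being assigned.
#'
#' @param accuracy observed accuracy in \[0, 1\].
#' @param n number of classified participants.
#' @return p-value.
#' @export
classification_significance <- function(accuracy, n) {
  if (n <= 0) stopf("n must be positive")
  if (accuracy < 0 || accuracy > 1) stopf("accuracy must be in [0, 1]")
  x <- round(accuracy * n)
  sum(dbinom(x:n, n, 0.5))
}
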