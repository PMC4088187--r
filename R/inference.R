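# Encode two-level factors/characters as 0/1 for regression.
encode_predictors <- function(df, predictors) {
  for (p in predictors) {
    v <- df[[p]]
    if (is.character(v) || is.factor(v)) {
      lev <- sort(unique(as.character(v)))
      if (length(lev) > 2) stopf("predictor %s has > 2 levels", p)
      df[[p]] <- as.numeric(as.character(v) == lev[length(lev)])
    }
  }
  df
}

# p-value of a single coefficient in an OLS fit (NA if not estimable).
coef_p <- function(fit, term) {
  s <- summary(fit)$coefficients
  rn <- gsub("`", "", rownames(s))
  if (!term %in% rn) return(NA_real_)
  s[match(term, rn), 4]
}

#' Stepwise regression with p-value entry and removal
#'
#' Classic forward-entry / backward-removal stepwise ordinary least
#' squares: at each step the candidate predictor with the smallest partial
#' p-value enters if `p < p_enter`; any included predictor whose p-value
#' has risen above `p_remove` is then removed; iterate to a fixed point.
#' Predictors that are collinear with the current model (inestimable
#' coefficient) are skipped with a warning.
#'
#' @param data data.frame holding the criterion and predictors.
#' @param criterion name of the criterion column.
#' @param predictors candidate predictor names; two-level factors are
#'   encoded 0/1.
#' @param p_enter,p_remove entry and removal thresholds (0.05 / 0.10).
#' @return a `stepwise_result`: list with `selected`, `coefficients`,
#'   `p_values`, `r_squared` (ordinary coefficient of determination of the
#'   final model; 0 for the empty model), `model` (the `lm` fit or NULL)
#'   and `residuals`.
#' @export
stepwise_regression <- function(data, criterion = "value",
                                predictors = c("group", "age", "gender",
                                               "n_trials"),
                                p_enter = 0.05, p_remove = 0.10) {
  if (nrow(data) < 8) stopf("need >= 8 rows")
  miss <- setdiff(c(criterion, predictors), names(data))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  data <- encode_predictors(data, predictors)
  keep <- predictors[vapply(predictors,
                            function(p) length(unique(data[[p]])) > 1,
                            TRUE)]
  included <- character(0)
  fit_model <- function(terms) {
    f <- if (length(terms) == 0) sprintf("`%s` ~ 1", criterion) else
      sprintf("`%s` ~ %s", criterion, paste(sprintf("`%s`", terms),
                                            collapse = " + "))
    lm(stats::as.formula(f), data = data)
  }
  for (iter in seq_len(50)) {
    changed <- FALSE
    # forward step
    cands <- setdiff(keep, included)
    if (length(cands) > 0) {
      ps <- vapply(cands, function(p) {
        fit <- fit_model(c(included, p))
        pv <- coef_p(fit, p)
        if (is.na(pv)) {
          warnf("skipping collinear candidate %s", p)
          pv <- Inf
        }
        pv
      }, 0)
      if (min(ps) < p_enter) {
        included <- c(included, cands[which.min(ps)])
        changed <- TRUE
      }
    }
    # backward step
    if (length(included) > 0) {
      fit <- fit_model(included)
      ps <- vapply(included, function(p) coef_p(fit, p), 0)
      worst <- which.max(ps)
      if (length(ps) > 0 && ps[worst] > p_remove) {
        included <- included[-worst]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (length(included) == 0) {
    return(structure(list(selected = character(0), coefficients = numeric(0),
                          p_values = numeric(0), r_squared = 0,
                          model = NULL,
                          residuals = data[[criterion]] -
                            mean(data[[criterion]])),
                     class = "stepwise_result"))
  }
  fit <- fit_model(included)
  s <- summary(fit)
  cf <- coef(fit)[-1]
  names(cf) <- gsub("`", "", names(cf))
  cf <- cf[included]
  pv <- vapply(included, function(p) coef_p(fit, p), 0)
  structure(list(selected = included, coefficients = cf, p_values = pv,
                 r_squared = s$r.squared,
                 overall_p = {
                   f <- s$fstatistic
                   if (is.null(f)) NA_real_ else
                     pf(f[1], f[2], f[3], lower.tail = FALSE)
                 },
                 model = fit, residuals = stats::residuals(fit)),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  if (length(x$selected) == 0) {
    cat("<stepwise_result> no predictor entered\n")
  } else {
    cat(sprintf("<stepwise_result> selected: %s; r^2 = %.3f\n",
                paste(x$selected, collapse = ", "), x$r_squared))
  }
  invisible(x)
}

#' One-sample Kolmogorov-Smirnov normality check
#'
#' Standardises the sample by its mean and standard deviation and tests it
#' against the standard normal. Note that with estimated moments the plain
#' KS reference distribution is conservative (the Lilliefors effect); this
#' mirrors the common practice of gating t-tests on a KS check rather than
#' providing an exactly calibrated normality test.
#'
#' @param x numeric sample (n >= 3, non-zero variance).
#' @param standardize standardise by sample mean/sd first (default TRUE).
#' @return p-value.
#' @export
ks_normality <- function(x, standardize = TRUE) {
  if (length(x) < 3) stopf("need n >= 3")
  if (sd(x) == 0) stopf("zero variance sample")
  z <- if (standardize) (x - mean(x)) / sd(x) else x
  suppressWarnings(ks.test(z, "pnorm"))$p.value
}

#' Pooled-variance two-sample t-test with direction
#'
#' @param a,b numeric samples (>= 2 each).
#' @return list with `t`, `df`, `p` (two-sided), `direction` (`"A>B"`,
#'   `"B>A"` or `"A=B"`), and the group means.
#' @export
posthoc_ttest <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stopf("need >= 2 values per group")
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) stopf("zero pooled variance")
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  p <- 2 * pt(-abs(t), df)
  dir <- if (t > 0) "A>B" else if (t < 0) "B>A" else "A=B"
  list(t = t, df = df, p = p, direction = dir,
       mean_a = mean(a), mean_b = mean(b))
}

#' Run stepwise regressions over a long-format feature table
#'
#' One stepwise regression per cell of feature x condition x band x
#' segment (or per feature x condition for segment-free criteria such as
#' baseline power or log-likelihood ratios). Wherever `group` is selected,
#' a KS normality check gates a post-hoc pooled t-test between the groups.
#' All p-values are uncorrected and flagged as such.
#'
#' @param features long-format data.frame with columns `participant`,
#'   `group`, `age`, `gender`, `n_trials`, `feature`, `condition`, `band`,
#'   `segment`, `value` (`band`/`segment` may be NA).
#' @param p_enter,p_remove stepwise thresholds.
#' @return data.frame with one row per cell: selected predictors,
#'   `r_squared`, regression p of the group coefficient (NA when group not
#'   selected), post-hoc p-values, direction, and `p_uncorrected = TRUE`.
#' @export
run_feature_regressions <- function(features, p_enter = 0.05,
                                    p_remove = 0.10) {
  need <- c("participant", "group", "age", "gender", "n_trials", "feature",
            "condition", "band", "segment", "value")
  miss <- setdiff(need, names(features))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  cells <- unique(features[, c("feature", "condition", "band", "segment")])
  same <- function(a, b) (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sel <- features$feature == cells$feature[i] &
      features$condition == cells$condition[i] &
      same(features$band, cells$band[i]) &
      same(features$segment, cells$segment[i])
    cell <- features[sel & !is.na(features$value), , drop = FALSE]
    out <- data.frame(cells[i, , drop = FALSE], n = nrow(cell),
                      selected = NA_character_, r_squared = NA_real_,
                      group_p = NA_real_, ks_p = NA_real_,
                      ttest_p = NA_real_, direction = NA_character_,
                      p_uncorrected = TRUE, row.names = NULL)
    if (nrow(cell) >= 8 && length(unique(cell$group)) == 2) {
      sw <- tryCatch(
        stepwise_regression(cell, "value", p_enter = p_enter,
                            p_remove = p_remove),
        error = function(e) NULL)
      if (!is.null(sw)) {
        out$selected <- paste(sw$selected, collapse = "+")
        out$r_squared <- sw$r_squared
        if ("group" %in% sw$selected) {
          out$group_p <- sw$p_values[["group"]]
          ga <- cell$value[cell$group == sort(unique(cell$group))[1]]
          gb <- cell$value[cell$group == sort(unique(cell$group))[2]]
          out$ks_p <- tryCatch(ks_normality(cell$value), error = function(e) NA)
          tt <- tryCatch(posthoc_ttest(ga, gb), error = function(e) NULL)
          if (!is.null(tt)) {
            out$ttest_p <- tt$p
            out$direction <- tt$direction
          }
        }
      }
    }
    rows[[i]] <- out
  }
  do.call(rbind, rows)
}
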