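direction_of <- function(log2fc) {
  dplyr::case_when(log2fc > 0 ~ "up", log2fc < 0 ~ "down", TRUE ~ "flat")
}

group_stats <- function(study) {
  ci <- case_idx(study); ni <- control_idx(study)
  X <- study$values
  n1 <- length(ci); n2 <- length(ni)
  m1 <- rowMeans(X[, ci, drop = FALSE])
  m2 <- rowMeans(X[, ni, drop = FALSE])
  v1 <- rowSums((X[, ci, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((X[, ni, drop = FALSE] - m2)^2) / (n2 - 1)
  list(n1 = n1, n2 = n2, m1 = m1, m2 = m2, v1 = v1, v2 = v2)
}

#' Per-feature Welch t differential expression table
#'
#' Two-sided Welch (unequal-variance) t test per feature with
#' Welch-Satterthwaite degrees of freedom. The log2 fold change is the case
#' mean minus the control mean (values are log2 intensities). When both
#' groups have zero variance the record is degenerate: equal means give
#' t = 0, p = 1; unequal means give the smallest representable p and a
#' `degenerate` flag.
#'
#' @param study An [expression_study].
#' @return A tibble (class `de_table`) with columns `feature`, `log2fc`,
#'   `se`, `t`, `df`, `p`, `p_adj` (Benjamini-Hochberg), `direction`,
#'   `degenerate`.
#' @export
welch_t_table <- function(study) {
  gs <- group_stats(study)
  if (gs$n1 < 2 || gs$n2 < 2) stop("need >=2 samples per group", call. = FALSE)
  diff <- gs$m1 - gs$m2
  se2 <- gs$v1 / gs$n1 + gs$v2 / gs$n2
  df <- se2^2 / ((gs$v1 / gs$n1)^2 / (gs$n1 - 1) +
                   (gs$v2 / gs$n2)^2 / (gs$n2 - 1))
  t_stat <- diff / sqrt(se2)
  p <- pmax(2 * pt(abs(t_stat), df, lower.tail = FALSE),
            .Machine$double.xmin)

  degenerate <- se2 == 0
  zero_eq <- degenerate & diff == 0
  zero_ne <- degenerate & diff != 0
  t_stat[zero_eq] <- 0; p[zero_eq] <- 1; df[zero_eq] <- gs$n1 + gs$n2 - 2
  t_stat[zero_ne] <- sign(diff[zero_ne]) * Inf
  p[zero_ne] <- .Machine$double.xmin
  df[zero_ne] <- gs$n1 + gs$n2 - 2
  degenerate <- zero_ne

  out <- tibble::tibble(
    feature = rownames(study$values),
    log2fc = unname(diff),
    se = unname(sqrt(se2)),
    t = unname(t_stat),
    df = unname(df),
    p = unname(p),
    p_adj = bh_adjust(unname(p)),
    direction = direction_of(unname(diff)),
    degenerate = unname(degenerate)
  )
  structure(out, class = c("de_table", class(out)))
}

# Newton inversion of trigamma, as used for empirical-Bayes moment matching
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-8) break
  }
  y
}

#' Empirical-Bayes moderated t differential expression table
#'
#' Pooled within-group variances are shrunk toward a common prior by the
#' standard empirical-Bayes scheme: the prior degrees of freedom `d0` and
#' prior variance `s0^2` are estimated by moment matching of the log sample
#' variances (equating their observed mean and variance to those of a scaled
#' F distribution), the posterior variance is
#' `(d0*s0^2 + d*s^2) / (d0 + d)`, and the moderated t uses `d + d0` degrees
#' of freedom. With fewer than `min_features` features the hyperparameters
#' cannot be estimated and the function falls back to [welch_t_table()] with
#' a warning.
#'
#' @inheritParams welch_t_table
#' @param min_features Minimum number of features for hyperparameter
#'   estimation (default 10).
#' @return A `de_table` tibble (see [welch_t_table()]) plus columns `s2_post`,
#'   `d0`, `s0_2`.
#' @export
moderated_t_table <- function(study, min_features = 10) {
  if (nrow(study$values) < min_features) {
    warning("fewer than ", min_features,
            " features: falling back to welch_t_table()", call. = FALSE)
    return(welch_t_table(study))
  }
  gs <- group_stats(study)
  if (gs$n1 < 2 || gs$n2 < 2) stop("need >=2 samples per group", call. = FALSE)
  d <- gs$n1 + gs$n2 - 2
  s2 <- ((gs$n1 - 1) * gs$v1 + (gs$n2 - 1) * gs$v2) / d

  z <- log(s2[s2 > 0 & is.finite(s2)])
  e_z <- mean(z); v_z <- var(z)
  # Var(log s^2) = trigamma(d/2) + trigamma(d0/2); E uses digammas
  rhs <- v_z - trigamma(d / 2)
  if (is.na(rhs) || rhs <= 0) {
    # no excess dispersion in the log variances: complete shrinkage to the
    # plain average sample variance
    d0 <- Inf
    s0_2 <- mean(s2[is.finite(s2)])
  } else {
    d0 <- 2 * trigamma_inverse(rhs)
    s0_2 <- exp(e_z + digamma(d0 / 2) - digamma(d / 2) -
                  log(d0 / 2) + log(d / 2))
  }
  s2_post <- if (is.infinite(d0)) rep(s0_2, length(s2)) else
    (d0 * s0_2 + d * s2) / (d0 + d)

  diff <- gs$m1 - gs$m2
  se <- sqrt(s2_post * (1 / gs$n1 + 1 / gs$n2))
  t_stat <- diff / se
  # total df capped at the pooled residual df across all features
  df_tot <- min(d + d0, d * length(s2))
  p <- pmax(2 * pt(abs(t_stat), df = df_tot, lower.tail = FALSE),
            .Machine$double.xmin)
  out <- tibble::tibble(
    feature = rownames(study$values),
    log2fc = unname(diff),
    se = unname(se),
    t = unname(t_stat),
    df = df_tot,
    p = unname(p),
    p_adj = bh_adjust(unname(p)),
    direction = direction_of(unname(diff)),
    degenerate = FALSE,
    s2_post = unname(s2_post),
    d0 = d0,
    s0_2 = s0_2
  )
  structure(out, class = c("de_table", class(out)))
}

#' Combine per-study p values by Fisher's method
#'
#' For each feature present in every study, the Fisher statistic
#' `X2 = -2 * sum(log(p))` is referred to a chi-square distribution with
#' `2k` degrees of freedom (`k` studies). The consensus log2 fold change is
#' the inverse-variance weighted mean of the per-study fold changes; features
#' whose per-study fold changes disagree in sign are flagged `discordant`.
#'
#' @param tables List of `de_table` tibbles (from [welch_t_table()] or
#'   [moderated_t_table()]). Features missing from any study are dropped.
#' @return A tibble of class `meta_de_table` with columns `feature`,
#'   `log2fc`, `x2`, `df`, `p`, `p_adj`, `direction`, `discordant` and one
#'   `p_<study>` column per input table.
#' @export
fisher_combine <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1)
  feats <- Reduce(intersect, lapply(tables, function(t) t$feature))
  if (length(feats) == 0) stop("no shared features across studies", call. = FALSE)
  k <- length(tables)
  nm <- names(tables)
  if (is.null(nm) || any(!nzchar(nm))) nm <- sprintf("study%d", seq_len(k))

  aligned <- lapply(tables, function(t) {
    t[match(feats, t$feature), , drop = FALSE]
  })
  p_mat <- vapply(aligned, function(t) t$p, numeric(length(feats)))
  p_mat <- matrix(p_mat, ncol = k)
  if (any(p_mat <= 0)) stop("p values must be in (0, 1]", call. = FALSE)
  fc_mat <- matrix(vapply(aligned, function(t) t$log2fc, numeric(length(feats))),
                   ncol = k)
  w_mat <- matrix(vapply(aligned, function(t) 1 / pmax(t$se, 1e-12)^2,
                         numeric(length(feats))), ncol = k)

  x2 <- -2 * rowSums(log(p_mat))
  p_comb <- pchisq(x2, df = 2 * k, lower.tail = FALSE)
  p_comb <- pmax(p_comb, .Machine$double.xmin)
  fc <- rowSums(fc_mat * w_mat) / rowSums(w_mat)
  discordant <- apply(sign(fc_mat), 1, function(s) {
    s <- s[s != 0]; length(unique(s)) > 1
  })

  out <- tibble::tibble(
    feature = feats,
    log2fc = fc,
    x2 = x2,
    df = 2L * k,
    p = p_comb,
    p_adj = bh_adjust(p_comb),
    direction = direction_of(fc),
    discordant = discordant
  )
  for (j in seq_len(k)) out[[paste0("p_", nm[j])]] <- p_mat[, j]
  structure(out, class = c("meta_de_table", class(out)))
}

#' Call differentially expressed features
#'
#' Two rule sets are supported. With `fc_threshold = NULL` (the human-study
#' rule) a feature is called when its raw p value is strictly below
#' `p_threshold`. With a fold-change threshold (the rat-study rule) the
#' inequalities are inclusive: `p <= p_threshold` and linear fold change
#' `>= fc_threshold` (i.e. `|log2fc| >= log2(fc_threshold)`).
#'
#' @param table A `de_table` or `meta_de_table`.
#' @param p_threshold P-value cutoff (default 0.05).
#' @param fc_threshold Linear fold-change cutoff, or `NULL` for no
#'   fold-change filter.
#' @return The subset of `table` that passes, same columns.
#' @export
call_de <- function(table, p_threshold = 0.05, fc_threshold = NULL) {
  stopifnot(p_threshold >= 0, p_threshold <= 1)
  if (is.null(fc_threshold)) {
    keep <- table$p < p_threshold
  } else {
    stopifnot(fc_threshold >= 1)
    keep <- table$p <= p_threshold &
      abs(table$log2fc) >= log2(fc_threshold)
  }
  table[keep, , drop = FALSE]
}
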