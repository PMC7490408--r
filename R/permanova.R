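#' Univariate permutation ANOVA (Euclidean distance)
#'
#' One-way permutational analysis of variance: the pseudo-F statistic is
#' computed by partitioning the matrix of squared Euclidean distances
#' into among- and within-group sums of squares, and its significance is
#' assessed by permuting group labels. On univariate data this pseudo-F
#' is identical to the classical one-way ANOVA F; the permutation p-value
#' replaces the normal-theory one and is
#' \eqn{p = (\#\{F^{perm} \ge F^{obs}\} + 1) / (n_{perm} + 1)},
#' the +1 counting the observed ordering so p can never be zero.
#'
#' @param values numeric vector of observations.
#' @param groups factor (or coercible) of group labels; every group needs
#'   at least 2 observations. Unbalanced designs are handled.
#' @param n_perm number of label permutations (default 9999).
#' @param seed optional integer seed; seeded runs are reproducible.
#' @return Object of class `perm_anova`: `pseudo_f`, `df`, `p_perm`,
#'   `n_perm`, `seed`, `ss` (among/within sums of squares).
#' @examples
#' set.seed(1)
#' perm_anova(c(rnorm(5), rnorm(5, 2)), rep(c("a", "b"), each = 5),
#'            n_perm = 199, seed = 42)
#' @export
perm_anova <- function(values, groups, n_perm = 9999, seed = NULL) {
  groups <- factor(groups)
  stopifnot(is.numeric(values), length(values) == length(groups))
  n_g <- table(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(n_g < 2)) stop("every group needs at least 2 observations")
  n <- length(values)
  a <- nlevels(groups)
  # squared Euclidean distances; SS via the Gower identity
  d2 <- outer(values, values, function(x, y) (x - y)^2)
  ss_total <- sum(d2) / (2 * n)
  within_ss <- function(lab) {
    s <- 0
    for (g in levels(groups)) {
      idx <- lab == g
      s <- s + sum(d2[idx, idx]) / (2 * sum(idx))
    }
    s
  }
  f_of <- function(lab) {
    ssw <- within_ss(lab)
    ssa <- ss_total - ssw
    if (ss_total == 0) return(0)
    (ssa / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_of(groups)
  if (!is.null(seed)) set.seed(seed)
  f_perm <- vapply(seq_len(n_perm), function(i)
    f_of(groups[sample.int(n)]), numeric(1))
  if (ss_total == 0) {
    p <- 1
  } else {
    p <- (sum(f_perm >= f_obs - 1e-12) + 1) / (n_perm + 1)
  }
  structure(list(pseudo_f = f_obs, df = c(a - 1, n - a), p_perm = p,
                 n_perm = n_perm, seed = seed,
                 ss = c(among = ss_total - within_ss(groups),
                        within = within_ss(groups))),
            class = "perm_anova")
}

#' @export
print.perm_anova <- function(x, ...) {
  cat("Univariate PERMANOVA (Euclidean distance)\n")
  cat(sprintf("  pseudo-F(%d, %d) = %.4g,  P(perm) = %.4g  [%d permutations]\n",
              x$df[1], x$df[2], x$pseudo_f, x$p_perm, x$n_perm))
  invisible(x)
}

#' Pairwise post hoc permutation tests
#'
#' Two-group permutation tests for every pair of levels, run after a
#' significant omnibus test. P-values are uncorrected by default (the
#' convention of the permutation-ANOVA software this mirrors); set
#' `adjust = "holm"` for a familywise correction.
#'
#' @inheritParams perm_anova
#' @param adjust p-value adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`).
#' @return data.frame with one row per pair: group1, group2, pseudo_f,
#'   p_perm (and `p_adj` when adjusted).
#' @export
pairwise_posthoc <- function(values, groups, n_perm = 9999, seed = NULL,
                             adjust = "none") {
  groups <- factor(groups)
  lev <- levels(groups)
  if (length(lev) < 2) stop("need at least 2 groups")
  pairs <- combn(lev, 2)
  if (!is.null(seed)) set.seed(seed)
  out <- apply(pairs, 2, function(pr) {
    idx <- groups %in% pr
    fit <- perm_anova(values[idx], droplevels(groups[idx]), n_perm = n_perm)
    data.frame(group1 = pr[1], group2 = pr[2],
               pseudo_f = fit$pseudo_f, p_perm = fit$p_perm)
  })
  out <- do.call(rbind, out)
  if (adjust != "none") out$p_adj <- p.adjust(out$p_perm, method = adjust)
  out
}

#' Two-factor crossed permutation ANOVA (Type III, residual permutation)
#'
#' Tests each term of a two-way crossed design by permutation of
#' reduced-model residuals (Freedman-Lane): for each term, the reduced
#' model omits that term (Type III partial sums of squares, sum-to-zero
#' contrasts), residuals are permuted and added back to the reduced fit,
#' and the term's partial F is recomputed. Suitable for balanced to
#' moderately unbalanced designs; heavily unbalanced or nested designs
#' are out of scope.
#'
#' @param values numeric response.
#' @param f1,f2 factors (crossed).
#' @param n_perm permutations per term (default 9999).
#' @param seed optional integer seed.
#' @return data.frame, one row per term (`f1`, `f2`, `f1:f2`):
#'   partial F and P(perm).
#' @export
perm_anova2 <- function(values, f1, f2, n_perm = 9999, seed = NULL) {
  f1 <- factor(f1); f2 <- factor(f2)
  stopifnot(length(values) == length(f1), length(f1) == length(f2))
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  dat <- data.frame(y = values, f1 = f1, f2 = f2)
  X_full <- model.matrix(~ f1 * f2, dat)
  asg <- attr(X_full, "assign")      # 0 = intercept, 1 = f1, 2 = f2, 3 = f1:f2
  terms <- c("f1" = 1L, "f2" = 2L, "f1:f2" = 3L)
  qr_full <- qr(X_full)
  rss <- function(qrX, y) sum(qr.resid(qrX, y)^2)
  df_res <- nrow(X_full) - qr_full$rank
  if (df_res < 1) stop("no residual degrees of freedom")
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(names(terms), function(tm) {
    keep <- asg != terms[[tm]]
    qr_red <- qr(X_full[, keep, drop = FALSE])
    df_t <- qr_full$rank - qr_red$rank
    f_stat <- function(y) {
      r1 <- rss(qr_full, y)
      ((rss(qr_red, y) - r1) / df_t) / (r1 / df_res)
    }
    f_obs <- f_stat(values)
    fit_red <- qr.fitted(qr_red, values)
    res_red <- values - fit_red
    f_perm <- vapply(seq_len(n_perm), function(i)
      f_stat(fit_red + res_red[sample.int(length(res_red))]), numeric(1))
    data.frame(term = tm, df = df_t, pseudo_f = f_obs,
               p_perm = (sum(f_perm >= f_obs - 1e-12) + 1) / (n_perm + 1))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
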