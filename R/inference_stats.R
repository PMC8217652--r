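## Bootstrap paired/independent t-tests, Bonferroni correction, Cohen's d
## conventions, and the two-sample permutation test used for the coherence
## comparison.

#' Paired bootstrap t-test
#'
#' Classical paired t statistic and 95% CI on the mean difference
#' (t-distribution, df = n - 1), with a two-sided bootstrap p-value from
#' resampling the paired differences with replacement (percentile method:
#' twice the smaller tail probability of the resampled mean-difference
#' distribution around zero). Effect size is the paired Cohen's d
#' `|t| / sqrt(n)`.
#'
#' @param a,b numeric vectors of per-participant values, paired by position.
#' @param n_boot bootstrap iterations (default 1000).
#' @param seed integer seed.
#' @return List of class `paired_test`: `mean_a`, `mean_b`, `ci_low`,
#'   `ci_high`, `t`, `p_classical`, `p` (bootstrap), `d`, `n`.
#' @export
paired_bootstrap_t <- function(a, b, n_boot = 1000, seed = 1L) {
  if (length(a) != length(b))
    fl_stop("LengthMismatch", "paired samples differ in length")
  n <- length(a)
  if (n < 3) fl_stop("TooFewPairs", "need >= 3 pairs, got %d", n)
  d_i <- a - b
  md <- mean(d_i)
  se <- sd(d_i) / sqrt(n)
  t_stat <- if (se == 0) 0 else md / se
  tcrit <- qt(0.975, df = n - 1)
  set.seed(seed)
  boot <- replicate(n_boot, mean(sample(d_i, replace = TRUE)))
  p_boot <- min(1, 2 * min(mean(boot <= 0), mean(boot >= 0)))
  structure(list(mean_a = mean(a), mean_b = mean(b),
                 ci_low = md - tcrit * se, ci_high = md + tcrit * se,
                 t = t_stat,
                 p_classical = if (se == 0) 1
                               else 2 * stats::pt(-abs(t_stat), df = n - 1),
                 p = p_boot, d = cohens_d_paired(t_stat, n), n = n),
            class = "paired_test")
}

#' Paired Cohen's d from the t statistic
#'
#' The convention `d = |t| / sqrt(n)` (the standardised mean of the paired
#' differences), which reproduces published effect-size columns computed
#' with the common online calculators.
#'
#' @param t paired t statistic.
#' @param n number of pairs (>= 1).
#' @return Non-negative effect size.
#' @export
cohens_d_paired <- function(t, n) {
  stopifnot(n >= 1)
  abs(t) / sqrt(n)
}

#' Independent-samples bootstrap t-test
#'
#' Welch t statistic and CI, a two-sided bootstrap p-value from group-wise
#' resampling (percentile method on the resampled mean difference), and
#' pooled-SD Cohen's d.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @inheritParams paired_bootstrap_t
#' @return List of class `paired_test` (same shape as
#'   [paired_bootstrap_t()]).
#' @export
independent_bootstrap_t <- function(a, b, n_boot = 1000, seed = 1L) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) fl_stop("TooFewValues", "each group needs >= 2")
  md <- mean(a) - mean(b)
  va <- var(a); vb <- var(b)
  se <- sqrt(va / na + vb / nb)
  df <- if (se == 0) na + nb - 2
        else (va / na + vb / nb)^2 /
          ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  t_stat <- if (se == 0) 0 else md / se
  sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  set.seed(seed)
  boot <- replicate(n_boot, mean(sample(a, replace = TRUE)) -
                            mean(sample(b, replace = TRUE)))
  p_boot <- min(1, 2 * min(mean(boot <= 0), mean(boot >= 0)))
  tcrit <- qt(0.975, df = df)
  structure(list(mean_a = mean(a), mean_b = mean(b),
                 ci_low = md - tcrit * se, ci_high = md + tcrit * se,
                 t = t_stat,
                 p_classical = if (se == 0) 1
                               else 2 * stats::pt(-abs(t_stat), df = df),
                 p = p_boot,
                 d = if (sp == 0) 0 else abs(md) / sp,
                 n = c(na, nb)), class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf(paste0("<test> means %.4f vs %.4f, t = %.3f, ",
                     "95%% CI [%.4f, %.4f], bootstrap p = %.3f, d = %.3f\n"),
              x$mean_a, x$mean_b, x$t, x$ci_low, x$ci_high, x$p, x$d))
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise level (default 0.05).
#' @param m number of comparisons (>= 1).
#' @return `alpha / m` (report rounded to 3 decimals: 0.05 over 7
#'   comparisons gives 0.007).
#' @export
bonferroni_alpha <- function(alpha = 0.05, m = 1) {
  stopifnot(m >= 1, alpha > 0)
  alpha / m
}

#' Two-sample permutation test on the difference of means
#'
#' Labels are permuted uniformly at random; the two-sided p-value uses the
#' add-one convention `p = (#{|perm| >= |obs|} + 1) / (n_perm + 1)`, so
#' p is never 0 and is valid under the null. Effect size is pooled-SD
#' Cohen's d of the observed difference.
#'
#' @param a,b numeric vectors (non-empty).
#' @param n_perm number of label permutations (default 10000).
#' @param seed integer seed.
#' @return List of class `permutation_test`: `observed`, `p`, `n_perm`,
#'   `d`, `seed`.
#' @export
permutation_test <- function(a, b, n_perm = 10000, seed = 1L) {
  na <- length(a); nb <- length(b)
  if (na < 1 || nb < 1) fl_stop("TooFewValues", "both groups must be non-empty")
  pool <- c(a, b)
  if (length(unique(pool)) == 1L)
    fl_stop("DegenerateGroups", "all values identical across both groups")
  obs <- mean(a) - mean(b)
  n <- na + nb
  set.seed(seed)
  ## vectorised: each column one permutation of group-a membership
  idx <- replicate(n_perm, sample.int(n, na))
  suma <- colSums(matrix(pool[idx], nrow = na))
  perm <- suma / na - (sum(pool) - suma) / nb
  p <- (sum(abs(perm) >= abs(obs) - 1e-12) + 1) / (n_perm + 1)
  sp <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2))
  structure(list(observed = obs, p = p, n_perm = n_perm,
                 d = if (sp == 0) Inf else abs(obs) / sp, seed = seed),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("<permutation_test> observed diff %.4f, p = %.4f (%d perms), d = %.3f\n",
              x$observed, x$p, x$n_perm, x$d))
  invisible(x)
}

#' Paired AU comparison table for a cohort
#'
#' Runs [paired_bootstrap_t()] (lie vs truth) per AU on the per-clip mean
#' scores and returns a table shaped like the published paired-comparison
#' table: per-AU group means, 95% CI of the mean difference, t, bootstrap
#' p, and effect size, with the Bonferroni threshold attached.
#'
#' @param summaries data.frame from [cohort_mean_aus()].
#' @param au_set AU ids to compare.
#' @param alpha family-wise level.
#' @param n_boot,seed bootstrap settings.
#' @return data.frame with attribute `alpha_bonferroni`.
#' @export
au_comparison_table <- function(summaries, au_set = FEAR_AUS_7,
                                alpha = 0.05, n_boot = 1000, seed = 1L) {
  s <- summaries[order(summaries$participant_id), ]
  lie <- s[s$condition == "lie", ]
  truth <- s[s$condition == "truth", ]
  if (!identical(lie$participant_id, truth$participant_id))
    fl_stop("MixedIdentity", "unpaired participants in summary table")
  rows <- lapply(au_set, function(au) {
    col <- paste0("AU", au)
    r <- paired_bootstrap_t(lie[[col]], truth[[col]], n_boot, seed)
    data.frame(feature = col, mean_deception = r$mean_a,
               mean_truth = r$mean_b, ci_low = r$ci_low,
               ci_high = r$ci_high, t = r$t, p = r$p, d = r$d,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha_bonferroni") <- bonferroni_alpha(alpha, length(au_set))
  out
}
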