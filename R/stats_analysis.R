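## Split-plot (mixed) ANOVA and Student-Newman-Keuls post hoc tests.
##
## Design: one between-subjects factor (abductor group) and one
## repeated measure (F_ap level) on a balanced cohort. Sums of squares
## are computed from first principles: the between-subjects stratum
## tests the group effect against specimen-within-group variation, the
## within-subjects stratum tests the F_ap main effect and the
## group x F_ap interaction against the specimen x F_ap residual.
## Sphericity is assumed by default (a Greenhouse-Geisser correction is
## available but off, matching the unadjusted repeated-measures
## analysis being reproduced). "Significance level of 95%" is read as
## alpha = 0.05.

#' Split-plot ANOVA for a cohort metric
#'
#' @param table Long-format cohort table with columns `specimen_id`,
#'   `group`, `fap_level`, `metric`, `value` (one row per specimen per
#'   F_ap level per metric).
#' @param metric_name Which metric to analyse.
#' @param gg Apply the Greenhouse-Geisser sphericity correction to the
#'   within-subject tests? Default `FALSE`.
#' @return Object of class `anova_result`: `effects` data frame (rows
#'   `group`, `fap`, `group:fap` with SS, df pairs, MS, F, p), error
#'   terms `ms_subjects` / `df_subjects` (between) and `ms_error` /
#'   `df_error` (within), the SS decomposition, and cell counts.
#' @export
split_plot_anova <- function(table, metric_name, gg = FALSE) {
  d <- table[table$metric == metric_name, , drop = FALSE]
  if (!nrow(d)) stop("metric '", metric_name, "' not found in the table")
  d$group <- factor(d$group)
  d$fap_level <- factor(d$fap_level)
  d$specimen_id <- factor(d$specimen_id)
  a <- nlevels(d$group)
  b <- nlevels(d$fap_level)
  tab <- stats::xtabs(~ specimen_id + fap_level, d)
  if (any(tab != 1))
    stop("unbalanced design: every specimen must appear exactly once ",
         "per F_ap level for metric '", metric_name, "'")
  spec_group <- stats::aggregate(group ~ specimen_id, d, unique)
  n_by_group <- table(spec_group$group)
  if (length(unique(n_by_group)) != 1 || any(n_by_group < 2))
    stop("unbalanced design: groups must have equal n >= 2")
  n <- unname(n_by_group[1])
  gm <- mean(d$value)
  A <- tapply(d$value, d$group, mean)
  B <- tapply(d$value, d$fap_level, mean)
  AB <- tapply(d$value, list(d$group, d$fap_level), mean)
  M <- tapply(d$value, d$specimen_id, mean)
  ss_total <- sum((d$value - gm)^2)
  ss_between <- b * sum((M - gm)^2)
  ss_A <- n * b * sum((A - gm)^2)
  ss_subj <- ss_between - ss_A
  ss_B <- a * n * sum((B - gm)^2)
  ss_AB <- n * sum((AB - outer(A, rep(1, b)) -
                      outer(rep(1, a), B) + gm)^2)
  ss_err <- ss_total - ss_between - ss_B - ss_AB
  df_A <- a - 1; df_subj <- a * (n - 1)
  df_B <- b - 1; df_AB <- (a - 1) * (b - 1)
  df_err <- a * (n - 1) * (b - 1)
  ms_subj <- ss_subj / df_subj
  ms_err <- ss_err / df_err
  eps <- 1
  if (gg) {
    ## Greenhouse-Geisser epsilon from the pooled within-group
    ## covariance of the b repeated measures
    Y <- stats::xtabs(value ~ specimen_id + fap_level, d)
    grp <- spec_group$group[match(rownames(Y), spec_group$specimen_id)]
    S <- Reduce(`+`, lapply(split(seq_len(nrow(Y)), grp), function(i)
      stats::cov(Y[i, , drop = FALSE]) * (length(i) - 1))) / (a * (n - 1))
    dbar <- mean(diag(S)); mbar <- mean(S)
    eps <- (b * (dbar - mbar))^2 /
      ((b - 1) * (sum(S^2) - 2 * b * mean(rowMeans(S)^2) + b^2 * mbar^2))
    eps <- min(1, max(1 / (b - 1), eps))
  }
  Fs <- c(group = (ss_A / df_A) / ms_subj,
          fap = (ss_B / df_B) / ms_err,
          `group:fap` = (ss_AB / df_AB) / ms_err)
  ## a perfectly flat table has 0/0 effects: report F = 0, p = 1
  flat <- !is.finite(Fs) & c(ss_A, ss_B, ss_AB) < 1e-300
  Fs[flat] <- 0
  effects <- data.frame(
    effect = c("group", "fap", "group:fap"),
    SS = c(ss_A, ss_B, ss_AB),
    df1 = c(df_A, df_B, df_AB),
    df2 = c(df_subj, df_err, df_err),
    MS = c(ss_A / df_A, ss_B / df_B, ss_AB / df_AB),
    F = unname(Fs),
    p = c(stats::pf(Fs[1], df_A, df_subj, lower.tail = FALSE),
          stats::pf(Fs[2], df_B * eps, df_err * eps, lower.tail = FALSE),
          stats::pf(Fs[3], df_AB * eps, df_err * eps, lower.tail = FALSE)))
  structure(list(metric = metric_name, effects = effects,
                 ss_subjects = ss_subj, ms_subjects = ms_subj,
                 df_subjects = df_subj,
                 ss_error = ss_err, ms_error = ms_err, df_error = df_err,
                 ss_total = ss_total, n_per_group = n, a = a, b = b,
                 gg_epsilon = eps,
                 cell_means = AB),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("Split-plot ANOVA:", x$metric, "\n")
  print(transform(x$effects, F = signif(F, 4), p = signif(p, 3)),
        row.names = FALSE)
  invisible(x)
}

## ---- studentized range distribution --------------------------------------
##
## Implemented by direct numerical integration (not table lookup):
## P(Q <= q; k, df) = E_s[ P(range of k std normals <= q s) ] with
## s = sqrt(chi^2_df / df).

prange_normal <- function(w, k) {
  if (w <= 0) return(0)
  f <- function(z) k * stats::dnorm(z) *
    (stats::pnorm(z) - stats::pnorm(z - w))^(k - 1)
  stats::integrate(f, -Inf, Inf, rel.tol = 1e-9)$value
}

#' Studentized range distribution by numerical quadrature
#'
#' Distribution of the range of `k` independent standard normals
#' divided by an independent chi estimate of the scale on `df` degrees
#' of freedom, evaluated by nested numerical integration.
#'
#' @param q Quantile (scalar).
#' @param k Number of means spanned.
#' @param df Error degrees of freedom (`Inf` allowed).
#' @return `ptukey_range`: lower-tail probability. `qtukey_range`: the
#'   `p` quantile, found by root bracketing on `ptukey_range`.
#' @export
ptukey_range <- function(q, k, df) {
  if (q <= 0) return(0)
  if (!is.finite(df)) return(prange_normal(q, k))
  ldc <- (df / 2) * log(df / 2) - lgamma(df / 2) + log(2)
  f <- function(s) vapply(s, function(si)
    exp(ldc + (df - 1) * log(si) - df * si^2 / 2) *
      prange_normal(q * si, k), numeric(1))
  stats::integrate(f, 0, Inf, rel.tol = 1e-8)$value
}

#' @rdname ptukey_range
#' @param p Lower-tail probability.
#' @export
qtukey_range <- function(p, k, df) {
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  lo <- 1e-3; hi <- 10
  while (ptukey_range(hi, k, df) < p) hi <- hi * 2
  stats::uniroot(function(q) ptukey_range(q, k, df) - p, c(lo, hi),
                 tol = 1e-7)$root
}

## ---- Student-Newman-Keuls -------------------------------------------------

#' Student-Newman-Keuls step-down comparisons
#'
#' Orders the means and steps down: the range spanning `r` ordered means
#' is compared against the studentized-range critical value for span
#' `r`; a range that fails is declared homogeneous and none of its
#' inner pairs are tested (the protection that distinguishes SNK from
#' unprotected pairwise testing). Critical values come from
#' [qtukey_range()].
#'
#' @param level_means Named numeric vector of group/level means.
#' @param error_ms Error mean square.
#' @param error_df Error degrees of freedom.
#' @param n_per_mean Observations per mean.
#' @param alpha Familywise level per span (0.05).
#' @return Object of class `posthoc_result`: `ordered_means`, `pairs`
#'   (data frame with the studentized range, critical value and
#'   decision per pair) and `subsets` (homogeneous subsets as index
#'   vectors into the ordered means).
#' @export
snk_posthoc <- function(level_means, error_ms, error_df, n_per_mean,
                        alpha = 0.05) {
  if (!is.finite(error_ms) || error_ms <= 0)
    stop("error_ms must be > 0")
  if (error_df < 1) stop("error_df must be >= 1")
  if (n_per_mean < 2) stop("n_per_mean must be >= 2")
  k <- length(level_means)
  if (is.null(names(level_means)))
    names(level_means) <- paste0("m", seq_len(k))
  ord <- order(level_means)
  m <- level_means[ord]
  se <- sqrt(error_ms / n_per_mean)
  qcrit <- c(NA_real_, vapply(2:max(2, k), function(r)
    qtukey_range(1 - alpha, r, error_df), numeric(1)))
  sig <- matrix(NA, k, k)   # sig[i,j] for i<j in the ordered scale
  mark_ns <- function(lo, hi)
    for (i in lo:(hi - 1)) for (j in (i + 1):hi)
      if (is.na(sig[i, j])) sig[i, j] <<- FALSE
  step_down <- function(lo, hi) {
    if (hi <= lo) return(invisible())
    if (!is.na(sig[lo, hi])) return(invisible())
    r <- hi - lo + 1
    qobs <- (m[hi] - m[lo]) / se
    if (qobs > qcrit[r]) {
      sig[lo, hi] <<- TRUE
      step_down(lo, hi - 1)
      step_down(lo + 1, hi)
    } else mark_ns(lo, hi)
  }
  if (k >= 2) step_down(1, k)
  pairs <- do.call(rbind, lapply(seq_len(k - 1), function(i)
    do.call(rbind, lapply((i + 1):k, function(j) data.frame(
      lower = names(m)[i], upper = names(m)[j],
      diff = unname(m[j] - m[i]), span = j - i + 1,
      q = unname((m[j] - m[i]) / se), q_crit = qcrit[j - i + 1],
      significant = sig[i, j])))))
  ## homogeneous subsets: maximal non-significant ordered runs (runs
  ## wholly contained in an earlier run are not re-emitted)
  subsets <- list()
  last_end <- 0
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !isTRUE(sig[i, j + 1])) j <- j + 1
    if (j > last_end || i > last_end) {
      subsets[[length(subsets) + 1]] <- names(m)[i:j]
      last_end <- j
    }
  }
  structure(list(ordered_means = m, se = se, alpha = alpha,
                 error_df = error_df, pairs = pairs, subsets = subsets),
            class = "posthoc_result")
}

#' @export
print.posthoc_result <- function(x, ...) {
  cat("SNK post hoc (alpha =", x$alpha, ", SE =", signif(x$se, 4), ")\n")
  print(transform(x$pairs, diff = signif(diff, 4), q = signif(q, 3),
                  q_crit = signif(q_crit, 3)), row.names = FALSE)
  cat("homogeneous subsets:",
      paste(vapply(x$subsets, paste, "", collapse = "+"), collapse = " | "),
      "\n")
  invisible(x)
}

#' Simple-effects SNK comparisons for the split-plot design
#'
#' Runs the comparisons implied by the summary-table annotations:
#' F_ap levels within each group (against the within-subject error) and
#' the two groups at each F_ap level (against the mixed error
#' `(MS_subjects + (b - 1) MS_error) / b` with Satterthwaite degrees of
#' freedom, the standard simple-effect error for a between comparison
#' at a fixed repeated-measures level).
#'
#' @param table Long cohort table (see [split_plot_anova()]).
#' @param metric_name Metric to compare.
#' @param alpha Level.
#' @return List: `anova` ([split_plot_anova()] result),
#'   `within_group` (one [snk_posthoc()] per group over F_ap levels),
#'   `between_group` (per F_ap level: difference, q, critical value,
#'   significance).
#' @export
simple_effects_snk <- function(table, metric_name, alpha = 0.05) {
  an <- split_plot_anova(table, metric_name)
  d <- table[table$metric == metric_name, , drop = FALSE]
  n <- an$n_per_group; b <- an$b
  within <- lapply(split(d, d$group), function(dd) {
    m <- tapply(dd$value, dd$fap_level, mean)
    snk_posthoc(m, an$ms_error, an$df_error, n, alpha)
  })
  ## mixed error for group comparisons at a fixed level
  ms_mix <- (an$ms_subjects + (b - 1) * an$ms_error) / b
  df_mix <- (an$ms_subjects + (b - 1) * an$ms_error)^2 /
    (an$ms_subjects^2 / an$df_subjects +
       ((b - 1) * an$ms_error)^2 / an$df_error)
  qc <- qtukey_range(1 - alpha, 2, df_mix)
  between <- do.call(rbind, lapply(levels(factor(d$fap_level)), function(l) {
    dd <- d[d$fap_level == l, ]
    m <- tapply(dd$value, dd$group, mean)
    qobs <- abs(diff(range(m))) / sqrt(ms_mix / n)
    data.frame(fap_level = l, diff = unname(m[2] - m[1]), q = qobs,
               q_crit = qc, df = df_mix, significant = qobs > qc)
  }))
  list(anova = an, within_group = within, between_group = between)
}

#' Group x level summary in the layout of the reference tables
#'
#' Per group, F_ap level and metric: mean, t-based 95% confidence
#' half-width (`qt(0.975, n - 1) * sd / sqrt(n)`) and n.
#'
#' @param table Long cohort table.
#' @param conf Confidence level (0.95).
#' @return Data frame `metric, group, fap_level, n, mean, ci_halfwidth`.
#' @export
summarize_cohort <- function(table, conf = 0.95) {
  sp <- split(table, list(table$metric, table$group, table$fap_level),
              drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    n <- nrow(d)
    if (n < 2) stop("summary cell with fewer than 2 specimens: ",
                    d$metric[1], " / ", d$group[1], " / ", d$fap_level[1])
    data.frame(metric = d$metric[1], group = d$group[1],
               fap_level = d$fap_level[1], n = n, mean = mean(d$value),
               ci_halfwidth = stats::qt(1 - (1 - conf) / 2, n - 1) *
                 stats::sd(d$value) / sqrt(n))
  }))
  rownames(out) <- NULL
  out[order(out$metric, out$group, out$fap_level), ]
}
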