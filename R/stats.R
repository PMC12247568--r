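#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired samples. Zero differences are
#' dropped; the exact null distribution is used for `n <= 25` remaining
#' pairs (when untied), and the normal approximation with continuity
#' correction otherwise. All-zero differences return `p = 1` with a
#' degenerate flag.
#'
#' @param x,y equal-length paired numeric vectors.
#' @return A one-row tibble: `statistic` (V, sum of positive ranks), `n`
#'   (pairs after zero removal), `p`, `method`, `degenerate`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(tibble::tibble(statistic = NA_real_, n = 0L, p = 1,
                          method = "degenerate", degenerate = TRUE))
  }
  ties <- any(duplicated(abs(d)))
  exact <- n <= 25 && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(d, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  tibble::tibble(statistic = unname(ht$statistic), n = n,
                 p = min(ht$p.value, 1),
                 method = if (exact) "exact" else "normal-cc",
                 degenerate = FALSE)
}

#' Paired t-test
#'
#' Classic paired t with `df = n - 1`. Zero-variance differences are
#' flagged degenerate rather than reported as infinite t.
#'
#' @param x,y equal-length paired numeric vectors (n >= 2).
#' @return One-row tibble: `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) < 1e-10 * max(1, abs(mean(d)))) {
    return(tibble::tibble(t = NA_real_, df = length(d) - 1L, p = NA_real_,
                          mean_diff = mean(d), degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, mean_diff = unname(ht$estimate),
                 degenerate = FALSE)
}

#' Intraclass correlation (two-way consistency, single measure)
#'
#' Across-day reliability of a subjects x days matrix: the ICC(3,1)
#' consistency form `(MSR - MSE) / (MSR + (d - 1) MSE)` from the two-way
#' ANOVA decomposition (subjects and days as factors), with
#' `F = MSR / MSE`, `df1 = n - 1`, `df2 = (n - 1)(d - 1)`. Consistency
#' (not absolute agreement): adding a constant to any day leaves it
#' unchanged. Rows with missing cells are dropped with a warning.
#'
#' @param m numeric matrix, subjects x days.
#' @return One-row tibble: `icc`, `f_value`, `df1`, `df2`, `p`,
#'   `n_subjects`, `n_days`.
#' @export
icc_consistency <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) {
    warning("missing cells: reducing to complete cases")
    m <- m[stats::complete.cases(m), , drop = FALSE]
  }
  n <- nrow(m); d <- ncol(m)
  if (n < 2 || d < 2) stop_ps("need >= 2 subjects and >= 2 days",
                              "ps_insufficient_data")
  df <- data.frame(y = as.vector(m),
                   subject = factor(rep(seq_len(n), times = d)),
                   day = factor(rep(seq_len(d), each = n)))
  a <- suppressWarnings(stats::anova(stats::lm(y ~ subject + day, data = df)))
  msr <- a["subject", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  icc <- (msr - mse) / (msr + (d - 1) * mse)
  f <- msr / mse
  df1 <- n - 1L; df2 <- (n - 1L) * (d - 1L)
  tibble::tibble(icc = icc, f_value = f, df1 = df1, df2 = df2,
                 p = stats::pf(f, df1, df2, lower.tail = FALSE),
                 n_subjects = n, n_days = d)
}

#' Bonferroni correction over a comparison family
#'
#' Rejects at level `alpha` iff `p <= alpha / m`; adjusted p is
#' `min(1, m p)`.
#'
#' @param pvals numeric vector of raw p-values in `[0, 1]`.
#' @param alpha family-wise level (default 0.05).
#' @return Tibble with `p`, `p_adjusted`, `significant`, and the family
#'   size `m` as an attribute-free column.
#' @export
bonferroni <- function(pvals, alpha = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  m <- length(pvals)
  adj <- stats::p.adjust(pvals, method = "bonferroni")
  tibble::tibble(p = pvals, p_adjusted = adj, m = m,
                 significant = pvals <= alpha / m)
}

#' Pairwise state-coverage comparison table
#'
#' Builds the standard reporting table for per-state coverages: every
#' pair of states within each task compared by the chosen paired test, the
#' same state compared across tasks, and a Bonferroni correction over the
#' whole family of rows.
#'
#' @param cov tibble with columns `subject`, `session`, `task`, `state`,
#'   `coverage` (one row per subject-session-task-state).
#' @param test `"wilcoxon"` (connectivity states) or `"t"` (microstates).
#' @param alpha family-wise level.
#' @return Tidy tibble mirroring the usual table layout: `cs_1`, `task_1`,
#'   `mean_1`, `sd_1`, `cs_2`, `task_2`, `mean_2`, `sd_2`, `statistic`,
#'   `p`, `p_adjusted`, `significant`.
#' @export
compare_coverages <- function(cov, test = c("wilcoxon", "t"), alpha = 0.05) {
  test <- match.arg(test)
  states <- sort(unique(cov$state))
  tasks <- sort(unique(cov$task))
  unit_key <- function(d) paste(d$subject, d$session)
  rows <- list()
  get_vec <- function(task, state) {
    d <- cov[cov$task == task & cov$state == state, ]
    d <- d[order(d$subject, d$session), ]
    list(v = d$coverage, key = unit_key(d))
  }
  add_row <- function(t1, s1, t2, s2) {
    a <- get_vec(t1, s1); b <- get_vec(t2, s2)
    shared <- intersect(a$key, b$key)
    va <- a$v[match(shared, a$key)]
    vb <- b$v[match(shared, b$key)]
    res <- if (test == "wilcoxon") wilcoxon_signed_rank(va, vb)
           else paired_t(va, vb)
    tibble::tibble(
      cs_1 = s1, task_1 = t1, mean_1 = mean(va), sd_1 = stats::sd(va),
      cs_2 = s2, task_2 = t2, mean_2 = mean(vb), sd_2 = stats::sd(vb),
      statistic = res[[1]][1], p = res$p[1])
  }
  for (tk in tasks) {
    cmb <- utils::combn(states, 2)
    for (ci in seq_len(ncol(cmb))) {
      rows[[length(rows) + 1L]] <- add_row(tk, cmb[1, ci], tk, cmb[2, ci])
    }
  }
  if (length(tasks) == 2) {
    for (st in states) {
      rows[[length(rows) + 1L]] <- add_row(tasks[1], st, tasks[2], st)
    }
  }
  out <- dplyr::bind_rows(rows)
  bf <- bonferroni(out$p, alpha = alpha)
  out$p_adjusted <- bf$p_adjusted
  out$significant <- bf$significant
  out
}

#' Across-day reliability table
#'
#' One ICC per state and task from the subjects x days coverage matrix.
#'
#' @param cov as in [compare_coverages()].
#' @return Tibble with `task`, `state`, and the [icc_consistency()]
#'   columns.
#' @export
reliability_icc <- function(cov) {
  combos <- unique(cov[, c("task", "state")])
  purrr::pmap_dfr(combos, function(task, state) {
    d <- cov[cov$task == task & cov$state == state, ]
    m <- tidyr::pivot_wider(d[, c("subject", "session", "coverage")],
                            names_from = "session",
                            values_from = "coverage")
    mm <- as.matrix(m[, -1, drop = FALSE])
    dplyr::bind_cols(tibble::tibble(task = task, state = state),
                     icc_consistency(mm))
  })
}
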