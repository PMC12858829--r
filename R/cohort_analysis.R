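#' Group summaries: mean and interquartile range
#'
#' Per-group mean, first and third quartiles (linear-interpolation
#' quantiles, R type 7) and n for one value column of a cohort table.
#'
#' @param table data.frame of per-subject records.
#' @param value column to summarize (e.g. `"C_mi"` or `"dice"`).
#' @param group_by grouping column (e.g. `"cohort"`).
#' @return data.frame with columns group, n, mean, q1, q3, ordered by
#'   group label.
#' @export
summarize_groups <- function(table, value, group_by = "cohort") {
  if (!group_by %in% names(table))
    stop("unknown grouping column: ", group_by)
  if (!value %in% names(table))
    stop("unknown value column: ", value)
  groups <- sort(unique(as.character(table[[group_by]])))
  out <- lapply(groups, function(g) {
    x <- table[[value]][table[[group_by]] == g]
    q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    data.frame(group = g, n = length(x), mean = mean(x),
               q1 = q[1], q3 = q[2], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Welch two-sample t-test
#'
#' Unequal-variance (Welch) independent-samples t-test with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#'
#' @param values_a,values_b numeric vectors, each of length >= 2 with
#'   finite variance.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs n >= 2")
  if (!all(is.finite(values_a)) || !all(is.finite(values_b)))
    stop("non-finite values")
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0 &&
      mean(values_a) == mean(values_b))
    return(list(t = 0, df = length(values_a) + length(values_b) - 2, p = 1))
  ht <- stats::t.test(values_a, values_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values (monotone, capped at 1) and rejection
#' flags at level q.
#'
#' @param pvalues numeric vector in [0, 1].
#' @param q FDR level.
#' @return list with `p_adj` and logical `reject`.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  p_adj <- stats::p.adjust(pvalues, method = "BH")
  list(p_adj = p_adj, reject = p_adj <= q)
}

#' Flag values outside the reference IQR fences
#'
#' A new value is flagged when it falls outside
#' [Q1 - f*IQR, Q3 + f*IQR] of the reference distribution. The default
#' f = 1.5 is the Tukey fence; f = 0 flags everything outside the
#' interquartile range itself (which marks roughly half of
#' in-distribution subjects, so it is a deliberately aggressive
#' screen).
#'
#' @param reference_values numeric, n >= 4.
#' @param new_values numeric values to screen.
#' @param fence_multiplier f >= 0.
#' @return logical vector, one flag per new value.
#' @export
iqr_flags <- function(reference_values, new_values, fence_multiplier = 1.5) {
  if (length(reference_values) < 4L)
    stop("reference needs n >= 4")
  if (fence_multiplier < 0) stop("fence_multiplier must be >= 0")
  q <- stats::quantile(reference_values, c(0.25, 0.75), type = 7,
                       names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - fence_multiplier * iqr
  hi <- q[2] + fence_multiplier * iqr
  new_values < lo | new_values > hi
}

histogram_probs <- function(x, breaks, eps) {
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE),
                     nbins = length(breaks) - 1L)
  p <- counts + eps
  p / sum(p)
}

#' KL divergence between new and reference uncertainty distributions
#'
#' D_KL(new || reference) over a shared equal-width histogram spanning
#' the pooled range, with additive smoothing eps on both distributions
#' before normalization. Reported in nats. The symmetric
#' Jensen-Shannon variant is available via `symmetric = TRUE`.
#'
#' @param reference_values,new_values numeric samples, each n >= 10.
#' @param bins number of histogram bins.
#' @param eps additive smoothing count per bin.
#' @param symmetric return Jensen-Shannon divergence instead.
#' @return scalar >= 0 (nats).
#' @export
kl_divergence <- function(reference_values, new_values, bins = 32,
                          eps = 1e-6, symmetric = FALSE) {
  if (length(reference_values) < 10L || length(new_values) < 10L)
    stop("each sample needs n >= 10")
  pooled <- c(reference_values, new_values)
  rng <- range(pooled)
  if (rng[1] == rng[2])
    stop("degenerate input: all pooled values identical")
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  pr <- histogram_probs(reference_values, breaks, eps)
  pn <- histogram_probs(new_values, breaks, eps)
  kl <- function(a, b) sum(a * log(a / b))
  if (symmetric) {
    m <- (pr + pn) / 2
    0.5 * kl(pn, m) + 0.5 * kl(pr, m)
  } else {
    kl(pn, pr)
  }
}

parse_contrast <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    parts <- strsplit(x, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("contrast must be 'groupA:groupB'")
    parts
  } else if (length(x) == 2L) as.character(x)
  else stop("contrast must name exactly two groups")
}

#' Compare uncertainty across cohorts
#'
#' Welch t-tests for each requested pairwise contrast of groups,
#' jointly FDR-corrected (Benjamini-Hochberg), with group means and
#' IQRs attached.
#'
#' @param table per-subject cohort table.
#' @param metric value column to compare (e.g. `"C_mi"`).
#' @param contrasts list of contrasts, each `"groupA:groupB"` or a
#'   2-vector of group labels.
#' @param group_by grouping column, default `"cohort"`.
#' @param q FDR level.
#' @return data.frame: contrast, metric, n_a, n_b, mean_a, mean_b,
#'   iqr_a, iqr_b, t, df, p, p_adj, reject.
#' @export
compare_cohorts <- function(table, metric, contrasts,
                            group_by = "cohort", q = 0.05) {
  if (!metric %in% names(table)) stop("unknown metric column: ", metric)
  if (!group_by %in% names(table)) stop("unknown grouping column: ", group_by)
  contrasts <- lapply(contrasts, parse_contrast)
  groups <- unique(as.character(table[[group_by]]))
  rows <- lapply(contrasts, function(ct) {
    if (!all(ct %in% groups))
      stop("contrast group(s) missing from table: ",
           paste(setdiff(ct, groups), collapse = ", "))
    xa <- table[[metric]][table[[group_by]] == ct[1]]
    xb <- table[[metric]][table[[group_by]] == ct[2]]
    wt <- welch_t(xa, xb)
    qa <- stats::quantile(xa, c(0.25, 0.75), type = 7, names = FALSE)
    qb <- stats::quantile(xb, c(0.25, 0.75), type = 7, names = FALSE)
    data.frame(contrast = paste(ct, collapse = ":"), metric = metric,
               n_a = length(xa), n_b = length(xb),
               mean_a = mean(xa), mean_b = mean(xb),
               iqr_a = qa[2] - qa[1], iqr_b = qb[2] - qb[1],
               t = wt$t, df = wt$df, p = wt$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  fdr <- bh_fdr(out$p, q)
  out$p_adj <- fdr$p_adj
  out$reject <- fdr$reject
  out
}
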