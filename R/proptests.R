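#' Small-occurrence guard for the two-proportion z-test
#'
#' The normal approximation behind the two-proportion z-score requires
#' the expected cell counts \code{n1*p1k}, \code{n1*(1-p1k)},
#' \code{n2*p2k} and \code{n2*(1-p2k)} to be large enough. When any of
#' the four falls below 5 the z-score is not applicable and Fisher's
#' exact test is used instead.
#'
#' @param x1,x2 Occurrence counts of the item in set 1 and set 2.
#' @param n1,n2 Set totals (clonotypes for diversity, sequences for
#'   expression); must be positive.
#' @return Logical (vectorized): \code{TRUE} when the exact test must be
#'   used.
#' @export
small_count_guard <- function(x1, n1, x2, n2) {
  stopifnot(all(n1 > 0), all(n2 > 0))
  # n*p = x and n*(1-p) = n-x, so the rule reduces to cell counts
  x1 < 5 | (n1 - x1) < 5 | x2 < 5 | (n2 - x2) < 5
}

#' Two-proportion z-test for a difference in gene proportions
#'
#' Tests H0: p1 = p2 for one gene's proportion in two independent
#' clonotype sets. The statistic uses the pooled standard error
#' (score form), \deqn{z = (p1 - p2) / \sqrt{\hat p (1-\hat p)(1/n_1 + 1/n_2)}}
#' with \eqn{\hat p = (x_1+x_2)/(n_1+n_2)}; the two-sided p-value is the
#' normal tail probability. The confidence interval for the difference
#' uses the unpooled (Wald) standard error
#' \eqn{\sqrt{p_1(1-p_1)/n_1 + p_2(1-p_2)/n_2}}.
#'
#' @inheritParams small_count_guard
#' @param alpha Type I error rate for the \code{1-alpha} CI (default 0.05).
#' @param check_guard Error when \code{\link{small_count_guard}} fires
#'   (default \code{TRUE}); the caller should use
#'   \code{\link{fisher_exact_two_sided}} for such counts.
#' @return Data frame (vectorized over counts) with columns \code{z},
#'   \code{rawp}, \code{diff}, \code{ci_low}, \code{ci_high}.
#' @export
ztest_two_proportions <- function(x1, n1, x2, n2, alpha = 0.05, check_guard = TRUE) {
  if (check_guard && any(small_count_guard(x1, n1, x2, n2)))
    stop("small-occurrence guard fired: use fisher_exact_two_sided() for these counts")
  p1 <- x1 / n1
  p2 <- x2 / n2
  pooled <- (x1 + x2) / (n1 + n2)
  se0 <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se0
  rawp <- 2 * stats::pnorm(-abs(z))
  se1 <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  crit <- stats::qnorm(1 - alpha / 2)
  data.frame(
    z = z, rawp = rawp, diff = p1 - p2,
    ci_low = (p1 - p2) - crit * se1,
    ci_high = (p1 - p2) + crit * se1
  )
}

#' Two-sided Fisher exact test on a 2x2 occurrence table
#'
#' Exact two-sided p-value for the table
#' \code{[[x1, n1-x1], [x2, n2-x2]]} under fixed margins, using the
#' probability-mass rule: the sum of hypergeometric probabilities of all
#' tables at most as probable as the observed one. Degenerate tables
#' (an all-zero margin) return 1.
#'
#' @inheritParams small_count_guard
#' @return Numeric vector of two-sided p-values.
#' @export
fisher_exact_two_sided <- function(x1, n1, x2, n2) {
  mapply(function(a, m, b, n) {
    if ((a + b) == 0 || (a + b) == (m + n)) return(1)
    # fisher.test can return 1 + eps through floating-point accumulation
    min(1, stats::fisher.test(matrix(c(a, m - a, b, n - b), nrow = 2,
                                     byrow = TRUE))$p.value)
  }, x1, n1, x2, n2)
}

.procedures <- c("bonferroni", "holm", "hochberg", "sidakSS", "sidakSD", "BH", "BY")

#' Multiple-testing adjustment of raw p-values
#'
#' Adjusted p-values for one family of m hypotheses under the familywise
#' procedures Bonferroni, Holm (step-down), Hochberg (step-up), Sidak
#' single-step (\code{sidakSS}) and Sidak step-down (\code{sidakSD}), and
#' the false-discovery-rate procedures Benjamini-Hochberg (\code{BH}) and
#' Benjamini-Yekutieli (\code{BY}). With p(1) <= ... <= p(m) the sorted
#' raw values:
#' \itemize{
#'   \item bonferroni: \code{min(1, m p_i)}
#'   \item sidakSS: \code{1 - (1 - p_i)^m}
#'   \item holm: \code{max_{j<=i} min(1, (m-j+1) p(j))}
#'   \item sidakSD: \code{max_{j<=i} 1 - (1 - p(j))^(m-j+1)}
#'   \item hochberg: \code{min_{j>=i} min(1, (m-j+1) p(j))}
#'   \item BH: \code{min_{j>=i} min(1, (m/j) p(j))}
#'   \item BY: \code{min_{j>=i} min(1, (m c_m / j) p(j))}, \code{c_m = sum_{k=1}^m 1/k}
#' }
#' Results are returned in the original order.
#'
#' @param rawp Numeric vector of raw p-values in [0, 1].
#' @param procedure One of \code{"bonferroni"}, \code{"holm"},
#'   \code{"hochberg"}, \code{"sidakSS"}, \code{"sidakSD"}, \code{"BH"},
#'   \code{"BY"}.
#' @return Numeric vector of adjusted p-values, same length and order.
#' @export
adjust_pvalues <- function(rawp, procedure = .procedures) {
  procedure <- match.arg(procedure)
  m <- length(rawp)
  if (m == 0L) return(numeric(0))
  stopifnot(all(rawp >= 0 & rawp <= 1))
  if (procedure == "bonferroni") return(pmin(1, m * rawp))
  if (procedure == "sidakSS") return(1 - (1 - rawp)^m)
  o <- order(rawp)
  ps <- rawp[o]
  i <- seq_len(m)
  adj_sorted <- switch(
    procedure,
    holm = cummax(pmin(1, (m - i + 1) * ps)),
    sidakSD = cummax(1 - (1 - ps)^(m - i + 1)),
    hochberg = rev(cummin(rev(pmin(1, (m - i + 1) * ps)))),
    BH = rev(cummin(rev(pmin(1, (m / i) * ps)))),
    BY = rev(cummin(rev(pmin(1, (m * sum(1 / i) / i) * ps))))
  )
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

#' All seven adjustments at once
#'
#' @inheritParams adjust_pvalues
#' @return Data frame with one column per procedure
#'   (\code{adj_bonferroni}, ..., \code{adj_BY}), rows in input order.
#' @export
adjust_pvalues_all <- function(rawp) {
  out <- lapply(.procedures, function(pr) adjust_pvalues(rawp, pr))
  names(out) <- paste0("adj_", .procedures)
  as.data.frame(out)
}

#' Run the per-item comparison over one testing family
#'
#' For every single item of a \code{\link{count_by_gene}} family table,
#' computes the difference in proportions between the two sets, a
#' two-proportion z-test (or Fisher's exact test when the
#' \code{\link{small_count_guard}} fires), the Wald confidence interval
#' of the difference, and all seven adjusted p-values over the family of
#' all items in the table (V, D and J jointly). The
#' \code{interpretation} column lists \code{"rawp"} plus every procedure
#' whose adjusted p-value is below \code{alpha}; \code{"NS"} marks items
#' significant under nothing.
#'
#' @param table A \code{gene_count_table} (typically from
#'   \code{\link{count_family}}).
#' @param alpha Type I error rate (default 0.05).
#' @return Data frame of class \code{prop_test_results}; one row per item
#'   with columns \code{item}, \code{gene_type}, \code{level},
#'   \code{mode}, \code{x1}, \code{n1}, \code{x2}, \code{n2}, \code{p1},
#'   \code{p2}, \code{diff}, \code{ci_low}, \code{ci_high}, \code{z},
#'   \code{method}, \code{rawp}, the seven \code{adj_*} columns and
#'   \code{interpretation}. Items tested by Fisher's exact test are also
#'   listed in the \code{"small_occurrence"} attribute.
#' @export
run_comparison <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "gene_count_table"), nrow(table) > 0L)
  tot <- attr(table, "totals")
  n1 <- tot[["n1"]]; n2 <- tot[["n2"]]
  x1 <- table$x1; x2 <- table$x2
  use_fisher <- small_count_guard(x1, n1, x2, n2)

  zt <- ztest_two_proportions(x1, n1, x2, n2, alpha = alpha, check_guard = FALSE)
  rawp <- zt$rawp
  z <- zt$z
  if (any(use_fisher)) {
    rawp[use_fisher] <- fisher_exact_two_sided(x1[use_fisher], n1, x2[use_fisher], n2)
    z[use_fisher] <- NA_real_
  }
  adj <- adjust_pvalues_all(rawp)

  sig <- adj < alpha
  interpretation <- vapply(seq_len(nrow(table)), function(i) {
    procs <- .procedures[sig[i, ]]
    if (rawp[i] < alpha) procs <- c("rawp", procs)
    if (length(procs) == 0L) "NS" else paste(procs, collapse = ";")
  }, "")

  res <- data.frame(
    item = table$item,
    gene_type = table$gene_type,
    level = attr(table, "level"),
    mode = attr(table, "mode"),
    x1 = x1, n1 = n1, x2 = x2, n2 = n2,
    p1 = x1 / n1, p2 = x2 / n2,
    diff = zt$diff, ci_low = zt$ci_low, ci_high = zt$ci_high,
    z = z,
    method = ifelse(use_fisher, "fisher", "z"),
    rawp = rawp,
    stringsAsFactors = FALSE
  )
  res <- cbind(res, adj)
  res$interpretation <- interpretation
  structure(res,
            alpha = alpha,
            small_occurrence = res$item[use_fisher],
            class = c("prop_test_results", "data.frame"))
}

#' Allele-level follow-up of significant genes
#'
#' Runs the allele-level comparison for (by default) only the alleles of
#' genes whose difference in proportions was validated by all seven
#' multiple-testing procedures at \code{alpha}; the allele family size m
#' is the number of such alleles across all gene types. This shows
#' whether a significant gene-level difference is carried by one allele
#' or shared. Set \code{all_alleles = TRUE} to test every observed allele
#' instead.
#'
#' @param gene_rows \code{prop_test_results} from the gene-level run.
#' @param set1,set2 The compared \code{repertoire_set}s.
#' @param mode \code{"diversity"} or \code{"expression"}.
#' @param alpha Type I error rate.
#' @param all_alleles Test all observed alleles rather than restricting
#'   to all-procedure-validated genes.
#' @return \code{prop_test_results} for alleles; zero rows (with a
#'   message) when no gene qualifies.
#' @export
allele_followup <- function(gene_rows, set1, set2, mode = "diversity",
                            alpha = 0.05, all_alleles = FALSE) {
  stopifnot(inherits(gene_rows, "prop_test_results"))
  adj_cols <- paste0("adj_", .procedures)
  all_sig <- rowSums(as.matrix(gene_rows[, adj_cols]) < alpha) == length(.procedures)
  sig_genes <- gene_rows$item[all_sig]
  tab <- count_family(set1, set2, level = "allele", mode = mode)
  if (!all_alleles) {
    if (length(sig_genes) == 0L) {
      message("no gene validated by all procedures; no allele follow-up")
      empty <- tab[0, , drop = FALSE]
      return(run_comparison_empty(empty, alpha))
    }
    allele_gene <- sub("\\*[^*]*$", "", tab$item)
    keep <- allele_gene %in% sig_genes
    sev <- attr(tab, "several")
    tab <- structure(tab[keep, , drop = FALSE],
                     totals = attr(tab, "totals"), several = sev,
                     level = "allele", mode = mode,
                     class = c("gene_count_table", "data.frame"))
  }
  run_comparison(tab, alpha = alpha)
}

run_comparison_empty <- function(empty_tab, alpha) {
  res <- data.frame(
    item = character(), gene_type = character(), level = character(),
    mode = character(), x1 = integer(), n1 = integer(), x2 = integer(),
    n2 = integer(), p1 = numeric(), p2 = numeric(), diff = numeric(),
    ci_low = numeric(), ci_high = numeric(), z = numeric(),
    method = character(), rawp = numeric(), stringsAsFactors = FALSE
  )
  for (pr in .procedures) res[[paste0("adj_", pr)]] <- numeric()
  res$interpretation <- character()
  structure(res, alpha = alpha, small_occurrence = character(),
            class = c("prop_test_results", "data.frame"))
}

#' Rejection-count curves over an alpha grid
#'
#' For each procedure (plus the unadjusted \code{"rawp"} curve), counts
#' how many null hypotheses are rejected (adjusted p < alpha) at each
#' alpha of a grid. Counts are non-decreasing in alpha.
#'
#' @param rows \code{prop_test_results}.
#' @param procedures Procedures to include; default the raw curve plus
#'   all seven.
#' @param alpha_grid Increasing grid of alpha levels in (0, 1]; default
#'   0.001 to 0.25 by 0.001.
#' @return Data frame with columns \code{procedure}, \code{alpha},
#'   \code{n_rejected}.
#' @export
rejection_curves <- function(rows, procedures = c("rawp", .procedures),
                             alpha_grid = seq(0.001, 0.25, by = 0.001)) {
  stopifnot(inherits(rows, "prop_test_results"))
  out <- lapply(procedures, function(pr) {
    p <- if (pr == "rawp") rows$rawp else rows[[paste0("adj_", pr)]]
    data.frame(procedure = pr, alpha = alpha_grid,
               n_rejected = vapply(alpha_grid, function(a) sum(p < a), 0L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Scatter-table of z-scores against -log10 p-values
#'
#' The tabular form of the volcano-style scatter plot: for each item, the
#' z-score (absent for Fisher-tested items), the sign of the difference
#' in proportions, and the negative decimal logarithm of the raw and
#' adjusted p-values. Zero p-values are capped at the smallest positive
#' double so the logarithm stays finite.
#'
#' @param rows \code{prop_test_results}.
#' @return Data frame with columns \code{item}, \code{gene_type},
#'   \code{z}, \code{method}, \code{sign} (\code{+1}/\code{-1}/\code{0}
#'   for the sign of \code{diff}), \code{neg_log10_rawp}, one
#'   \code{neg_log10_adj_*} column per procedure, and
#'   \code{significant} (raw p below the family alpha).
#' @export
scatter_table <- function(rows) {
  stopifnot(inherits(rows, "prop_test_results"))
  alpha <- attr(rows, "alpha")
  nl <- function(p) -log10(pmax(p, .Machine$double.xmin))
  out <- data.frame(
    item = rows$item,
    gene_type = rows$gene_type,
    z = rows$z,
    method = rows$method,
    sign = sign(rows$diff),
    neg_log10_rawp = nl(rows$rawp),
    stringsAsFactors = FALSE
  )
  for (pr in .procedures)
    out[[paste0("neg_log10_adj_", pr)]] <- nl(rows[[paste0("adj_", pr)]])
  out$significant <- rows$rawp < alpha
  out
}
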