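test_that("small-occurrence guard fires when any expected cell is below 5", {
  expect_true(small_count_guard(3, 1000, 10, 1000))    # n1*p1 = 3
  expect_false(small_count_guard(500, 1000, 400, 1000))
  expect_true(small_count_guard(0, 1000, 0, 1000))     # zero occurrence
  expect_true(small_count_guard(998, 1000, 500, 1000)) # n1*(1-p1) = 2
  expect_equal(small_count_guard(c(3, 500), 1000, c(10, 400), 1000),
               c(TRUE, FALSE))
})

test_that("equal proportions give z = 0, rawp = 1 and a symmetric CI", {
  r <- ztest_two_proportions(100, 1000, 100, 1000)
  expect_equal(r$z, 0)
  expect_equal(r$rawp, 1)
  expect_equal(r$diff, 0)
  expect_equal(r$ci_low, -r$ci_high)
})

test_that("z statistic and p-value match an independent large-sample routine", {
  cases <- list(c(100, 1000, 50, 1000), c(250, 2000, 300, 2500),
                c(40, 300, 70, 400))
  for (cs in cases) {
    r <- ztest_two_proportions(cs[1], cs[2], cs[3], cs[4])
    # prop.test without continuity correction: X-squared == z^2
    pt <- prop.test(c(cs[1], cs[3]), c(cs[2], cs[4]), correct = FALSE)
    expect_equal(r$z^2, unname(pt$statistic), tolerance = 1e-12)
    expect_equal(r$rawp, pt$p.value, tolerance = 1e-12)
    expect_lt(r$ci_low, r$diff); expect_gt(r$ci_high, r$diff)
  }
})

test_that("|z| > 1.96 coincides with rawp < 0.05", {
  set.seed(202)
  for (i in 1:50) {
    n1 <- sample(500:2000, 1); n2 <- sample(500:2000, 1)
    x1 <- rbinom(1, n1, 0.1); x2 <- rbinom(1, n2, runif(1, 0.05, 0.2))
    if (small_count_guard(x1, n1, x2, n2)) next
    r <- ztest_two_proportions(x1, n1, x2, n2)
    expect_equal(abs(r$z) > qnorm(0.975), r$rawp < 0.05)
  }
})

test_that("the guard contract stops the z-test on small counts", {
  expect_error(ztest_two_proportions(2, 100, 50, 100), "fisher")
})

test_that("Fisher two-sided p-values follow the probability-mass rule", {
  expect_equal(fisher_exact_two_sided(0, 10, 0, 10), 1)   # degenerate
  expect_equal(fisher_exact_two_sided(5, 10, 5, 10), 1)   # observed is the mode
  # exhaustive enumeration oracle on the example table [[1,9],[9,1]]
  expect_equal(fisher_exact_two_sided(1, 10, 9, 10),
               oracle_fisher_enum(1, 10, 9, 10), tolerance = 1e-10)
})

test_that("adjusted p-values match hand computations and references", {
  # m = 1: adjusted equals raw for every procedure
  for (pr in c("bonferroni", "holm", "hochberg", "sidakSS", "sidakSD", "BH", "BY"))
    expect_equal(adjust_pvalues(0.0321, pr), 0.0321, info = pr)
  # closed-form hand computation
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "BH"), c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "bonferroni"), c(0.03, 0.06, 0.09))
  expect_equal(adjust_pvalues(numeric(0), "BH"), numeric(0))
  # reference implementation on random vectors, unsorted input order
  set.seed(31)
  for (i in 1:20) {
    p <- runif(sample(2:40, 1))^2
    expect_equal(adjust_pvalues(p, "bonferroni"), p.adjust(p, "bonferroni"))
    expect_equal(adjust_pvalues(p, "holm"), p.adjust(p, "holm"))
    expect_equal(adjust_pvalues(p, "hochberg"), p.adjust(p, "hochberg"))
    expect_equal(adjust_pvalues(p, "BH"), p.adjust(p, "BH"))
    expect_equal(adjust_pvalues(p, "BY"), p.adjust(p, "BY"))
    expect_equal(adjust_pvalues(p, "sidakSS"), oracle_sidak_ss(p))
    expect_equal(adjust_pvalues(p, "sidakSD"), oracle_sidak_sd(p))
  }
})

test_that("procedure dominance holds elementwise on random inputs", {
  set.seed(77)
  for (i in 1:25) {
    p <- runif(sample(3:60, 1))
    adj <- adjust_pvalues_all(p)
    expect_true(all(adj$adj_bonferroni >= adj$adj_sidakSS - 1e-12))
    expect_true(all(adj$adj_sidakSS >= p - 1e-12))
    expect_true(all(adj$adj_bonferroni >= adj$adj_holm - 1e-12))
    expect_true(all(adj$adj_holm >= adj$adj_BH - 1e-12))
    expect_true(all(adj$adj_BY >= adj$adj_BH - 1e-12))
    expect_true(all(as.matrix(adj) >= p - 1e-12) && all(as.matrix(adj) <= 1))
  }
})

test_that("run_comparison fills one row per item with family-wide adjustment", {
  pair <- tiny_pair(seed = 21, n1 = 2000, n2 = 2000)
  s1 <- filter_cdr3_range(pair$set1, label = "s1")
  s2 <- filter_cdr3_range(pair$set2, label = "s2")
  tab <- count_family(s1, s2)
  rows <- run_comparison(tab)
  expect_equal(nrow(rows), nrow(tab))
  expect_true(all(rows$method %in% c("z", "fisher")))
  expect_true(all(is.na(rows$z[rows$method == "fisher"])))
  expect_true(all(rows$rawp >= 0 & rows$rawp <= 1))
  adj <- as.matrix(rows[, paste0("adj_", c("bonferroni", "holm", "hochberg",
                                           "sidakSS", "sidakSD", "BH", "BY"))])
  expect_true(all(adj >= rows$rawp - 1e-12 & adj <= 1))
  expect_true(all(rows$ci_low <= rows$diff & rows$diff <= rows$ci_high))
  # interpretation is consistent with the adjusted columns
  i <- which(rows$interpretation != "NS")
  if (length(i)) {
    first <- i[[1]]
    procs <- strsplit(rows$interpretation[first], ";")[[1]]
    if ("BH" %in% procs) expect_lt(rows$adj_BH[first], 0.05)
  }
  # single-item family: adjusted equals raw
  tab1 <- tab[1, , drop = FALSE]
  attributes(tab1)[c("totals", "level", "mode", "several")] <-
    attributes(tab)[c("totals", "level", "mode", "several")]
  class(tab1) <- class(tab)
  r1 <- run_comparison(tab1)
  expect_equal(r1$adj_BH, r1$rawp)
})

test_that("null tables yield no significant items beyond the error rate", {
  pair <- tiny_pair(seed = 55, n1 = 3000, n2 = 3000)  # no injected effects
  s1 <- filter_cdr3_range(pair$set1, label = "s1")
  s2 <- filter_cdr3_range(pair$set2, label = "s2")
  rows <- run_comparison(count_family(s1, s2))
  expect_lt(mean(rows$rawp < 0.05), 0.2)            # far from pervasive
  expect_lt(sum(rows$adj_bonferroni < 0.05), 3)     # familywise control
})

test_that("allele follow-up is restricted to all-procedure-validated genes", {
  pair <- tiny_pair(seed = 13, n1 = 12000, n2 = 12000,
                    effects = c("IGHV4-34" = 0.05))
  s1 <- filter_cdr3_range(pair$set1, label = "s1")
  s2 <- filter_cdr3_range(pair$set2, label = "s2")
  gene_rows <- run_comparison(count_family(s1, s2))
  ar <- allele_followup(gene_rows, s1, s2)
  expect_true(nrow(ar) >= 1L)
  expect_true(all(grepl("^IGHV4-34\\*", ar$item)))
  # the family for adjustment is exactly the restricted allele set
  expect_equal(ar$adj_bonferroni, pmin(1, nrow(ar) * ar$rawp))
  # override tests every observed allele
  all_rows <- allele_followup(gene_rows, s1, s2, all_alleles = TRUE)
  expect_gt(nrow(all_rows), nrow(ar))
})

test_that("genes significant under BH only do not qualify for allele follow-up", {
  # three-gene V family engineered so two genes pass BH (adj 0.045) but
  # no familywise procedure: raw p-values 0.0200, 0.0300, ~1
  build <- function(xa, xb, n) {
    v <- c(rep("IGHV1-2*02", xa), rep("IGHV3-7*01", xb),
           rep("IGHV3-23*01", n - xa - xb))
    make_records(v = v, cdr3 = "ARDY")
  }
  s1 <- filter_cdr3_range(build(121, 93, 3000), label = "s1")
  s2 <- filter_cdr3_range(build(159, 66, 3000), label = "s2")
  rows <- run_comparison(count_by_gene(s1, s2, "V"))
  bh_only <- rows$adj_BH < 0.05 & rows$adj_bonferroni >= 0.05
  expect_equal(sum(bh_only), 2L)
  expect_message(ar <- allele_followup(rows, s1, s2), "no gene validated")
  expect_equal(nrow(ar), 0L)
})

test_that("rejection curves are monotone and saturate at alpha = 1", {
  pair <- tiny_pair(seed = 33, n1 = 1500, n2 = 1500)
  s1 <- filter_cdr3_range(pair$set1, label = "s1")
  s2 <- filter_cdr3_range(pair$set2, label = "s2")
  rows <- run_comparison(count_family(s1, s2))
  cur <- rejection_curves(rows, alpha_grid = c(seq(0.01, 0.99, 0.01), 1))
  for (pr in unique(cur$procedure)) {
    y <- cur$n_rejected[cur$procedure == pr]
    expect_true(all(diff(y) >= 0), info = pr)
  }
  # every p-value (adjusted or not) is < 1 here, so alpha = 1 rejects all
  expect_true(all(cur$n_rejected[cur$alpha == 1] == nrow(rows)) ||
                any(rows$rawp == 1 | rows$adj_BY == 1))
  # direct-counting cross-check at one alpha
  expect_equal(cur$n_rejected[cur$procedure == "BH" & cur$alpha == 0.05],
               sum(rows$adj_BH < 0.05))
})

test_that("scatter table records -log10 p, sign and the z/raw significance link", {
  pair <- tiny_pair(seed = 44, n1 = 1500, n2 = 1500,
                    effects = c("IGHV3-23" = 0.04))
  s1 <- filter_cdr3_range(pair$set1, label = "s1")
  s2 <- filter_cdr3_range(pair$set2, label = "s2")
  rows <- run_comparison(count_family(s1, s2))
  sc <- scatter_table(rows)
  expect_equal(sc$neg_log10_rawp, -log10(pmax(rows$rawp, .Machine$double.xmin)))
  expect_true(all(is.na(sc$z[sc$method == "fisher"])))
  expect_true(all(is.finite(sc$neg_log10_rawp)))
  # sign convention: significant positive difference <=> z > 1.96
  zr <- !is.na(sc$z)
  expect_equal(sc$significant[zr] & sc$sign[zr] > 0, sc$z[zr] > qnorm(0.975))
  # a raw p of 0.01 maps to exactly 2
  rows2 <- rows; rows2$rawp[1] <- 0.01
  expect_equal(scatter_table(rows2)$neg_log10_rawp[1], 2)
})
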