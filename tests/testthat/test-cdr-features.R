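test_that("the 13-position CDR3 loop carries its canonical labels", {
  expect_equal(imgt_cdr3_positions(13),
               as.character(105:117))
})

test_that("short loops lose positions at the loop top, long loops gain insertions", {
  expect_equal(imgt_cdr3_positions(12),
               as.character(c(105:110, 112:117)))          # 111 absent
  expect_equal(imgt_cdr3_positions(15),
               c("105", "106", "107", "108", "109", "110", "111",
                 "111.1", "112.1", "112", "113", "114", "115", "116", "117"))
  expect_equal(imgt_cdr3_positions(14),
               c(as.character(105:111), "112.1", as.character(112:117)))
  # right side sheds first when shrinking
  expect_equal(imgt_cdr3_positions(5), c("105", "106", "107", "116", "117"))
})

test_that("every length from 1 to 45 yields exactly L labels with stable anchors", {
  for (L in 1:45) {
    lab <- imgt_cdr3_positions(L)
    expect_length(lab, L)
    expect_equal(anyDuplicated(lab), 0L)
    if (L >= 2) expect_true(all(c("105", "117") %in% lab))
  }
  expect_error(imgt_cdr3_positions(0))
})

test_that("CDR1 and CDR2 use their own fixed spans", {
  expect_equal(cdr_positions(1, 12), as.character(27:38))
  expect_equal(cdr_positions(2, 10), as.character(56:65))
  expect_equal(cdr_positions(2, 8), as.character(c(56:59, 62:65)))
  expect_error(cdr_positions(1, 13), "span")
})

test_that("length distributions count diversity and expression correctly", {
  recs <- make_records(cdr3 = c("ARDY", "ARDY", "ARDDY"), n_seq = c(7L, 1L, 2L))
  s <- filter_cdr3_range(recs, label = "one")
  div <- length_distribution(s, cdr_type = 3, mode = "diversity")
  expect_equal(div$count[div$length == 4], 2)
  expr <- length_distribution(s, cdr_type = 3, mode = "expression")
  expect_equal(expr$count[expr$length == 4], 8)
  expect_equal(expr$count[expr$length == 5], 2)
  # one clonotype with 7 sequences lands a bin of 7
  s7 <- filter_cdr3_range(make_records(cdr3 = "ARDDDY", n_seq = 7L), label = "x")
  e7 <- length_distribution(s7, cdr_type = 3, mode = "expression")
  expect_equal(e7$count, 7)
})

test_that("normalization scales bins per 10,000 and preserves the total", {
  expect_equal(normalize_per_10000(500, 25000), 200)
  pair <- tiny_pair(seed = 15)
  s1 <- filter_cdr3_range(pair$set1, label = "s1")
  nd <- length_distribution(s1, cdr_type = 3, normalized = TRUE)
  expect_equal(sum(nd$count), 10000, tolerance = 1e-9)
})

test_that("the synthetic length distribution peaks at 15 AA", {
  pair <- tiny_pair(seed = 19, n1 = 4000)
  s1 <- filter_cdr3_range(pair$set1, label = "s1")
  d <- length_distribution(s1, cdr_type = 3)
  expect_true(d$length[which.max(d$count)] %in% 14:15)
})

test_that("CDR3 listings agree with the histogram bin at each length", {
  pair <- tiny_pair(seed = 23)
  s1 <- filter_cdr3_range(pair$set1, label = "s1")
  d <- length_distribution(s1, cdr_type = 3)
  for (L in c(10, 15, 20)) {
    lst <- list_cdr3_at_length(s1, L)
    bin <- d$count[d$length == L]
    expect_equal(nrow(lst), if (length(bin)) bin else 0)
    if (nrow(lst)) expect_true(all(nchar(lst$cdr3_aa) == L))
  }
  expect_message(out <- list_cdr3_at_length(s1, 3), "outside")
  expect_equal(nrow(out), 0L)
})

test_that("amino-acid class schemes cover the 20 residues and stay disjoint", {
  for (scheme in c("AA", "hydropathy", "volume", "chemical", "charge",
                   "hydrogen", "polarity", "physicochemical")) {
    map <- aa_classes(scheme)
    expect_setequal(names(map), strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  }
  expect_length(unique(aa_classes("hydropathy")), 3L)
  expect_length(unique(aa_classes("volume")), 5L)
  expect_length(unique(aa_classes("chemical")), 7L)
  expect_equal(unname(aa_classes("charge")[c("K", "D", "A")]),
               c("positive", "negative", "uncharged"))
})

test_that("monomorphic positions give zero entropy, unit Wu-Kabat, zero Simpson", {
  recs <- make_records(cdr3 = rep("ARDY", 5))
  s <- filter_cdr3_range(recs, label = "x")
  prof <- position_profile(s, 3, 4)
  expect_equal(prof$indices$shannon, rep(0, 4))
  expect_equal(prof$indices$wu_kabat, rep(1, 4))
  expect_equal(prof$indices$simpson, rep(0, 4))
  expect_equal(unname(colSums(prof$counts)), rep(5, 4))
})

test_that("four equally frequent classes give 2 bits and Simpson 0.75", {
  recs <- make_records(cdr3 = c("ARDY", "RRDY", "DRDY", "YRDY"))
  s <- filter_cdr3_range(recs, label = "x")
  prof <- position_profile(s, 3, 4)
  expect_equal(prof$indices$shannon[1], 2)
  expect_equal(prof$indices$simpson[1], 0.75)
  expect_equal(prof$indices$wu_kabat[1], 4 * 4 / 1)
})

test_that("closed-form index values hold on direct count vectors", {
  expect_equal(shannon_entropy(c(5, 0, 0)), 0)
  expect_equal(wu_kabat(c(5, 0, 0)), 1)
  expect_equal(simpson_index(c(5, 0, 0)), 0)
  expect_equal(shannon_entropy(rep(1, 4)), 2)
  expect_equal(simpson_index(rep(1, 4)), 0.75)
  expect_equal(wu_kabat(rep(1, 20)), 20 * 20 / 1)  # 400
  expect_error(shannon_entropy(c(0, 0)), "all-zero")
})

test_that("profile indices match independent recomputation from the counts", {
  pair <- tiny_pair(seed = 29, n1 = 1500)
  s1 <- filter_cdr3_range(pair$set1, label = "s1")
  for (scheme in c("AA", "hydropathy", "volume")) {
    prof <- position_profile(s1, 3, 15, class_scheme = scheme)
    expect_equal(dim(prof$counts)[2], 15L)
    # conservation: every position sums to the number of contributors
    expect_true(all(colSums(prof$counts) == prof$n_contributing))
    for (j in c(1, 8, 15)) {
      cnt <- prof$counts[, j]
      p <- cnt[cnt > 0] / sum(cnt)
      expect_equal(prof$indices$shannon[j], -sum(p * log2(p)))
      expect_equal(prof$indices$simpson[j], 1 - sum(p^2))
      expect_equal(prof$indices$wu_kabat[j],
                   sum(cnt > 0) * sum(cnt) / max(cnt))
      expect_lte(prof$indices$shannon[j], log2(nrow(prof$counts)))
      expect_gte(prof$indices$wu_kabat[j], 1)
      expect_true(prof$indices$simpson[j] >= 0 && prof$indices$simpson[j] < 1)
    }
  }
})

test_that("expression weighting multiplies contributions by sequence counts", {
  recs <- make_records(cdr3 = c("ARDY", "GRDY"), n_seq = c(3L, 1L))
  s <- filter_cdr3_range(recs, label = "x")
  prof <- position_profile(s, 3, 4, mode = "expression")
  expect_equal(prof$n_contributing, 4)
  expect_equal(unname(prof$counts["A", 1]), 3)
})

test_that("sequences with unknown letters are skipped with a warning", {
  recs <- make_records(cdr3 = c("ARDY", "ARDY"))
  s <- filter_cdr3_range(recs, label = "x")
  s$records$cdr3_aa[2] <- "ARBY"          # B is not a standard residue
  expect_warning(prof <- position_profile(s, 3, 4), "skipped")
  expect_equal(prof$n_contributing, 1)
})
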