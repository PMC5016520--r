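# Shared fixtures and independent oracles for the test suite.

# Quick hand-built record table (valid by construction).
make_records <- function(v = "IGHV4-34*01", d = "IGHD3-10*01", j = "IGHJ4*02",
                         cdr3 = "ARDGYSSGWYFD", n_seq = 1L, id = NULL) {
  n <- max(length(v), length(d), length(j), length(cdr3), length(n_seq))
  df <- data.frame(
    clonotype_id = if (is.null(id)) as.character(seq_len(n)) else id,
    v_call = rep_len(v, n), d_call = rep_len(d, n), j_call = rep_len(j, n),
    cdr1_aa = rep_len("GFTFSSYA", n), cdr2_aa = rep_len("ISYDGSNK", n),
    cdr3_aa = rep_len(cdr3, n),
    cdr3_length = nchar(rep_len(cdr3, n)),
    n_sequences = rep_len(as.integer(n_seq), n),
    stringsAsFactors = FALSE
  )
  df
}

# Small synthetic pair used across tests (cheap; fixed seed).
tiny_pair <- function(seed = 7L, n1 = 800L, n2 = 700L, effects = numeric(0)) {
  generate_pair(sim_config(n1 = n1, n2 = n2, effects = effects, seed = seed))
}

# ---- independent oracles -------------------------------------------------

# Exhaustive two-sided Fisher p-value by enumeration over all tables with
# the observed margins (probability-mass rule).
oracle_fisher_enum <- function(x1, n1, x2, n2) {
  k <- x1 + x2
  N <- n1 + n2
  support <- max(0, k - n2):min(k, n1)
  probs <- vapply(support, function(a)
    exp(lchoose(n1, a) + lchoose(n2, k - a) - lchoose(N, k)), 0)
  p_obs <- probs[match(x1, support)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Sidak single-step and step-down adjusted p-values, coded directly from
# their definitions (independent of adjust_pvalues()).
oracle_sidak_ss <- function(p) 1 - (1 - p)^length(p)
oracle_sidak_sd <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- cummax(1 - (1 - p[o])^(m - seq_len(m) + 1))
  out <- numeric(m); out[o] <- adj
  out
}

# Brute-force agglomerative Ward clustering: at each step recompute, for
# every candidate pair of clusters, the exact increase in total
# within-cluster sum of squares, and merge the minimizing pair
# (lowest-index tie-break). Heights reported on the ward.D2 scale
# sqrt(2 * delta-ESS).
oracle_ward <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  clusters <- as.list(seq_len(n))
  labels <- -seq_len(n)             # hclust convention: negatives = leaves
  merges <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)
  ess <- function(idx) {
    if (length(idx) == 1L) return(0)
    centered <- sweep(x[idx, , drop = FALSE], 2, colMeans(x[idx, , drop = FALSE]))
    sum(centered^2)
  }
  for (step in seq_len(n - 1L)) {
    best <- NULL
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in seq((i + 1L), length(clusters))) {
        d <- ess(c(clusters[[i]], clusters[[j]])) - ess(clusters[[i]]) - ess(clusters[[j]])
        if (is.null(best) || d < best$d - 1e-12) best <- list(i = i, j = j, d = d)
      }
    }
    merges[step, ] <- sort(c(labels[best$i], labels[best$j]))
    heights[step] <- sqrt(2 * max(0, best$d))
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    labels[best$i] <- step
    clusters[[best$j]] <- NULL
    labels <- labels[-best$j]
  }
  list(merge = merges, height = heights)
}

# Canonical form of an hclust-style merge matrix: the set partition after
# each merge step, so structurally equal trees compare equal regardless
# of row/child ordering conventions.
merge_partitions <- function(merge, n) {
  members <- function(node) {
    if (node < 0) return(-node)
    sort(c(members(merge[node, 1L]), members(merge[node, 2L])))
  }
  lapply(seq_len(nrow(merge)), function(s) members(s))
}
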