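#' Filter clonotypes by CDR3 length and build a repertoire set
#'
#' Clonotypes whose CDR3 amino-acid length falls outside
#' \code{[min_len, max_len]} (bounds inclusive; defaults 4 and 45 AA) are
#' length outliers: they are excluded from all downstream statistics but
#' kept in the object for reporting. The set carries its two totals: the
#' diversity total \code{n_clonotypes} (number of kept clonotypes, the n
#' of the per-gene proportions) and the expression total
#' \code{n_sequences_total} (sum of assigned sequence counts).
#'
#' @param records Clonotype record data frame (see
#'   \code{\link{read_stats_file}}).
#' @param min_len,max_len Inclusive CDR3 length bounds in amino acids.
#' @param label Set name used in reports (e.g. \code{"set1"}).
#' @return An object of class \code{repertoire_set}.
#' @export
filter_cdr3_range <- function(records, min_len = 4L, max_len = 45L, label = "set") {
  stopifnot(min_len >= 1L, max_len >= min_len)
  if (inherits(records, "repertoire_set")) records <- records$records
  keep <- !is.na(records$cdr3_length) &
    records$cdr3_length >= min_len & records$cdr3_length <= max_len
  kept <- records[keep, , drop = FALSE]
  out <- records[!keep, , drop = FALSE]
  rownames(kept) <- rownames(out) <- NULL
  structure(
    list(
      label = label,
      records = kept,
      outliers = out,
      cdr3_min = as.integer(min_len),
      cdr3_max = as.integer(max_len),
      n_clonotypes = nrow(kept),
      n_sequences_total = sum(kept$n_sequences)
    ),
    class = "repertoire_set"
  )
}

#' @export
print.repertoire_set <- function(x, ...) {
  cat("<repertoire_set> ", x$label, "\n", sep = "")
  cat("  CDR3 length range: ", x$cdr3_min, "-", x$cdr3_max, " AA\n", sep = "")
  cat("  clonotypes (diversity): ", x$n_clonotypes, "\n", sep = "")
  cat("  assigned sequences (expression): ", x$n_sequences_total, "\n", sep = "")
  cat("  length outliers excluded: ", nrow(x$outliers), "\n", sep = "")
  invisible(x)
}

#' One-line summary of a repertoire set
#'
#' Reports the diversity and expression totals together with the split of
#' assigned sequences into "one copy" clonotypes (exactly one sequence)
#' and "more than one".
#'
#' @param set A \code{repertoire_set}.
#' @return One-row data frame.
#' @export
set_summary <- function(set) {
  one <- set$records$n_sequences == 1L
  data.frame(
    label = set$label,
    n_clonotypes = set$n_clonotypes,
    n_sequences_total = set$n_sequences_total,
    n_one_copy = sum(set$records$n_sequences[one]),
    n_more_than_one = sum(set$records$n_sequences[!one]),
    n_outliers = nrow(set$outliers),
    stringsAsFactors = FALSE
  )
}

.set_total <- function(set, mode) {
  switch(mode, diversity = set$n_clonotypes,
         expression = set$n_sequences_total,
         stop("unknown mode: ", mode))
}

.call_column <- function(gene_type) {
  switch(gene_type, V = "v_call", D = "d_call", J = "j_call",
         stop("gene_type must be one of 'V', 'D', 'J'"))
}

# Classify each record's call at the requested level.
# Returns a data frame with columns item (single-item name or NA) and
# bucket (name under which ambiguous/unassignable calls accumulate, NA for
# single items).
.classify_calls <- function(calls, level) {
  p <- parse_gene_calls(calls)
  missing <- is.na(calls) | !nzchar(calls)
  item <- rep(NA_character_, length(calls))
  bucket <- rep(NA_character_, length(calls))
  bucket[missing] <- "(no call)"
  bad <- !missing & is.na(p$group)
  bucket[bad] <- "(unparseable)"
  ok <- !missing & !bad
  if (level == "gene") {
    single <- ok & !is.na(p$gene)           # incl. several alleles of one gene
    item[single] <- p$gene[single]
    sev <- ok & is.na(p$gene)
    bucket[sev] <- p$raw[sev]
  } else {
    single <- ok & !p$is_several & !is.na(p$allele)
    item[single] <- paste0(p$gene[single], "*", p$allele[single])
    noall <- ok & !p$is_several & is.na(p$allele)
    bucket[noall] <- paste0(p$gene[noall], " (no allele)")
    sev <- ok & p$is_several
    bucket[sev] <- p$raw[sev]
  }
  data.frame(item = item, bucket = bucket, stringsAsFactors = FALSE)
}

#' Per-gene (or per-allele) counts for two repertoire sets
#'
#' Tabulates, for each distinct single gene (or gene*allele) of one gene
#' type, its diversity count (number of kept clonotypes) or expression
#' count (number of assigned sequences) in each set. Ambiguous multi-gene
#' ("several") calls, several-allele calls at allele level, allele-less
#' calls at allele level, and records without a call for the requested
#' gene type do not contribute to any single item; they accumulate in the
#' \code{"several"} attribute so that single + several counts always add
#' up to the set totals.
#'
#' @param set1,set2 \code{repertoire_set} objects filtered with identical
#'   CDR3 bounds.
#' @param gene_type \code{"V"}, \code{"D"} or \code{"J"}.
#' @param level \code{"gene"} or \code{"allele"}.
#' @param mode \code{"diversity"} (clonotype counts) or
#'   \code{"expression"} (assigned-sequence counts).
#' @return A data frame of class \code{gene_count_table} with columns
#'   \code{item}, \code{gene_type}, \code{x1}, \code{x2} (items present in
#'   only one set appear with a zero in the other), plus attributes
#'   \code{totals} (named vector \code{n1}, \code{n2}), \code{several}
#'   (data frame \code{item}, \code{x1}, \code{x2}), \code{level} and
#'   \code{mode}.
#' @export
count_by_gene <- function(set1, set2, gene_type = c("V", "D", "J"),
                          level = c("gene", "allele"),
                          mode = c("diversity", "expression")) {
  gene_type <- match.arg(gene_type)
  level <- match.arg(level)
  mode <- match.arg(mode)
  stopifnot(inherits(set1, "repertoire_set"), inherits(set2, "repertoire_set"))
  if (set1$cdr3_min != set2$cdr3_min || set1$cdr3_max != set2$cdr3_max)
    stop("sets were filtered with different CDR3 length bounds")
  col <- .call_column(gene_type)

  tab_one <- function(set) {
    calls <- set$records[[col]]
    w <- if (mode == "diversity") rep(1L, nrow(set$records)) else set$records$n_sequences
    cls <- .classify_calls(calls, level)
    list(
      single = tapply(w[!is.na(cls$item)], cls$item[!is.na(cls$item)], sum),
      several = tapply(w[!is.na(cls$bucket)], cls$bucket[!is.na(cls$bucket)], sum)
    )
  }
  t1 <- tab_one(set1)
  t2 <- tab_one(set2)
  if (gene_type == "D" && length(t1$single) == 0L && length(t2$single) == 0L)
    warning("no single ", level, "-level D calls in either set", call. = FALSE)

  merge_counts <- function(a, b) {
    items <- as.character(sort(union(names(a), names(b))))
    data.frame(
      item = items,
      x1 = as.integer(ifelse(items %in% names(a), a[items], 0L)),
      x2 = as.integer(ifelse(items %in% names(b), b[items], 0L)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  singles <- merge_counts(t1$single, t2$single)
  singles$gene_type <- if (nrow(singles)) gene_type else character(0)
  singles <- singles[, c("item", "gene_type", "x1", "x2")]
  several <- merge_counts(t1$several, t2$several)

  structure(
    singles,
    totals = c(n1 = .set_total(set1, mode), n2 = .set_total(set2, mode)),
    several = several,
    level = level,
    mode = mode,
    class = c("gene_count_table", "data.frame")
  )
}

#' Combine per-type count tables into one testing family
#'
#' Binds V, D and J tables of one level/mode into a single table so that
#' the multiple-testing family spans the gene types jointly (e.g. 72 gene
#' hypotheses = 41 V + 25 D + 6 J in a typical IGH comparison).
#'
#' @param ... \code{gene_count_table} objects with identical totals, level
#'   and mode.
#' @return A combined \code{gene_count_table}.
#' @export
combine_count_tables <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1L]]) && !inherits(tabs[[1L]], "data.frame"))
    tabs <- tabs[[1L]]
  stopifnot(length(tabs) >= 1L)
  tot <- attr(tabs[[1L]], "totals")
  lev <- attr(tabs[[1L]], "level")
  mod <- attr(tabs[[1L]], "mode")
  for (t in tabs) {
    if (!identical(attr(t, "totals"), tot) || !identical(attr(t, "level"), lev) ||
        !identical(attr(t, "mode"), mod))
      stop("count tables to combine must share totals, level and mode")
  }
  out <- do.call(rbind, lapply(tabs, function(t) as.data.frame(t)))
  rownames(out) <- NULL
  sev <- do.call(rbind, lapply(tabs, attr, "several"))
  structure(out, totals = tot, several = sev, level = lev, mode = mod,
            class = c("gene_count_table", "data.frame"))
}

#' Count tables for all gene types of a locus comparison
#'
#' Convenience wrapper building the joint V + D + J family table used for
#' gene-level (or allele-level) testing. Gene types without any call in
#' either set are dropped with a warning.
#'
#' @inheritParams count_by_gene
#' @param gene_types Gene types to include, default \code{c("V","D","J")}.
#' @return A combined \code{gene_count_table}.
#' @export
count_family <- function(set1, set2, gene_types = c("V", "D", "J"),
                         level = "gene", mode = "diversity") {
  tabs <- list()
  for (gt in gene_types) {
    tab <- withCallingHandlers(
      count_by_gene(set1, set2, gt, level = level, mode = mode),
      warning = function(w) invokeRestart("muffleWarning")
    )
    if (nrow(tab) > 0L) tabs[[gt]] <- tab
  }
  if (length(tabs) == 0L) stop("no single calls found for any requested gene type")
  combine_count_tables(tabs)
}
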