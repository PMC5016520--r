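#' Normalize a count per 10,000
#'
#' @param count Count (vectorized).
#' @param total Positive total of the same mode (clonotypes for
#'   diversity, sequences for expression).
#' @return \code{count / total * 10000}.
#' @export
normalize_per_10000 <- function(count, total) {
  if (any(total <= 0)) stop("total must be positive")
  count / total * 10000
}

#' Locus gene ordering
#'
#' Reads the bundled (approximate) human IGH locus ordering, or a
#' user-supplied two-column file \code{locus<TAB>gene}, giving the order
#' in which V/D/J genes are displayed in synthesis tables and plots.
#'
#' @param locus Locus name to extract (default \code{"IGH"}).
#' @param file Optional path to an alternative ordering file.
#' @return Character vector of gene names in locus order, with attribute
#'   \code{source} (\code{"bundled"} or the file path).
#' @export
gene_ordering <- function(locus = "IGH", file = NULL) {
  src <- if (is.null(file)) "bundled" else file
  if (is.null(file))
    file <- system.file("extdata", "igh_gene_order.tsv", package = "clonocomp")
  tab <- utils::read.table(file, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  genes <- tab$gene[tab$locus == locus]
  if (anyDuplicated(genes)) stop("duplicate gene names in ordering for ", locus)
  structure(genes, source = src)
}

#' Order items by locus position
#'
#' Known genes keep the ordering-file positions; unknown items are
#' appended in ascending name order with a warning. Allele items
#' (\code{gene*allele}) are ordered by gene position then allele.
#'
#' @param items Character vector of gene or allele names.
#' @param ordering Gene ordering from \code{\link{gene_ordering}}.
#' @return Integer permutation of \code{seq_along(items)}.
#' @export
order_genes <- function(items, ordering) {
  genes <- sub("\\*[^*]*$", "", items)
  pos <- match(genes, ordering)
  unknown <- unique(genes[is.na(pos)])
  if (length(unknown))
    warning("gene(s) not in ordering, appended in name order: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  pos[is.na(pos)] <- length(ordering) + rank(genes[is.na(pos)], ties.method = "min")
  order(pos, items)
}

#' Synthesis table of normalized proportions and test outcomes
#'
#' One row per tested item combining the per-10,000 normalized counts of
#' both sets, the difference in proportions with its confidence interval,
#' and a significance flag per multiple-testing procedure. V/D/J genes
#' are ordered by locus position; allele-level items in ascending name
#' order.
#'
#' @param rows \code{prop_test_results}.
#' @param ordering Gene ordering (\code{\link{gene_ordering}}); ignored
#'   for allele-level rows.
#' @return Data frame with columns \code{item}, \code{gene_type},
#'   \code{x1}, \code{x2}, \code{norm1}, \code{norm2}, \code{diff},
#'   \code{ci_low}, \code{ci_high}, \code{rawp} and one logical
#'   \code{sig_*} column per procedure.
#' @export
synthesis_table <- function(rows, ordering = gene_ordering()) {
  stopifnot(inherits(rows, "prop_test_results"))
  alpha <- attr(rows, "alpha")
  out <- data.frame(
    item = rows$item, gene_type = rows$gene_type,
    x1 = rows$x1, x2 = rows$x2,
    norm1 = normalize_per_10000(rows$x1, rows$n1),
    norm2 = normalize_per_10000(rows$x2, rows$n2),
    diff = rows$diff, ci_low = rows$ci_low, ci_high = rows$ci_high,
    rawp = rows$rawp,
    stringsAsFactors = FALSE
  )
  for (pr in .procedures)
    out[[paste0("sig_", pr)]] <- rows[[paste0("adj_", pr)]] < alpha
  ord <- if (all(rows$level == "allele")) order(out$item)
         else order_genes(out$item, ordering)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bar-and-interval synthesis plot
#'
#' Normalized per-10,000 proportions of both sets as side-by-side bars,
#' with the difference in proportions and its confidence interval in a
#' lower panel; items significant under every procedure are marked.
#'
#' @param synth Output of \code{\link{synthesis_table}}.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_synthesis <- function(synth, title = "Normalized gene proportions") {
  long <- rbind(
    data.frame(item = synth$item, set = "set1", norm = synth$norm1),
    data.frame(item = synth$item, set = "set2", norm = synth$norm2)
  )
  long$item <- factor(long$item, levels = synth$item)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$item, y = .data$norm,
                                     fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(title = title, x = NULL, y = "count per 10,000") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       hjust = 1, size = 6))
}

#' Bar plot of a CDR length distribution
#'
#' @param dist Output of \code{\link{length_distribution}}.
#' @return A ggplot object.
#' @export
plot_length_distribution <- function(dist) {
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$length, y = .data$count,
                                     fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = paste0("CDR", attr(dist, "cdr_type"), " length (AA)"),
                  y = if (attr(dist, "normalized")) "per 10,000"
                      else attr(dist, "mode")) +
    ggplot2::theme_minimal()
}

#' Rejection-count line graph
#'
#' @param curves Output of \code{\link{rejection_curves}}.
#' @return A ggplot object.
#' @export
plot_rejection_curves <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$alpha, y = .data$n_rejected,
                                       colour = .data$procedure)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = expression(alpha), y = "rejected null hypotheses") +
    ggplot2::theme_minimal()
}

#' Per-position variability plot
#'
#' @param profile A \code{\link{position_profile}}.
#' @param index \code{"shannon"}, \code{"wu_kabat"} or \code{"simpson"}.
#' @return A ggplot object.
#' @export
plot_variability <- function(profile, index = c("shannon", "wu_kabat", "simpson")) {
  index <- match.arg(index)
  df <- profile$indices
  df$position <- factor(df$position, levels = profile$positions)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data[[index]])) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "IMGT position", y = index,
                  title = paste0(profile$label, " CDR", profile$cdr_type,
                                 " length ", profile$L)) +
    ggplot2::theme_minimal()
}
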