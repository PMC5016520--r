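#' V-J / V-D / D-J gene-association contingency table
#'
#' Cross-tabulates, over the kept clonotypes of one set, the single-gene
#' calls of two gene types. Clonotypes with an ambiguous (several-gene)
#' or missing call for either type are excluded from the table and
#' reported in the \code{"excluded"} attribute, so the cell total equals
#' the number of clonotypes with single calls for both types.
#'
#' @param set A \code{repertoire_set}.
#' @param pair \code{"VJ"}, \code{"VD"} or \code{"DJ"} (rows x columns).
#' @param normalized Scale cells to counts per 10,000 of the cell total.
#' @param mode \code{"diversity"} (one count per clonotype) or
#'   \code{"expression"} (assigned-sequence weights).
#' @return A numeric matrix of class \code{association_matrix} (rows =
#'   first gene type, columns = second), with attributes \code{pair},
#'   \code{excluded} (count of excluded clonotypes) and
#'   \code{normalized}.
#' @export
association_matrix <- function(set, pair = c("VJ", "VD", "DJ"),
                               normalized = FALSE,
                               mode = c("diversity", "expression")) {
  pair <- match.arg(pair)
  mode <- match.arg(mode)
  stopifnot(inherits(set, "repertoire_set"))
  types <- strsplit(pair, "")[[1L]]
  r <- set$records
  g1 <- .classify_calls(r[[.call_column(types[1L])]], "gene")
  g2 <- .classify_calls(r[[.call_column(types[2L])]], "gene")
  ok <- !is.na(g1$item) & !is.na(g2$item)
  w <- if (mode == "diversity") rep(1, nrow(r)) else r$n_sequences
  if (!any(ok)) {
    warning("no clonotype with single ", types[1L], " and ", types[2L],
            " calls in ", set$label, call. = FALSE)
    m <- matrix(numeric(0), 0, 0)
  } else {
    m <- tapply(w[ok], list(g1$item[ok], g2$item[ok]), sum, default = 0)
    m <- m[sort(rownames(m)), sort(colnames(m)), drop = FALSE]
  }
  if (normalized && length(m) && sum(m) > 0) m <- normalize_per_10000(m, sum(m))
  structure(m, pair = pair, excluded = sum(w[!ok]), normalized = normalized,
            label = set$label, class = c("association_matrix", "matrix"))
}

#' Double Ward hierarchical clustering of an association matrix
#'
#' Clusters the rows (on their count vectors) and, independently, the
#' columns of a gene-association matrix by Ward's minimum-variance
#' criterion on Euclidean distances (the squared-distance updating
#' variant, \code{hclust} method \code{"ward.D2"}). Leaf orders come
#' from the dendrograms, whose tie-breaks are deterministic for a given
#' input ordering; merge heights are non-decreasing.
#'
#' @param mat An \code{association_matrix} (or any numeric matrix).
#' @return List with \code{row_order} and \code{col_order} (integer
#'   permutations) and \code{row_tree} / \code{col_tree} (\code{hclust}
#'   objects, \code{NULL} for a dimension with fewer than 2 items).
#' @export
ward_cluster <- function(mat) {
  one_way <- function(x) {
    if (nrow(x) < 2L) return(list(order = seq_len(nrow(x)), tree = NULL))
    h <- stats::hclust(stats::dist(x, method = "euclidean"), method = "ward.D2")
    list(order = h$order, tree = h)
  }
  rows <- one_way(unclass(mat))
  cols <- one_way(t(unclass(mat)))
  list(row_order = rows$order, col_order = cols$order,
       row_tree = rows$tree, col_tree = cols$tree)
}

#' Merge history of a clustering as a newick string
#'
#' @param tree An \code{hclust} object (e.g. from
#'   \code{\link{ward_cluster}}).
#' @return Newick string with merge heights as branch lengths.
#' @export
tree_newick <- function(tree) {
  stopifnot(inherits(tree, "hclust"))
  ape::write.tree(ape::as.phylo(tree))
}

#' Save an association heatmap with clustering dendrograms
#'
#' Static heatmap (PNG or PDF by file extension) of an association
#' matrix; when \code{cluster = TRUE} rows and columns are reordered by
#' \code{\link{ward_cluster}} and the dendrograms drawn in the margins.
#'
#' @param mat An \code{association_matrix}.
#' @param path Output image path (\code{.png} or \code{.pdf}).
#' @param cluster Apply the double Ward clustering (default \code{TRUE}).
#' @return The path, invisibly.
#' @export
save_association_heatmap <- function(mat, path, cluster = TRUE) {
  m <- unclass(mat)
  attr(m, "pair") <- attr(m, "excluded") <- attr(m, "normalized") <- attr(m, "label") <- NULL
  if (cluster && nrow(m) >= 2L && ncol(m) >= 2L) {
    cl <- ward_cluster(m)
    pheatmap::pheatmap(m, cluster_rows = cl$row_tree, cluster_cols = cl$col_tree,
                       filename = path, silent = TRUE)
  } else {
    pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                       filename = path, silent = TRUE)
  }
  invisible(path)
}
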