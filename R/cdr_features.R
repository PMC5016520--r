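#' CDR length distribution for one or two repertoire sets
#'
#' Distribution of clonotypes (diversity) or assigned sequences
#' (expression) per CDR length for a given CDR type. CDR3 lengths come
#' from the \code{cdr3_length} field; CDR1/CDR2 lengths are measured on
#' the stored amino-acid strings. Optionally normalized per 10,000.
#'
#' @param set1 A \code{repertoire_set}.
#' @param set2 Optional second \code{repertoire_set}.
#' @param cdr_type 1, 2 or 3.
#' @param mode \code{"diversity"} or \code{"expression"}.
#' @param normalized Report counts per 10,000 of the set total.
#' @return Data frame of class \code{length_distribution} with columns
#'   \code{set}, \code{length}, \code{count} (long format; every length
#'   observed in either set appears for both, zero-filled).
#' @export
length_distribution <- function(set1, set2 = NULL, cdr_type = 3,
                                mode = c("diversity", "expression"),
                                normalized = FALSE) {
  mode <- match.arg(mode)
  sets <- list(set1)
  if (!is.null(set2)) sets <- c(sets, list(set2))
  lens_of <- function(set) {
    r <- set$records
    switch(as.character(cdr_type),
           "1" = nchar(r$cdr1_aa),
           "2" = nchar(r$cdr2_aa),
           "3" = r$cdr3_length,
           stop("cdr_type must be 1, 2 or 3"))
  }
  per_set <- lapply(sets, function(set) {
    len <- lens_of(set)
    w <- if (mode == "diversity") rep(1, nrow(set$records)) else set$records$n_sequences
    keep <- !is.na(len) & len > 0
    if (!any(keep) && nrow(set$records) > 0L)
      warning("no CDR", cdr_type, " sequences available in ", set$label, call. = FALSE)
    tapply(w[keep], len[keep], sum)
  })
  all_len <- sort(as.integer(unique(unlist(lapply(per_set, names)))))
  out <- do.call(rbind, lapply(seq_along(sets), function(i) {
    cnt <- per_set[[i]]
    v <- ifelse(as.character(all_len) %in% names(cnt), cnt[as.character(all_len)], 0)
    v[is.na(v)] <- 0
    if (normalized) v <- normalize_per_10000(v, .set_total(sets[[i]], mode))
    data.frame(set = sets[[i]]$label, length = all_len, count = as.numeric(v),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, cdr_type = cdr_type, mode = mode, normalized = normalized,
            class = c("length_distribution", "data.frame"))
}

#' List the CDR3 sequences of the clonotypes at one length
#'
#' @param set A \code{repertoire_set}.
#' @param L CDR3 amino-acid length.
#' @return Data frame with columns \code{cdr3_aa}, \code{v_call},
#'   \code{j_call}, \code{n_sequences}; zero rows (with a message) when
#'   \code{L} is outside the set's filter range.
#' @export
list_cdr3_at_length <- function(set, L) {
  stopifnot(inherits(set, "repertoire_set"))
  if (L < set$cdr3_min || L > set$cdr3_max)
    message("length ", L, " is outside the filtered CDR3 range [",
            set$cdr3_min, ", ", set$cdr3_max, "]")
  r <- set$records[!is.na(set$records$cdr3_length) & set$records$cdr3_length == L, ,
                   drop = FALSE]
  out <- r[, c("cdr3_aa", "v_call", "j_call", "n_sequences")]
  rownames(out) <- NULL
  out
}

#' IMGT unique-numbering position labels for a CDR3 of length L
#'
#' The CDR3 loop spans base positions 105-117 (13 positions; the anchors
#' 104 and 118 are excluded). Shorter loops lose positions symmetrically
#' from the loop top between 111 and 112 (the right side first); longer
#' loops gain insertion labels at the top, 112.1 first, then 111.1,
#' 112.2, 111.2, ... The left block always holds \code{ceiling(L/2)}
#' labels and the right block \code{floor(L/2)}.
#'
#' @param L CDR3 length in amino acids (1 to 45 supported downstream;
#'   any L >= 1 is labelled).
#' @return Character vector of exactly \code{L} position labels.
#' @examples
#' imgt_cdr3_positions(13) # 105 ... 117, no gaps
#' imgt_cdr3_positions(15) # insertions 111.1 and 112.1 at the loop top
#' @export
imgt_cdr3_positions <- function(L) {
  .numbered_positions(L, first = 105L, last = 117L, allow_insertions = TRUE)
}

.numbered_positions <- function(L, first, last, allow_insertions = FALSE) {
  stopifnot(length(L) == 1L, L >= 1L)
  L <- as.integer(L)
  span <- last - first + 1L
  n_left <- ceiling(L / 2)
  n_right <- floor(L / 2)
  base_left <- ceiling(span / 2)   # e.g. 105..111 for CDR3
  base_right <- floor(span / 2)    # e.g. 112..117
  if (L <= span) {
    left <- seq(first, length.out = min(n_left, base_left))
    right <- seq(last, by = -1L, length.out = min(n_right, base_right))
    return(c(as.character(left), rev(as.character(right))))
  }
  if (!allow_insertions)
    stop("length ", L, " exceeds the ", span, "-position span ", first, "-", last)
  n_ins <- L - span
  left_ins <- floor(n_ins / 2)     # 111.1, 111.2, ...
  right_ins <- ceiling(n_ins / 2)  # 112.1 first at odd counts
  top_left <- first + base_left - 1L
  top_right <- last - base_right + 1L
  c(as.character(seq(first, top_left)),
    if (left_ins > 0) paste0(top_left, ".", seq_len(left_ins)),
    if (right_ins > 0) paste0(top_right, ".", rev(seq_len(right_ins))),
    as.character(seq(top_right, last)))
}

#' IMGT position labels for any CDR type
#'
#' CDR1 occupies positions 27-38 and CDR2 positions 56-65 of the V
#' domain; both are germline-encoded and bounded by their span, with the
#' same symmetric loop-top gap rule as CDR3. CDR3 (105-117) additionally
#' admits loop-top insertions.
#'
#' @param cdr_type 1, 2 or 3.
#' @param L CDR length in amino acids.
#' @return Character vector of \code{L} labels.
#' @export
cdr_positions <- function(cdr_type, L) {
  switch(as.character(cdr_type),
         "1" = .numbered_positions(L, 27L, 38L),
         "2" = .numbered_positions(L, 56L, 65L),
         "3" = imgt_cdr3_positions(L),
         stop("cdr_type must be 1, 2 or 3"))
}

.aa_class_env <- new.env(parent = emptyenv())

#' Amino-acid class maps
#'
#' Returns the mapping from the 20 standard amino-acid letters to class
#' representatives under one classification scheme. Schemes
#' \code{"hydropathy"}, \code{"volume"}, \code{"chemical"},
#' \code{"charge"}, \code{"hydrogen"} and \code{"polarity"} are read from
#' the editable table \code{extdata/aa_classes.tsv}; \code{"AA"} and
#' \code{"physicochemical"} are the identity (each residue its own
#' class).
#'
#' @param scheme Classification scheme name.
#' @param file Optional path to an alternative class table (same format
#'   as the bundled one).
#' @return Named character vector: names are AA letters, values class
#'   names.
#' @export
aa_classes <- function(scheme = c("AA", "hydropathy", "volume", "chemical",
                                  "charge", "hydrogen", "polarity",
                                  "physicochemical"),
                       file = NULL) {
  scheme <- match.arg(scheme)
  if (scheme %in% c("AA", "physicochemical"))
    return(stats::setNames(.AA20, .AA20))
  if (is.null(file)) {
    file <- system.file("extdata", "aa_classes.tsv", package = "clonocomp")
    key <- paste0("bundled::", scheme)
  } else key <- paste0(file, "::", scheme)
  if (!is.null(.aa_class_env[[key]])) return(.aa_class_env[[key]])
  tab <- utils::read.table(file, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  tab <- tab[tab$scheme == scheme, , drop = FALSE]
  if (nrow(tab) == 0L) stop("scheme '", scheme, "' not found in ", file)
  map <- character(0)
  for (i in seq_len(nrow(tab))) {
    letters_i <- strsplit(tab$aa[i], "")[[1L]]
    map[letters_i] <- tab$class[i]
  }
  missing <- setdiff(.AA20, names(map))
  if (length(missing))
    stop("scheme '", scheme, "' does not cover amino acid(s): ",
         paste(missing, collapse = ", "))
  .aa_class_env[[key]] <- map
  map
}

#' Positional amino-acid (or class) profile of a CDR at one length
#'
#' Every kept clonotype whose CDR of the requested type has length
#' \code{L} contributes its residue, mapped through the class scheme, at
#' each IMGT position. Counts are per clonotype (diversity, default) or
#' weighted by assigned sequences (expression). Per-position variability
#' is summarized by Shannon entropy (bits), the Wu-Kabat coefficient and
#' the Simpson index.
#'
#' @param set A \code{repertoire_set}.
#' @param cdr_type 1, 2 or 3.
#' @param L CDR length to profile.
#' @param class_scheme See \code{\link{aa_classes}}; default \code{"AA"}.
#' @param mode \code{"diversity"} or \code{"expression"}.
#' @return Object of class \code{position_profile}: list with
#'   \code{positions} (IMGT labels), \code{counts} (classes x positions
#'   matrix), \code{indices} (data frame \code{position},
#'   \code{shannon}, \code{wu_kabat}, \code{simpson}),
#'   \code{n_contributing} and the call metadata.
#' @export
position_profile <- function(set, cdr_type = 3, L, class_scheme = "AA",
                             mode = c("diversity", "expression")) {
  mode <- match.arg(mode)
  stopifnot(inherits(set, "repertoire_set"))
  r <- set$records
  seqs <- switch(as.character(cdr_type), "1" = r$cdr1_aa, "2" = r$cdr2_aa,
                 "3" = r$cdr3_aa, stop("cdr_type must be 1, 2 or 3"))
  sel <- !is.na(seqs) & nchar(seqs) == L
  seqs <- seqs[sel]
  w <- if (mode == "diversity") rep(1, sum(sel)) else r$n_sequences[sel]
  if (length(seqs) == 0L) stop("no clonotype with CDR", cdr_type, " of length ", L)
  known <- grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", seqs)
  if (any(!known)) {
    warning(sum(!known), " sequence(s) with non-standard letters skipped",
            call. = FALSE)
    seqs <- seqs[known]; w <- w[known]
  }
  map <- aa_classes(class_scheme)
  positions <- cdr_positions(cdr_type, L)
  letters_mat <- matrix(unlist(strsplit(seqs, "")), ncol = L, byrow = TRUE)
  classes <- sort(unique(unname(map)))
  counts <- matrix(0, nrow = length(classes), ncol = L,
                   dimnames = list(classes, positions))
  for (j in seq_len(L)) {
    cl <- map[letters_mat[, j]]
    tj <- tapply(w, cl, sum)
    counts[names(tj), j] <- tj
  }
  indices <- data.frame(
    position = positions,
    shannon = apply(counts, 2, shannon_entropy),
    wu_kabat = apply(counts, 2, wu_kabat),
    simpson = apply(counts, 2, simpson_index),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(positions = positions, counts = counts, indices = indices,
         n_contributing = sum(w), cdr_type = cdr_type, L = L,
         class_scheme = class_scheme, mode = mode, label = set$label),
    class = "position_profile"
  )
}

#' @export
print.position_profile <- function(x, ...) {
  cat("<position_profile> ", x$label, ": CDR", x$cdr_type, " length ", x$L,
      ", scheme ", x$class_scheme, " (", x$mode, ")\n", sep = "")
  cat("  contributions: ", x$n_contributing, "\n", sep = "")
  print(round(x$indices, 3))
  invisible(x)
}

#' Shannon entropy of a count vector (bits)
#'
#' \deqn{H = -\sum_i p_i \log_2 p_i} over the classes with positive
#' count. Positions with H > 2 bits are conventionally read as variable,
#' H < 1 as highly conserved.
#'
#' @param counts Non-negative counts, at least one positive.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(counts) {
  p <- .props(counts)
  -sum(p * log2(p))
}

#' Wu-Kabat variability coefficient
#'
#' Ratio between the number of distinct residues (or class
#' representatives) observed at a position, scaled by the total, and the
#' frequency of the most represented one: \code{k * N / n_max}. Equals 1
#' for a monomorphic position; larger is more variable.
#'
#' @inheritParams shannon_entropy
#' @return Coefficient >= 1.
#' @export
wu_kabat <- function(counts) {
  counts <- .check_counts(counts)
  pos <- counts[counts > 0]
  length(pos) * sum(pos) / max(pos)
}

#' Simpson diversity index
#'
#' \deqn{D = 1 - \sum_i p_i^2}: the probability that two random draws
#' from the position differ in class; 0 for a monomorphic position.
#'
#' @inheritParams shannon_entropy
#' @return Index in [0, 1].
#' @export
simpson_index <- function(counts) {
  p <- .props(counts)
  1 - sum(p^2)
}

.check_counts <- function(counts) {
  stopifnot(is.numeric(counts), all(counts >= 0))
  if (sum(counts) == 0) stop("variability index undefined for all-zero counts")
  counts
}

.props <- function(counts) {
  counts <- .check_counts(counts)
  pos <- counts[counts > 0]
  pos / sum(pos)
}
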