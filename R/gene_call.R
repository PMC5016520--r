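#' Parse an IMGT gene/allele call
#'
#' Interprets a gene-and-allele call string as produced by repertoire
#' annotation tools, e.g. \code{"IGHV4-34*01"}, \code{"IGHJ4*02"}, or an
#' ambiguous multi-gene call such as \code{"IGHV1-69*01, IGHV1-69D*01"}.
#' Functionality annotations appended to calls (\code{F}, \code{ORF},
#' \code{P}, possibly in parentheses or brackets) and a leading species
#' token (e.g. \code{"Homsap"}) are stripped before parsing: they are
#' metadata, not identity.
#'
#' @param text A single call string.
#' @return An object of class \code{gene_call}: a list with elements
#'   \code{raw} (input as read), \code{group} (locus group, e.g.
#'   \code{"IGHV"}), \code{gene} (gene name for single-gene calls, or the
#'   shared gene when a several-allele call lists alleles of one gene,
#'   otherwise \code{NA}), \code{allele} (two-digit-style allele suffix
#'   without the star, \code{NA} when absent), \code{is_several}
#'   (\code{TRUE} when more than one gene, or more than one allele of one
#'   gene, is listed) and \code{members} (data frame with columns
#'   \code{gene}, \code{allele}, one row per listed candidate).
#' @examples
#' parse_gene_call("IGHV4-34*01")
#' parse_gene_call("IGHV1-69*01, IGHV1-69D*01")$is_several
#' @export
parse_gene_call <- function(text) {
  if (length(text) != 1L) stop("parse_gene_call() takes a single string; see parse_gene_calls()")
  df <- parse_gene_calls(text)
  if (is.na(df$group)) stop("unparseable gene call: '", text, "'")
  members <- attr(df, "members")[[1L]]
  structure(
    list(
      raw = text,
      group = df$group,
      gene = df$gene,
      allele = df$allele,
      is_several = df$is_several,
      members = members
    ),
    class = "gene_call"
  )
}

#' @export
print.gene_call <- function(x, ...) {
  cat("<gene_call> ", format_gene_call(x), "\n", sep = "")
  cat("  group: ", x$group,
      "  several: ", x$is_several,
      "  members: ", nrow(x$members), "\n", sep = "")
  invisible(x)
}

#' Format a gene call back to its canonical text form
#'
#' Members are joined with \code{", "}; a single member with an allele is
#' rendered as \code{gene*allele}. Reading the result back with
#' \code{\link{parse_gene_call}} reproduces the same members.
#'
#' @param call A \code{gene_call} object.
#' @return A single string.
#' @export
format_gene_call <- function(call) {
  stopifnot(inherits(call, "gene_call"))
  format_members(call$members)
}

format_members <- function(members) {
  paste(ifelse(is.na(members$allele),
               members$gene,
               paste0(members$gene, "*", members$allele)),
        collapse = ", ")
}

# locus group = locus code (IGH/IGK/IGL, TRA/TRB/TRG/TRD) + gene-type letter
.group_regex <- "^(IG[HKL]|TR[ABGD])([VDJ])"

.strip_annotations <- function(x) {
  # functionality flags and species prefixes are annotations, not identity
  x <- gsub("[\\[(]\\s*(F|ORF|P)\\s*[\\])]", "", x, perl = TRUE)
  x <- gsub("(^|\\s)(F|ORF|P)(?=\\s|,|$)", "\\1", x, perl = TRUE)
  x <- gsub("(^|[,\\s])Homsap\\s+", "\\1", x)
  trimws(gsub("\\s+", " ", x))
}

.parse_member <- function(tok) {
  # one candidate: GENE or GENE*ALLELE
  m <- regmatches(tok, regexec("^((IG[HKL]|TR[ABGD])[VDJ][A-Za-z0-9/().-]*?)(\\*([0-9]+[A-Za-z]*))?$", tok))[[1L]]
  if (length(m) == 0L) return(NULL)
  list(gene = m[2L], allele = if (nzchar(m[4L])) m[5L] else NA_character_)
}

#' Parse many gene calls at once
#'
#' Vectorized companion of \code{\link{parse_gene_call}}, used by the
#' counting layer. Unparseable or empty strings yield a row of \code{NA}s
#' rather than an error so callers can report offending records.
#'
#' @param x Character vector of call strings (\code{NA}/empty allowed).
#' @return A data frame with one row per input and columns \code{raw},
#'   \code{group}, \code{gene}, \code{allele}, \code{is_several},
#'   \code{n_members}; the parsed member tables are attached as the
#'   \code{"members"} attribute (a list of data frames).
#' @export
parse_gene_calls <- function(x) {
  x <- as.character(x)
  ux <- unique(x)
  parsed <- lapply(ux, .parse_one_call)
  idx <- match(x, ux)
  out <- data.frame(
    raw = x,
    group = vapply(parsed, `[[`, "", "group")[idx],
    gene = vapply(parsed, `[[`, "", "gene")[idx],
    allele = vapply(parsed, `[[`, "", "allele")[idx],
    is_several = vapply(parsed, `[[`, NA, "is_several")[idx],
    n_members = vapply(parsed, `[[`, 0L, "n_members")[idx],
    stringsAsFactors = FALSE
  )
  attr(out, "members") <- lapply(parsed, `[[`, "members")[idx]
  out
}

.parse_one_call <- function(text) {
  bad <- list(group = NA_character_, gene = NA_character_, allele = NA_character_,
              is_several = NA, n_members = 0L, members = NULL)
  if (is.na(text)) return(bad)
  clean <- .strip_annotations(text)
  if (!nzchar(clean)) return(bad)
  toks <- trimws(unlist(strsplit(clean, "\\s*,\\s*|\\s+or\\s+")))
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0L) return(bad)
  mem <- lapply(toks, .parse_member)
  if (any(vapply(mem, is.null, NA))) return(bad)
  members <- data.frame(
    gene = vapply(mem, `[[`, "", "gene"),
    allele = vapply(mem, function(m) m$allele, NA_character_),
    stringsAsFactors = FALSE
  )
  groups <- regmatches(members$gene, regexpr(paste0(.group_regex, ""), members$gene))
  if (length(unique(groups)) != 1L) return(bad)
  several <- nrow(members) >= 2L
  same_gene <- length(unique(members$gene)) == 1L
  list(
    group = groups[1L],
    # several alleles of one gene still identify that gene
    gene = if (!several || same_gene) members$gene[1L] else NA_character_,
    allele = if (!several) members$allele[1L] else NA_character_,
    is_several = several,
    n_members = nrow(members),
    members = members
  )
}
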