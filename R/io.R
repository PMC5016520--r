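#' Column dialect for clonotype stats tables
#'
#' Annotation pipelines export the per-clonotype summary ("stats") table
#' under varying column names. A dialect maps the semantic fields this
#' package needs onto the columns of a concrete file. The canonical dialect
#' uses the names \code{clonotype_id}, \code{v_call}, \code{d_call},
#' \code{j_call}, \code{cdr1_aa}, \code{cdr2_aa}, \code{cdr3_aa},
#' \code{cdr3_length}, \code{n_sequences}; real exports can be adapted by
#' overriding entries of \code{column_map}, e.g. from a small YAML/JSON
#' key-value file (see \code{\link{read_dialect_file}}).
#'
#' @param column_map Named character vector or list mapping semantic field
#'   names to file column names. Unnamed fields keep their canonical names.
#'   \code{v_call}, \code{j_call} and \code{cdr3_aa} are mandatory and
#'   cannot be unmapped.
#' @param sep Field separator (default tab).
#' @param comment_prefix Lines starting with this prefix are skipped
#'   (default \code{"#"}).
#' @return An object of class \code{stats_dialect}.
#' @export
stats_dialect <- function(column_map = NULL, sep = "\t", comment_prefix = "#") {
  fields <- c("clonotype_id", "v_call", "d_call", "j_call",
              "cdr1_aa", "cdr2_aa", "cdr3_aa", "cdr3_length", "n_sequences")
  map <- stats::setNames(fields, fields)
  if (!is.null(column_map)) {
    column_map <- unlist(column_map)
    unknown <- setdiff(names(column_map), fields)
    if (length(unknown))
      stop("unknown dialect field(s): ", paste(unknown, collapse = ", "))
    map[names(column_map)] <- column_map
  }
  structure(list(column_map = map, sep = sep, comment_prefix = comment_prefix),
            class = "stats_dialect")
}

#' Read a dialect description from a YAML (or JSON) key-value file
#'
#' The file holds entries \code{field: column name}, plus the optional
#' reserved keys \code{sep} and \code{comment_prefix}.
#'
#' @param path Path to the YAML/JSON file.
#' @return A \code{\link{stats_dialect}}.
#' @export
read_dialect_file <- function(path) {
  kv <- yaml::read_yaml(path)
  sep <- if (!is.null(kv$sep)) kv$sep else "\t"
  cp <- if (!is.null(kv$comment_prefix)) kv$comment_prefix else "#"
  kv$sep <- NULL
  kv$comment_prefix <- NULL
  stats_dialect(column_map = kv, sep = sep, comment_prefix = cp)
}

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Read a clonotype stats table
#'
#' Reads one tab-separated clonotype table (one row per amino-acid
#' clonotype: V/(D)/J calls, CDR amino-acid sequences, CDR3 length, number
#' of sequences assigned) into a validated record data frame. Rows that
#' violate record invariants are not silently dropped: they are collected,
#' with a reason, in the \code{"rejected"} attribute (see
#' \code{\link{rejected_rows}}).
#'
#' Validation per row: the V and J calls (and the D call when non-empty)
#' must parse as gene calls; \code{cdr3_aa} may contain only the 20
#' standard amino-acid letters; \code{cdr3_length}, when supplied, must
#' equal \code{nchar(cdr3_aa)} for non-empty \code{cdr3_aa};
#' \code{n_sequences} must be an integer >= 1 (it defaults to 1 when the
#' column is absent).
#'
#' @param path Path to the file.
#' @param dialect A \code{\link{stats_dialect}}; default canonical.
#' @return A data frame of class \code{clonotype_records} with columns
#'   \code{clonotype_id}, \code{v_call}, \code{d_call}, \code{j_call},
#'   \code{cdr1_aa}, \code{cdr2_aa}, \code{cdr3_aa}, \code{cdr3_length},
#'   \code{n_sequences}; rejected rows as attribute \code{"rejected"}.
#' @export
read_stats_file <- function(path, dialect = stats_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (nzchar(dialect$comment_prefix))
    lines <- lines[!startsWith(lines, dialect$comment_prefix)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty stats file: ", path)
    return(.empty_records())
  }
  raw <- utils::read.table(
    text = lines, sep = dialect$sep, header = TRUE,
    colClasses = "character", check.names = FALSE,
    quote = "", comment.char = "", stringsAsFactors = FALSE
  )
  map <- dialect$column_map
  mandatory <- c("v_call", "j_call", "cdr3_aa")
  missing_cols <- mandatory[!(map[mandatory] %in% names(raw))]
  if (length(missing_cols))
    stop("mandatory column(s) missing from ", path, ": ",
         paste(map[missing_cols], collapse = ", "))
  get_col <- function(field, default) {
    col <- map[[field]]
    if (col %in% names(raw)) raw[[col]] else rep(default, nrow(raw))
  }
  rec <- data.frame(
    clonotype_id = get_col("clonotype_id", NA_character_),
    v_call = get_col("v_call", NA_character_),
    d_call = get_col("d_call", ""),
    j_call = get_col("j_call", NA_character_),
    cdr1_aa = get_col("cdr1_aa", ""),
    cdr2_aa = get_col("cdr2_aa", ""),
    cdr3_aa = get_col("cdr3_aa", NA_character_),
    cdr3_length = suppressWarnings(as.integer(get_col("cdr3_length", NA_character_))),
    n_sequences = suppressWarnings(as.integer(get_col("n_sequences", "1"))),
    stringsAsFactors = FALSE
  )
  if (all(is.na(rec$clonotype_id))) rec$clonotype_id <- as.character(seq_len(nrow(rec)))
  rec$cdr3_length[is.na(rec$cdr3_length)] <- nchar(rec$cdr3_aa)[is.na(rec$cdr3_length)]
  validate_clonotype_records(rec, source = path)
}

.empty_records <- function() {
  rec <- data.frame(
    clonotype_id = character(), v_call = character(), d_call = character(),
    j_call = character(), cdr1_aa = character(), cdr2_aa = character(),
    cdr3_aa = character(), cdr3_length = integer(), n_sequences = integer(),
    stringsAsFactors = FALSE
  )
  structure(rec, rejected = cbind(rec[0, ], reason = character()),
            class = c("clonotype_records", "data.frame"))
}

#' Validate clonotype records against the record invariants
#'
#' @param rec Data frame with the canonical record columns.
#' @param source Label used in the warning when rows are rejected.
#' @return \code{clonotype_records} data frame (valid rows) with the
#'   invalid rows and their reasons in the \code{"rejected"} attribute.
#' @export
validate_clonotype_records <- function(rec, source = "input") {
  reason <- rep(NA_character_, nrow(rec))
  flag <- function(bad, why) reason[bad & is.na(reason)] <<- why

  vp <- parse_gene_calls(rec$v_call)
  jp <- parse_gene_calls(rec$j_call)
  flag(is.na(vp$group), "unparseable v_call")
  flag(is.na(jp$group), "unparseable j_call")
  has_d <- !is.na(rec$d_call) & nzchar(rec$d_call)
  if (any(has_d)) {
    dp <- parse_gene_calls(rec$d_call[has_d])
    bad_d <- rep(FALSE, nrow(rec)); bad_d[has_d] <- is.na(dp$group)
    flag(bad_d, "unparseable d_call")
  }
  aa_ok <- !is.na(rec$cdr3_aa) & grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", rec$cdr3_aa)
  flag(!aa_ok, "cdr3_aa not composed of the 20 standard amino acids")
  len_ok <- is.na(rec$cdr3_length) | !nzchar(rec$cdr3_aa) |
    rec$cdr3_length == nchar(rec$cdr3_aa)
  flag(!len_ok, "cdr3_length does not match nchar(cdr3_aa)")
  flag(is.na(rec$n_sequences) | rec$n_sequences < 1L, "n_sequences missing or < 1")

  rejected <- rec[!is.na(reason), , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reason <- reason[!is.na(reason)]
    warning(nrow(rejected), " record(s) rejected while reading ", source,
            " (see rejected_rows())", call. = FALSE)
  } else {
    rejected <- cbind(rec[0, , drop = FALSE], reason = character())
  }
  kept <- rec[is.na(reason), , drop = FALSE]
  rownames(kept) <- NULL
  structure(kept, rejected = rejected,
            class = c("clonotype_records", "data.frame"))
}

#' Rows rejected while reading a clonotype table
#'
#' @param records A \code{clonotype_records} object.
#' @return Data frame of rejected rows with a \code{reason} column.
#' @export
rejected_rows <- function(records) {
  rej <- attr(records, "rejected")
  if (is.null(rej)) cbind(.empty_records()[0, ], reason = character()) else rej
}

#' Write the rejected-rows report as CSV
#'
#' @param records A \code{clonotype_records} object.
#' @param path Output CSV path.
#' @export
write_rejected_report <- function(records, path) {
  utils::write.csv(rejected_rows(records), path, row.names = FALSE)
  invisible(path)
}

#' Write a clonotype stats table
#'
#' Inverse of \code{\link{read_stats_file}}: writing then reading
#' reproduces the records field for field (absent D calls round-trip
#' through an empty field).
#'
#' @param records Record data frame (canonical columns).
#' @param path Output path.
#' @param dialect A \code{\link{stats_dialect}}.
#' @export
write_stats_file <- function(records, path, dialect = stats_dialect()) {
  map <- dialect$column_map
  out <- data.frame(
    records$clonotype_id, records$v_call, records$d_call, records$j_call,
    records$cdr1_aa, records$cdr2_aa, records$cdr3_aa,
    records$cdr3_length, records$n_sequences,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  names(out) <- unname(map[c("clonotype_id", "v_call", "d_call", "j_call",
                             "cdr1_aa", "cdr2_aa", "cdr3_aa",
                             "cdr3_length", "n_sequences")])
  utils::write.table(out, path, sep = dialect$sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
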