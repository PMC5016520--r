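#' Run configuration for a full comparison
#'
#' Validated bundle of everything one comparison run needs. It is
#' persisted (as part of the JSON manifest) alongside the outputs so a
#' run can be reproduced exactly.
#'
#' @param set1,set2 Paths to the two clonotype stats files.
#' @param dialect A \code{\link{stats_dialect}} or path to a dialect
#'   YAML file.
#' @param cdr3_min,cdr3_max Inclusive CDR3 length bounds (defaults 4, 45).
#' @param alpha Type I error rate (default 0.05).
#' @param mode \code{"diversity"} or \code{"expression"}.
#' @param levels Levels to test: subset of \code{c("gene", "allele")}.
#' @param all_alleles Test every observed allele instead of only alleles
#'   of all-procedure-validated genes.
#' @param order_file Optional locus ordering file
#'   (\code{\link{gene_ordering}}).
#' @param out Output directory (created if needed).
#' @param seed Integer seed recorded in the manifest (used by simulation
#'   subcommands; the comparison itself is deterministic).
#' @return Object of class \code{run_config}.
#' @export
run_config <- function(set1, set2, dialect = stats_dialect(),
                       cdr3_min = 4L, cdr3_max = 45L, alpha = 0.05,
                       mode = c("diversity", "expression"),
                       levels = c("gene", "allele"),
                       all_alleles = FALSE,
                       order_file = NULL, out = "clonocomp_out", seed = 1L) {
  mode <- match.arg(mode)
  if (is.character(dialect)) dialect <- read_dialect_file(dialect)
  stopifnot(inherits(dialect, "stats_dialect"))
  if (!all(levels %in% c("gene", "allele")))
    stop("levels must be a subset of c('gene', 'allele')")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (!(cdr3_min >= 1 && cdr3_max >= cdr3_min))
    stop("invalid CDR3 length range")
  for (p in c(set1, set2)) if (!file.exists(p)) stop("input file not found: ", p)
  structure(list(
    set1 = set1, set2 = set2, dialect = dialect,
    cdr3_min = as.integer(cdr3_min), cdr3_max = as.integer(cdr3_max),
    alpha = alpha, mode = mode, levels = levels, all_alleles = all_alleles,
    order_file = order_file, out = out, seed = as.integer(seed)
  ), class = "run_config")
}

.write_csv <- function(df, dir, name, digits = 6) {
  num <- vapply(df, is.numeric, NA) & !vapply(df, is.integer, NA)
  df[num] <- lapply(df[num], signif, digits = digits)
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  path
}

#' Run the full comparison pipeline
#'
#' Reads both sets, applies the CDR3 length filter, runs the gene-level
#' (and, when requested, allele-level) difference-in-proportions tests
#' with all seven multiple-testing adjustments, and writes the complete
#' set of report files into \code{config$out}: per-set summaries,
#' rejected-row reports, 21-plus-column results tables, rejection-curve
#' and scatter tables, synthesis tables, the small-occurrence list, and
#' a JSON manifest recording the configuration, package version and the
#' key counts of the run. Outputs are deterministic: the same
#' configuration produces byte-identical files.
#'
#' @param config A \code{\link{run_config}}.
#' @return Invisibly, a list with the two \code{repertoire_set}s, the
#'   result tables and the manifest.
#' @export
run_compare_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)

  rec1 <- read_stats_file(config$set1, config$dialect)
  rec2 <- read_stats_file(config$set2, config$dialect)
  s1 <- filter_cdr3_range(rec1, config$cdr3_min, config$cdr3_max, label = "set1")
  s2 <- filter_cdr3_range(rec2, config$cdr3_min, config$cdr3_max, label = "set2")

  .write_csv(rbind(set_summary(s1), set_summary(s2)), config$out, "set_summary.csv")
  write_rejected_report(rec1, file.path(config$out, "rejected_set1.csv"))
  write_rejected_report(rec2, file.path(config$out, "rejected_set2.csv"))
  if (nrow(s1$outliers) || nrow(s2$outliers))
    .write_csv(rbind(cbind(set = "set1", s1$outliers),
                     cbind(set = "set2", s2$outliers)),
               config$out, "cdr3_length_outliers.csv")

  ordering <- if (is.null(config$order_file)) gene_ordering()
              else gene_ordering(file = config$order_file)

  results <- list()
  gene_rows <- NULL
  if ("gene" %in% config$levels) {
    tab <- count_family(s1, s2, level = "gene", mode = config$mode)
    gene_rows <- run_comparison(tab, alpha = config$alpha)
    results$genes <- gene_rows
    .write_csv(as.data.frame(gene_rows), config$out, "results_genes.csv")
    .write_csv(rejection_curves(gene_rows), config$out, "rejection_curves_genes.csv")
    .write_csv(scatter_table(gene_rows), config$out, "scatter_genes.csv")
    .write_csv(suppressWarnings(synthesis_table(gene_rows, ordering)),
               config$out, "synthesis_genes.csv")
    .write_csv(attr(tab, "several"), config$out, "several_genes.csv")
    writeLines(attr(gene_rows, "small_occurrence"),
               file.path(config$out, "small_occurrence_genes.txt"))
  }
  if ("allele" %in% config$levels) {
    if (is.null(gene_rows)) {
      tab <- count_family(s1, s2, level = "allele", mode = config$mode)
      allele_rows <- run_comparison(tab, alpha = config$alpha)
    } else {
      allele_rows <- suppressMessages(
        allele_followup(gene_rows, s1, s2, mode = config$mode,
                        alpha = config$alpha, all_alleles = config$all_alleles))
    }
    results$alleles <- allele_rows
    .write_csv(as.data.frame(allele_rows), config$out, "results_alleles.csv")
    if (nrow(allele_rows)) {
      .write_csv(rejection_curves(allele_rows), config$out,
                 "rejection_curves_alleles.csv")
      .write_csv(scatter_table(allele_rows), config$out, "scatter_alleles.csv")
      .write_csv(suppressWarnings(synthesis_table(allele_rows, ordering)),
                 config$out, "synthesis_alleles.csv")
    }
    writeLines(attr(allele_rows, "small_occurrence"),
               file.path(config$out, "small_occurrence_alleles.txt"))
  }

  manifest <- list(
    package = "clonocomp",
    version = as.character(utils::packageVersion("clonocomp")),
    config = list(
      set1 = config$set1, set2 = config$set2,
      column_map = as.list(config$dialect$column_map),
      sep = config$dialect$sep,
      cdr3_min = config$cdr3_min, cdr3_max = config$cdr3_max,
      alpha = config$alpha, mode = config$mode,
      levels = as.list(config$levels), all_alleles = config$all_alleles,
      seed = config$seed
    ),
    counts = list(
      set1 = as.list(set_summary(s1)[-1]),
      set2 = as.list(set_summary(s2)[-1]),
      gene_hypotheses = if (!is.null(results$genes)) nrow(results$genes) else NULL,
      allele_hypotheses = if (!is.null(results$alleles)) nrow(results$alleles) else NULL
    )
  )
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(set1 = s1, set2 = s2, results = results, manifest = manifest))
}
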