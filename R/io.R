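# Table readers/writers (TSV for genomic tables, CSV for assay tables) and
# the end-to-end pipeline driver. Validation errors name the offending line
# of the input file (header = line 1).

.read_table <- function(path, sep) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  utils::read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    quote = "\"", comment.char = "", check.names = TRUE,
                    na.strings = c("NA", ""))
}

.require_cols <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("'", path, "' lacks required column(s): ",
         paste(missing, collapse = ", "))
}

#' Read a two-condition gene count table
#'
#' Tab-separated file with a header and columns `gene_id`, `count_group1`,
#' `count_group2`. Counts must be non-negative integers and gene ids unique;
#' malformed rows are reported with their file line number.
#'
#' @param path Path to the TSV file.
#' @return Data frame with the three validated columns.
#' @export
read_counts <- function(path) {
  df <- .read_table(path, sep = "\t")
  .require_cols(df, c("gene_id", "count_group1", "count_group2"), path)
  line <- seq_len(nrow(df)) + 1L
  for (col in c("count_group1", "count_group2")) {
    v <- df[[col]]
    bad <- !is.finite(v) | v < 0 | v != floor(v)
    if (any(bad))
      stop("'", path, "' line ", line[which(bad)[1]],
           ": invalid ", col, " (", v[which(bad)[1]], ")")
  }
  bad_id <- is.na(df$gene_id) | !nzchar(df$gene_id)
  if (any(bad_id))
    stop("'", path, "' line ", line[which(bad_id)[1]], ": empty gene_id")
  dup <- duplicated(df$gene_id)
  if (any(dup))
    stop("'", path, "' line ", line[which(dup)[1]],
         ": duplicate gene_id '", df$gene_id[which(dup)[1]], "'")
  df[c("gene_id", "count_group1", "count_group2")]
}

#' Read a gene annotation table
#'
#' Tab-separated file with columns `gene_id`, `kegg_ko` (K-number or `NA`),
#' `go_terms` (semicolon-separated GO accessions or `NA`), and optionally
#' `annotation` (free-text label).
#'
#' @param path Path to the TSV file.
#' @return Validated data frame.
#' @export
read_annotations <- function(path) {
  df <- .read_table(path, sep = "\t")
  .require_cols(df, c("gene_id", "kegg_ko", "go_terms"), path)
  line <- seq_len(nrow(df)) + 1L
  dup <- duplicated(df$gene_id)
  if (any(dup))
    stop("'", path, "' line ", line[which(dup)[1]],
         ": duplicate gene_id '", df$gene_id[which(dup)[1]], "'")
  ok_k <- is.na(df$kegg_ko) | grepl("^K[0-9]{5}$", df$kegg_ko)
  if (any(!ok_k))
    stop("'", path, "' line ", line[which(!ok_k)[1]],
         ": malformed K-number '", df$kegg_ko[which(!ok_k)[1]], "'")
  ok_g <- is.na(df$go_terms) |
    vapply(df$go_terms, function(s)
      all(grepl("^GO:[0-9]{7}$", .split_terms(s))), TRUE)
  if (any(!ok_g))
    stop("'", path, "' line ", line[which(!ok_g)[1]],
         ": malformed go_terms '", df$go_terms[which(!ok_g)[1]], "'")
  df
}

#' Read an assay measurement table (CSV)
#'
#' Comma-separated file with columns `sample_id`, `substrate_acid`, `ester`,
#' `initial_acid_mM`, and `response` or `ester_mM`.
#'
#' @param path Path to the CSV file.
#' @return Validated data frame.
#' @export
read_assay <- function(path) {
  df <- .read_table(path, sep = ",")
  .require_cols(df, c("sample_id", "substrate_acid", "ester",
                      "initial_acid_mM"), path)
  if (!any(c("response", "ester_mM") %in% names(df)))
    stop("'", path, "' needs a 'response' or 'ester_mM' column")
  if (any(!is.finite(df$initial_acid_mM) | df$initial_acid_mM <= 0)) {
    bad <- which(!is.finite(df$initial_acid_mM) | df$initial_acid_mM <= 0)[1]
    stop("'", path, "' line ", bad + 1L, ": invalid initial_acid_mM")
  }
  df
}

#' Read a standard-curve dilution table (CSV)
#'
#' Columns `analyte`, `conc_mM`, `response`; replicates as repeated rows.
#'
#' @param path Path to the CSV file.
#' @return Validated data frame.
#' @export
read_standards <- function(path) {
  df <- .read_table(path, sep = ",")
  .require_cols(df, c("analyte", "conc_mM", "response"), path)
  df
}

#' Write a table as TSV (full precision, LF newlines, `NA` for missing)
#'
#' @param df Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", eol = "\n")
  invisible(path)
}

#' Run the differential-transcription screening pipeline
#'
#' Reads (or accepts) a two-condition count table and an annotation table,
#' runs the exact two-library test, screens the up-regulated genes against
#' the whitelist, and writes the DE table, candidate table, a run log and a
#' manifest of MD5 hashes to `out_dir`. Any stage failure aborts before
#' partial outputs are written.
#'
#' @param counts Path to a counts TSV or a data frame as from
#'   [read_counts()].
#' @param annotations Path to an annotation TSV or a data frame.
#' @param out_dir Output directory (created if needed).
#' @param n1,n2 Library sizes; `NULL` uses column sums of the count table.
#' @param whitelist A `"term_whitelist"` or a path to a JSON/YAML override
#'   file with keys `kegg` and `go`.
#' @param fold_threshold,alpha,pseudocount,use_fdr Passed to [ac_test()].
#' @return Invisibly, a list with `fit`, `candidates` and `files`.
#' @export
run_pipeline <- function(counts, annotations, out_dir,
                         n1 = NULL, n2 = NULL,
                         whitelist = default_whitelist(),
                         fold_threshold = 2, alpha = 0.05,
                         pseudocount = 0.5, use_fdr = TRUE) {
  counts_path <- NULL; ann_path <- NULL
  if (is.character(counts)) { counts_path <- counts; counts <- read_counts(counts) }
  if (is.character(annotations)) { ann_path <- annotations
    annotations <- read_annotations(annotations) }
  if (is.character(whitelist)) whitelist <- read_whitelist(whitelist)

  fit <- ac_test(counts, n1 = n1, n2 = n2, fold_threshold = fold_threshold,
                 alpha = alpha, pseudocount = pseudocount, use_fdr = use_fdr)
  candidates <- screen_candidates(fit, annotations, whitelist)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(de = file.path(out_dir, "de_results.tsv"),
             candidates = file.path(out_dir, "candidates.tsv"),
             log = file.path(out_dir, "run_log.txt"),
             manifest = file.path(out_dir, "manifest.tsv"))
  write_tsv(fit$table, files[["de"]])
  write_tsv(as.data.frame(unclass(candidates),
                          stringsAsFactors = FALSE), files[["candidates"]])

  log_lines <- c(
    sprintf("esterscreen %s", as.character(utils::packageVersion("esterscreen"))),
    sprintf("R %s", getRversion()),
    sprintf("counts: %s (%d genes)",
            if (is.null(counts_path)) "<data frame>" else counts_path,
            nrow(counts)),
    sprintf("annotations: %s (%d records)",
            if (is.null(ann_path)) "<data frame>" else ann_path,
            nrow(annotations)),
    sprintf("lib sizes: n1=%s n2=%s", format(fit$lib_sizes[["n1"]]),
            format(fit$lib_sizes[["n2"]])),
    sprintf("config: fold_threshold=%g alpha=%g pseudocount=%g use_fdr=%s",
            fold_threshold, alpha, pseudocount, use_fdr),
    sprintf("whitelist: %d KEGG, %d GO terms",
            length(whitelist$kegg), length(whitelist$go)),
    sprintf("DE genes: %d up, %d down; candidates: %d; unannotated up: %d",
            sum(fit$table$is_de & fit$table$direction == "up"),
            sum(fit$table$is_de & fit$table$direction == "down"),
            nrow(candidates), attr(candidates, "n_unannotated_up")))
  writeLines(log_lines, files[["log"]])

  hashed <- c(files[["de"]], files[["candidates"]], files[["log"]],
              counts_path, ann_path)
  manifest <- data.frame(file = basename(hashed),
                         md5 = unname(tools::md5sum(hashed)),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, files[["manifest"]])

  invisible(list(fit = fit, candidates = candidates, files = files))
}
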