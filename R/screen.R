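# Annotation-whitelist screen: up-regulated genes -> esterification-enzyme
# candidates, plus annotation-coverage bookkeeping.

#' Default esterase/lipase annotation whitelist
#'
#' The KEGG K-numbers and GO accessions describing lipase, esterase,
#' carboxylesterase, pectinesterase and related hydrolase/lyase activities
#' that mark a gene as a potential esterification enzyme: 13 K-numbers and 7
#' GO terms.
#'
#' @return An object of class `"term_whitelist"`: a list with character
#'   vectors `kegg` and `go`.
#' @examples
#' wl <- default_whitelist()
#' "K16815" %in% wl$kegg
#' @export
default_whitelist <- function() {
  term_whitelist(
    kegg = c("K16815", "K14788", "K01051", "K01050", "K02332", "K13333",
             "K01956", "K03927", "K14675", "K09252", "K17648", "K12389",
             "K01049"),
    go = c("GO:0016042", "GO:0016787", "GO:0016829", "GO:0080030",
           "GO:0009395", "GO:0004806", "GO:0004372"))
}

#' Construct an annotation-term whitelist
#'
#' @param kegg Character vector of KEGG K-numbers (`K` + 5 digits).
#' @param go Character vector of GO accessions (`GO:` + 7 digits).
#' @return A `"term_whitelist"` object; at least one set must be non-empty.
#' @export
term_whitelist <- function(kegg = character(), go = character()) {
  kegg <- unique(as.character(kegg)); go <- unique(as.character(go))
  if (length(kegg) == 0 && length(go) == 0)
    stop("whitelist must contain at least one term")
  if (length(kegg) && any(!grepl("^K[0-9]{5}$", kegg)))
    stop("malformed K-number(s): ",
         paste(kegg[!grepl("^K[0-9]{5}$", kegg)], collapse = ", "))
  if (length(go) && any(!grepl("^GO:[0-9]{7}$", go)))
    stop("malformed GO accession(s): ",
         paste(go[!grepl("^GO:[0-9]{7}$", go)], collapse = ", "))
  structure(list(kegg = kegg, go = go), class = "term_whitelist")
}

#' @export
print.term_whitelist <- function(x, ...) {
  cat(sprintf("Annotation whitelist: %d KEGG K-number(s), %d GO term(s)\n",
              length(x$kegg), length(x$go)))
  invisible(x)
}

#' Read a whitelist override from a JSON or YAML file
#'
#' The file must contain keys `kegg` and/or `go`, each a list of accessions.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A `"term_whitelist"` object.
#' @export
read_whitelist <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  term_whitelist(kegg = unlist(cfg$kegg), go = unlist(cfg$go))
}

# split "GO:0016787;GO:0016042" -> character vector; NA/"" -> character(0)
.split_terms <- function(s) {
  if (is.na(s) || !nzchar(s)) return(character())
  trimws(strsplit(s, ";", fixed = TRUE)[[1]])
}

#' Screen up-regulated genes for esterification-enzyme candidates
#'
#' Intersects the differential-transcription calls with an annotation table:
#' a candidate is a gene that is called differentially transcribed, is
#' up-regulated (higher normalized level in group 1), and carries at least
#' one KEGG or GO term from the whitelist. Up-regulated genes with no
#' annotation record are excluded silently and counted in the
#' `n_unannotated_up` attribute.
#'
#' @param fit An `"ac_test"` object, or a data frame with columns `gene_id`,
#'   `fold_change`, `direction`, `is_de`.
#' @param annotations Data frame with columns `gene_id`, `kegg_ko` (K-number
#'   or `"NA"`), `go_terms` (semicolon-separated GO accessions, possibly
#'   empty), and optionally `annotation` (a free-text label such as
#'   `"Lipase"`).
#' @param whitelist A `"term_whitelist"`; default [default_whitelist()].
#' @return A data frame of class `"candidate_screen"` sorted by descending
#'   fold change (ties broken by `gene_id`), with columns `gene_id`,
#'   `annotation`, `kegg`, `go`, `fold_change`, `matched_terms`.
#' @examples
#' ann <- data.frame(gene_id = "g1", kegg_ko = "K16815",
#'                   go_terms = "GO:0016042", annotation = "Lipase")
#' de <- data.frame(gene_id = "g1", fold_change = 3.21,
#'                  direction = "up", is_de = TRUE)
#' screen_candidates(de, ann)
#' @export
screen_candidates <- function(fit, annotations, whitelist = default_whitelist()) {
  tab <- if (inherits(fit, "ac_test")) fit$table else fit
  req <- c("gene_id", "fold_change", "direction", "is_de")
  if (!all(req %in% names(tab)))
    stop("'fit' must provide columns ", paste(req, collapse = ", "))
  if (!all(c("gene_id", "kegg_ko", "go_terms") %in% names(annotations)))
    stop("'annotations' must have columns gene_id, kegg_ko, go_terms")
  if (anyDuplicated(tab$gene_id)) stop("duplicate gene_id in results")
  if (anyDuplicated(annotations$gene_id)) stop("duplicate gene_id in annotations")
  if (!inherits(whitelist, "term_whitelist"))
    whitelist <- do.call(term_whitelist, whitelist)

  up <- tab[tab$is_de & tab$direction == "up", , drop = FALSE]
  idx <- match(up$gene_id, annotations$gene_id)
  n_unannotated <- sum(is.na(idx))

  keep <- !is.na(idx)
  up <- up[keep, , drop = FALSE]
  ann <- annotations[idx[keep], , drop = FALSE]

  matched <- mapply(function(k, g) {
    terms <- c(if (!is.na(k) && grepl("^K[0-9]{5}$", k)) k else character(),
               .split_terms(g))
    intersect(terms, c(whitelist$kegg, whitelist$go))
  }, as.character(ann$kegg_ko), as.character(ann$go_terms),
  SIMPLIFY = FALSE, USE.NAMES = FALSE)

  hit <- lengths(matched) > 0
  out <- data.frame(
    gene_id = up$gene_id[hit],
    annotation = if ("annotation" %in% names(ann))
      as.character(ann$annotation)[hit] else NA_character_,
    kegg = as.character(ann$kegg_ko)[hit],
    go = as.character(ann$go_terms)[hit],
    fold_change = up$fold_change[hit],
    matched_terms = unname(vapply(matched[hit], paste, "", collapse = ";")),
    stringsAsFactors = FALSE)
  out <- out[order(-out$fold_change, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unannotated_up") <- n_unannotated
  class(out) <- c("candidate_screen", "data.frame")
  out
}

#' @export
print.candidate_screen <- function(x, ...) {
  cat(sprintf("%d candidate esterification-enzyme gene(s)", nrow(x)))
  n_un <- attr(x, "n_unannotated_up")
  if (!is.null(n_un) && n_un > 0)
    cat(sprintf(" (%d up-regulated gene(s) lacked an annotation record)", n_un))
  cat("\n")
  if (nrow(x)) print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Annotation coverage summary
#'
#' Percentage of assembled unigenes annotated by each functional database,
#' rounded half-up to two decimals.
#'
#' @param annotated Named non-negative integer vector: annotated unigenes per
#'   database.
#' @param total Positive integer: total unigenes assembled.
#' @return Data frame with columns `database`, `annotated`, `total`, `pct`.
#' @examples
#' annotation_coverage(c(NR = 22396, KEGG = 15484), total = 24319)
#' @export
annotation_coverage <- function(annotated, total) {
  if (length(annotated) == 0) stop("'annotated' must be non-empty")
  if (is.null(names(annotated)) || any(!nzchar(names(annotated))))
    stop("'annotated' must be a named vector")
  if (total < 1) stop("'total' must be positive")
  if (any(annotated < 0)) stop("counts must be non-negative")
  if (any(annotated > total)) stop("annotated count exceeds total")
  data.frame(database = names(annotated),
             annotated = as.integer(annotated),
             total = as.integer(total),
             pct = round_half_up(100 * annotated / total, 2),
             row.names = NULL, stringsAsFactors = FALSE)
}
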