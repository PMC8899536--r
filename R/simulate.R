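# Synthetic two-condition count libraries with planted fold changes and
# whitelist-annotated candidate genes, plus synthetic assay tables. Every
# dataset carries its generating truth so recovery can be scored exactly.

# One global seed drives three named substreams so regenerating one phase
# (rates, counts, annotations) never perturbs the others.
.substream_seeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 3L)
  names(s) <- c("rates", "counts", "annotations")
  s
}

#' Simulate a two-condition digital gene expression experiment
#'
#' Draws per-gene baseline expression rates from a gamma distribution,
#' multiplies a planted minority of genes by fold changes, and samples one
#' Poisson count library per condition scaled so the expected totals equal
#' the target library sizes — the single-library-per-group design the exact
#' two-library test assumes. The first `planted_candidates` of the planted
#' up-regulated genes receive esterase/lipase whitelist annotations; a
#' fraction of null genes receive decoy whitelist terms; all other genes get
#' off-whitelist annotations (a small fraction get no record at all).
#'
#' @param n_genes Number of genes (default 24319, a typical de-novo
#'   assembly size for a filamentous fungus).
#' @param n1,n2 Target library sizes (expected total counts; default 2e6).
#' @param baseline_mean Mean of the gamma baseline rate (scale is arbitrary:
#'   only relative rates matter; default 1).
#' @param baseline_dispersion Gamma shape; smaller = more skewed expression
#'   (default 0.7, a realistic transcriptome-wide skew).
#' @param de_fraction Fraction of genes with a planted fold change
#'   (default 0.05).
#' @param fold_min,fold_max Planted folds are drawn uniformly in
#'   `[fold_min, fold_max]` (defaults 4 and 16).
#' @param whitelist_fraction Fraction of null genes given decoy whitelist
#'   terms (default 0.01).
#' @param planted_candidates Number of planted up-regulated genes that carry
#'   whitelist terms (default 23); must not exceed the number of planted
#'   up-regulated genes.
#' @param planted_min_mean Floor on a planted candidate's expected baseline
#'   count (default 50) so planted signal is detectable at the simulated
#'   depth.
#' @param unannotated_fraction Fraction of non-candidate genes lacking an
#'   annotation record entirely (default 0.05).
#' @param overdispersion If > 0, counts are drawn negative-binomially with
#'   this dispersion (variance `mu + overdispersion * mu^2`) instead of
#'   Poisson, to probe the test's behaviour when its model is violated.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A list with `counts` (gene_id, count_group1, count_group2),
#'   `annotations` (gene_id, annotation, kegg_ko, go_terms), `lib_sizes`
#'   (realized column sums, named n1/n2), `target_lib_sizes`, and `truth`
#'   (gene_id, true_fold, is_planted_de, is_planted_candidate,
#'   has_whitelist_term, expected_x, expected_y).
#' @examples
#' sim <- simulate_counts(n_genes = 500, n1 = 1e5, n2 = 1e5, seed = 1)
#' head(sim$truth)
#' @export
simulate_counts <- function(n_genes = 24319, n1 = 2e6, n2 = 2e6,
                            baseline_mean = 1, baseline_dispersion = 0.7,
                            de_fraction = 0.05, fold_min = 4, fold_max = 16,
                            whitelist_fraction = 0.01, planted_candidates = 23,
                            planted_min_mean = 50,
                            unannotated_fraction = 0.05,
                            overdispersion = 0, seed = 1) {
  if (n_genes < 1 || n1 < 1 || n2 < 1) stop("sizes must be positive")
  if (de_fraction < 0 || de_fraction >= 1) stop("'de_fraction' must lie in [0, 1)")
  if (fold_min <= 1 || fold_max < fold_min) stop("need 1 < fold_min <= fold_max")
  if (whitelist_fraction < 0 || whitelist_fraction > 1)
    stop("'whitelist_fraction' must lie in [0, 1]")
  n_de <- round(de_fraction * n_genes)
  if (planted_candidates > n_de)
    stop("'planted_candidates' exceeds the number of planted DE genes")
  ss <- .substream_seeds(seed)

  gene_id <- sprintf("g%05d", seq_len(n_genes))

  ## -- rates substream: baselines, DE gene choice, folds ---------------------
  set.seed(ss[["rates"]])
  base <- stats::rgamma(n_genes, shape = baseline_dispersion,
                        rate = baseline_dispersion / baseline_mean)
  base <- pmax(base, 1e-8 * baseline_mean)
  de_idx <- if (n_de > 0) sample.int(n_genes, n_de) else integer()
  cand_idx <- de_idx[seq_len(planted_candidates)]
  # planted candidates are up-regulated; remaining DE genes go either way
  fold <- rep(1, n_genes)
  if (n_de > 0) {
    f <- stats::runif(n_de, fold_min, fold_max)
    dir_up <- c(rep(TRUE, planted_candidates),
                stats::runif(n_de - planted_candidates) < 0.5)
    fold[de_idx] <- ifelse(dir_up, f, 1 / f)
  }
  # floor planted-candidate baselines so expected group-2 counts stay
  # detectable (~ planted_min_mean reads) at the target depth
  if (length(cand_idx)) {
    floor_rate <- planted_min_mean * n_genes * baseline_mean / min(n1, n2)
    base[cand_idx] <- pmax(base[cand_idx], floor_rate)
  }

  rate1 <- base * fold           # group 1 carries the planted fold
  rate2 <- base
  mu_x <- rate1 * n1 / sum(rate1)
  mu_y <- rate2 * n2 / sum(rate2)

  ## -- counts substream ------------------------------------------------------
  set.seed(ss[["counts"]])
  if (overdispersion > 0) {
    x <- stats::rnbinom(n_genes, mu = mu_x, size = 1 / overdispersion)
    y <- stats::rnbinom(n_genes, mu = mu_y, size = 1 / overdispersion)
  } else {
    x <- stats::rpois(n_genes, mu_x)
    y <- stats::rpois(n_genes, mu_y)
  }

  ## -- annotations substream -------------------------------------------------
  set.seed(ss[["annotations"]])
  wl <- default_whitelist()
  null_idx <- setdiff(seq_len(n_genes), de_idx)
  n_decoy <- round(whitelist_fraction * length(null_idx))
  decoy_idx <- if (n_decoy > 0) sample(null_idx, n_decoy) else integer()
  wl_idx <- c(cand_idx, decoy_idx)

  kegg <- sprintf("K%05d", sample(20000:99999, n_genes, replace = TRUE))
  go <- sprintf("GO:%07d", sample(1e6:5e6, n_genes, replace = TRUE))
  label <- rep("Hypothetical protein", n_genes)
  if (length(wl_idx)) {
    kegg[wl_idx] <- sample(wl$kegg, length(wl_idx), replace = TRUE)
    go[wl_idx] <- sample(wl$go, length(wl_idx), replace = TRUE)
    label[wl_idx] <- sample(c("Lipase", "Esterase", "Carboxylesterase"),
                            length(wl_idx), replace = TRUE)
  }
  annotations <- data.frame(gene_id = gene_id, annotation = label,
                            kegg_ko = kegg, go_terms = go,
                            stringsAsFactors = FALSE)
  # drop some non-candidate annotation records entirely
  droppable <- setdiff(seq_len(n_genes), wl_idx)
  n_drop <- round(unannotated_fraction * length(droppable))
  if (n_drop > 0)
    annotations <- annotations[-sample(droppable, n_drop), , drop = FALSE]

  counts <- data.frame(gene_id = gene_id, count_group1 = x, count_group2 = y,
                       stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = gene_id, true_fold = fold,
                      is_planted_de = seq_len(n_genes) %in% de_idx,
                      is_planted_candidate = seq_len(n_genes) %in% cand_idx,
                      has_whitelist_term = seq_len(n_genes) %in% wl_idx,
                      expected_x = mu_x, expected_y = mu_y,
                      stringsAsFactors = FALSE)
  list(counts = counts, annotations = annotations,
       lib_sizes = c(n1 = sum(x), n2 = sum(y)),
       target_lib_sizes = c(n1 = n1, n2 = n2),
       truth = truth)
}

#' Simulate esterification assay tables
#'
#' Emits, for each ester, a serial-dilution standard table under a known
#' linear detector response and a measurement table whose responses encode
#' known true conversion ratios, optionally with Gaussian detector noise.
#' With `noise_sd = 0` the assay pipeline recovers the generating
#' conversions exactly.
#'
#' @param true_conversion_pct Named vector of generating conversion
#'   percentages in `[0, 100]`, one per ester. Defaults emulate a four-ester
#'   panel (ethyl valerate, caproate, caprylate, caprate) after culture
#'   optimization.
#' @param initial_acid_mM Initially supplied acid concentration (default 10).
#' @param dilutions Standard concentrations in mM.
#' @param replicates Replicates per standard point (default 3).
#' @param noise_sd Gaussian response noise standard deviation (default 0).
#' @param seed Integer seed.
#' @return List with `standards` (analyte, conc_mM, response),
#'   `measurements` (sample_id, substrate_acid, ester, initial_acid_mM,
#'   response), and `truth` (ester, true_conversion_pct, slope, intercept).
#' @export
simulate_assay <- function(true_conversion_pct = c(ethyl_valerate = 7.87,
                                                   ethyl_caproate = 29.20,
                                                   ethyl_caprylate = 94.80,
                                                   ethyl_caprate = 85.20),
                           initial_acid_mM = 10,
                           dilutions = c(0.5, 1, 2, 5, 10),
                           replicates = 3, noise_sd = 0, seed = 1) {
  if (any(true_conversion_pct < 0 | true_conversion_pct > 100))
    stop("'true_conversion_pct' must lie in [0, 100]")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  if (is.null(names(true_conversion_pct)))
    stop("'true_conversion_pct' must be named by ester")
  set.seed(seed)
  esters <- names(true_conversion_pct)
  acids <- sub("^ethyl_", "", esters)
  slope <- stats::runif(length(esters), 0.8, 1.6)
  intercept <- stats::runif(length(esters), -0.05, 0.05)

  standards <- do.call(rbind, lapply(seq_along(esters), function(i) {
    conc <- rep(dilutions, each = replicates)
    data.frame(analyte = esters[i], conc_mM = conc,
               response = slope[i] * conc + intercept[i] +
                 stats::rnorm(length(conc), 0, noise_sd),
               stringsAsFactors = FALSE)
  }))
  true_ester <- true_conversion_pct / 100 * initial_acid_mM
  measurements <- data.frame(
    sample_id = paste0("S", seq_along(esters)),
    substrate_acid = paste0(acids, "_acid"),
    ester = esters,
    initial_acid_mM = initial_acid_mM,
    response = slope * true_ester + intercept +
      stats::rnorm(length(esters), 0, noise_sd),
    stringsAsFactors = FALSE)
  truth <- data.frame(ester = esters,
                      true_conversion_pct = unname(true_conversion_pct),
                      slope = slope, intercept = intercept,
                      stringsAsFactors = FALSE)
  list(standards = standards, measurements = measurements, truth = truth)
}

#' Score differential-transcription and screening calls against the truth
#'
#' @param results An `"ac_test"` object or its table (columns `gene_id`,
#'   `p_two_sided`, `is_de`).
#' @param truth The `truth` component of [simulate_counts()].
#' @param candidates Optional [screen_candidates()] output; when given,
#'   sensitivity and precision are scored against the planted
#'   whitelist-annotated DE genes.
#' @param alpha Level for the raw-p type-I rate (default 0.05).
#' @return List with `type_i_raw` (fraction of true nulls with
#'   `p < alpha`), `type_i` (fraction of true nulls called DE), `power`
#'   (fraction of planted DE genes called DE), and — with `candidates` —
#'   `sensitivity` and `precision` of the candidate list.
#' @export
estimate_error_rates <- function(results, truth, candidates = NULL,
                                 alpha = 0.05) {
  tab <- if (inherits(results, "ac_test")) results$table else results
  if (!setequal(tab$gene_id, truth$gene_id))
    stop("results and truth cover different gene sets")
  tab <- tab[match(truth$gene_id, tab$gene_id), , drop = FALSE]
  null <- !truth$is_planted_de
  out <- list(
    type_i_raw = if (any(null)) mean(tab$p_two_sided[null] < alpha) else NA_real_,
    type_i = if (any(null)) mean(tab$is_de[null]) else NA_real_,
    power = if (any(!null)) mean(tab$is_de[!null]) else NA_real_)
  if (!is.null(candidates)) {
    planted <- truth$gene_id[truth$is_planted_candidate]
    called <- candidates$gene_id
    out$sensitivity <- if (length(planted)) mean(planted %in% called) else NA_real_
    out$precision <- if (length(called)) mean(called %in% planted) else NA_real_
  }
  out
}
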