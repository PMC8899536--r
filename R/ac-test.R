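# Exact two-library digital gene expression test.
#
# For a gene with x reads among N1 in library 1, the count y among N2 in
# library 2 has, conditionally, the distribution
#   p(y|x) = (N2/N1)^y * (x+y)! / (x! y!) * (1 + N2/N1)^-(x+y+1),
# i.e. a negative binomial with size x+1 and success probability N1/(N1+N2).
# All mass functions are evaluated in log space via lgamma so that counts up
# to ~1e7 neither overflow nor underflow.

#' Poisson probability mass function
#'
#' Mass function of the Poisson law that models a gene's read count in a
#' single deeply sequenced library: each gene captures a small fraction of a
#' large number of reads, so the count is Poisson with rate `lambda`, the
#' expected transcript copy number.
#'
#' @param x Non-negative integer count (vectorized).
#' @param lambda Non-negative Poisson rate.
#' @return `P(X = x)`, computed in log space.
#' @examples
#' poisson_pmf(3, 2)   # e^-2 * 8/6
#' @export
poisson_pmf <- function(x, lambda) {
  if (any(x < 0)) stop("'x' must be non-negative")
  if (any(lambda < 0)) stop("'lambda' must be non-negative")
  if (any(x != floor(x))) stop("'x' must be integer-valued")
  out <- numeric(length(x))
  zero <- lambda == 0
  if (any(zero)) out[zero] <- as.numeric(x[zero] == 0)
  if (any(!zero)) {
    xi <- x[!zero]
    li <- if (length(lambda) > 1) lambda[!zero] else lambda
    out[!zero] <- exp(-li + xi * log(li) - lgamma(xi + 1))
  }
  out
}

.check_pair <- function(x, y, n1, n2) {
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (any(x != floor(x)) || any(y != floor(y))) stop("counts must be integers")
  if (n1 < 1 || n2 < 1) stop("library sizes must be positive")
  if (any(x > n1) || any(y > n2)) stop("a count cannot exceed its library size")
  invisible(TRUE)
}

# log p(i|x) for a vector of i at fixed x and ratio r = n2/n1
.ac_lpmf <- function(i, x, r) {
  i * log(r) + lgamma(x + i + 1) - lgamma(x + 1) - lgamma(i + 1) -
    (x + i + 1) * log1p(r)
}

#' Conditional probability of the second-library count
#'
#' Probability mass `p(y | x)` of observing `y` reads for a gene in library 2
#' (total size `n2`) given `x` reads in library 1 (total size `n1`), under the
#' Poisson model with a common per-copy sequencing rate. Evaluated in log
#' space; safe for `x + y` up to 1e7.
#'
#' @param x,y Non-negative integer read counts in libraries 1 and 2
#'   (vectorized together).
#' @param n1,n2 Positive total library sizes (uniquely aligned reads).
#' @return `p(y|x)` in `(0, 1]`.
#' @examples
#' ac_pmf(5, 5, 1e6, 1e6)          # 252/2048
#' ac_pmf(2, 3, 100, 200)          # 80/729
#' @export
ac_pmf <- function(x, y, n1, n2) {
  .check_pair(x, y, n1, n2)
  exp(.ac_lpmf(y, x, n2 / n1))
}

#' Lower cumulative of the conditional count distribution
#'
#' `sum_{i=0..y} p(i|x)`: the probability that library 2 shows `y` or fewer
#' reads for the gene, given `x` reads in library 1.
#'
#' @inheritParams ac_pmf
#' @return Cumulative probability in `(0, 1)`; strictly increasing in `y`.
#' @examples
#' ac_cumulative(10, 0, 1e6, 1e6)  # 1/2048
#' @export
ac_cumulative <- function(x, y, n1, n2) {
  .check_pair(x, y, n1, n2)
  r <- n2 / n1
  mapply(function(xi, yi) {
    lp <- .ac_lpmf(0:yi, xi, r)
    m <- max(lp)
    exp(m + log(sum(exp(lp - m))))
  }, x, y)
}

# Upper tail sum_{i >= from} p(i|x), summed adaptively in chunks past the
# distribution's mean r*(x+1).
.ac_upper <- function(x, y_from, r, chunk = 512L, rel_tol = 1e-16) {
  total <- 0
  i0 <- y_from
  mean_i <- r * (x + 1)
  repeat {
    i <- i0:(i0 + chunk - 1L)
    lp <- .ac_lpmf(i, x, r)
    m <- max(lp)
    total <- total + exp(m + log(sum(exp(lp - m))))
    i0 <- i0 + chunk
    if (i0 > mean_i && exp(lp[chunk]) <= rel_tol * max(total, .Machine$double.xmin))
      break
  }
  total
}

#' Two-sided doubling p-value of the exact two-library test
#'
#' With `s = ac_cumulative(x, y, n1, n2)`, returns `2s` when `s <= 0.5` and
#' `2(1-s)` otherwise, clamped to `(0, 1]`. The upper branch is evaluated by
#' direct summation of the upper tail (not as `1 - s`) so small p-values keep
#' full relative accuracy. At the branch boundary `s = 0.5` — attained exactly
#' for `x = y` with equal library sizes — the value is exactly 1.
#'
#' @inheritParams ac_pmf
#' @return Two-sided p-value in `(0, 1]` (vectorized over `x`, `y`).
#' @examples
#' ac_two_sided_p(10, 0, 1e6, 1e6)   # 2/2048
#' ac_two_sided_p(7, 7, 1e6, 1e6)    # 1
#' @export
ac_two_sided_p <- function(x, y, n1, n2) {
  .check_pair(x, y, n1, n2)
  r <- n2 / n1
  p <- mapply(function(xi, yi) {
    lp <- .ac_lpmf(0:yi, xi, r)
    m <- max(lp)
    s <- exp(m + log(sum(exp(lp - m))))
    if (s <= 0.5) 2 * s else 2 * .ac_upper(xi, yi + 1L, r)
  }, x, y)
  p[p > 1 - 1e-12] <- 1
  pmax(pmin(p, 1), .Machine$double.xmin)
}

#' Library-size-normalized fold change
#'
#' Ratio of normalized transcription levels, `((x+c)/n1) / ((y+c)/n2)`. The
#' pseudocount `c` is applied only when either raw count is zero, so ratios of
#' strictly positive counts are exact.
#'
#' @inheritParams ac_pmf
#' @param pseudocount Non-negative value added to both counts when either is
#'   zero (default 0.5). With `pseudocount = 0` a zero count is an error.
#' @return Positive fold change (> 1 means higher normalized level in
#'   library 1).
#' @examples
#' fold_change(30, 10, 1000, 1000)        # 3
#' fold_change(0, 10, 1000, 1000)         # 0.5/10.5
#' @export
fold_change <- function(x, y, n1, n2, pseudocount = 0.5) {
  .check_pair(x, y, n1, n2)
  if (pseudocount < 0) stop("'pseudocount' must be non-negative")
  pc <- ifelse(pmin(x, y) == 0, pseudocount, 0)
  if (any(pc == 0 & pmin(x, y) == 0))
    stop("zero count with zero pseudocount: fold change undefined")
  ((x + pc) / n1) / ((y + pc) / n2)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment (wraps
#' [stats::p.adjust()] with `method = "BH"`); input order is preserved.
#'
#' @param p Non-empty vector of p-values in `(0, 1]`.
#' @return Adjusted p-values in `(0, 1]`, same order as the input.
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0) stop("'p' must be non-empty")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Exact two-library differential transcription test
#'
#' Fits the exact Poisson-conditional test to every gene of a two-condition
#' count table: the two-sided doubling p-value of `p(y|x)`, the
#' library-size-normalized fold change, BH-adjusted FDR, and the
#' differential-transcription call. A gene is called differentially
#' transcribed when its normalized level differs by strictly more than
#' `fold_threshold`-fold between the conditions and (by default) its FDR is at
#' most `alpha`; `alpha = 1` gives the pure fold-change rule.
#'
#' @param counts Data frame with columns `gene_id`, `count_group1`,
#'   `count_group2`. Group 1 is the condition of interest (e.g. the optimized
#'   culture); "up" means a higher normalized level in group 1.
#' @param n1,n2 Total uniquely aligned reads per library. `NULL` (default)
#'   uses the column sums of `counts`.
#' @param fold_threshold Strict fold-change cutoff (> 1), default 2:
#'   "more than twofold" excludes a ratio of exactly 2.
#' @param alpha Significance level in `(0, 1]`, default 0.05.
#' @param pseudocount Passed to [fold_change()], default 0.5.
#' @param use_fdr Apply `alpha` to the BH FDR (default) rather than to the raw
#'   p-value.
#' @return An object of class `"ac_test"`: a list with `table` (one row per
#'   gene: `gene_id`, `x`, `y`, `fold_change`, `p_two_sided`, `fdr`,
#'   `direction`, `is_de`), `lib_sizes`, `config`, and `call`.
#' @seealso [screen_candidates()] to filter the up-regulated genes by an
#'   annotation whitelist.
#' @examples
#' cts <- data.frame(gene_id = c("g1", "g2", "g3"),
#'                   count_group1 = c(300, 52, 12),
#'                   count_group2 = c(60, 48, 11))
#' fit <- ac_test(cts, n1 = 1e6, n2 = 1e6)
#' summary(fit)
#' @export
ac_test <- function(counts, n1 = NULL, n2 = NULL, fold_threshold = 2,
                    alpha = 0.05, pseudocount = 0.5, use_fdr = TRUE) {
  req <- c("gene_id", "count_group1", "count_group2")
  if (!is.data.frame(counts) || !all(req %in% names(counts)))
    stop("'counts' must be a data frame with columns ",
         paste(req, collapse = ", "))
  if (nrow(counts) == 0) stop("'counts' has no rows")
  if (anyDuplicated(counts$gene_id))
    stop("duplicate gene_id: ",
         paste(unique(counts$gene_id[duplicated(counts$gene_id)]), collapse = ", "))
  if (fold_threshold <= 1) stop("'fold_threshold' must exceed 1")
  if (alpha <= 0 || alpha > 1) stop("'alpha' must lie in (0, 1]")

  x <- counts$count_group1
  y <- counts$count_group2
  if (is.null(n1)) n1 <- sum(x)
  if (is.null(n2)) n2 <- sum(y)
  .check_pair(x, y, n1, n2)

  p <- ac_two_sided_p(x, y, n1, n2)
  fdr <- benjamini_hochberg(p)
  fc <- fold_change(x, y, n1, n2, pseudocount)
  direction <- ifelse(fc > 1, "up", ifelse(fc < 1, "down", "none"))
  sig <- if (use_fdr) fdr <= alpha else p <= alpha
  is_de <- (fc > fold_threshold | fc < 1 / fold_threshold) & sig

  tab <- data.frame(gene_id = as.character(counts$gene_id),
                    x = x, y = y, fold_change = fc, p_two_sided = p,
                    fdr = fdr, direction = direction, is_de = is_de,
                    stringsAsFactors = FALSE)
  structure(list(table = tab,
                 lib_sizes = c(n1 = n1, n2 = n2),
                 config = list(fold_threshold = fold_threshold, alpha = alpha,
                               pseudocount = pseudocount, use_fdr = use_fdr),
                 call = match.call()),
            class = "ac_test")
}

#' @export
print.ac_test <- function(x, ...) {
  tab <- x$table
  cat("Exact two-library differential transcription test\n")
  cat(sprintf("  %d genes; library sizes N1 = %s, N2 = %s\n",
              nrow(tab), format(x$lib_sizes[["n1"]], big.mark = ","),
              format(x$lib_sizes[["n2"]], big.mark = ",")))
  cat(sprintf("  DE (fold > %g, %s <= %g): %d up, %d down\n",
              x$config$fold_threshold,
              if (x$config$use_fdr) "FDR" else "p", x$config$alpha,
              sum(tab$is_de & tab$direction == "up"),
              sum(tab$is_de & tab$direction == "down")))
  invisible(x)
}

#' @export
summary.ac_test <- function(object, ...) {
  tab <- object$table
  out <- list(n_genes = nrow(tab),
              lib_sizes = object$lib_sizes,
              config = object$config,
              n_up = sum(tab$is_de & tab$direction == "up"),
              n_down = sum(tab$is_de & tab$direction == "down"),
              top = utils::head(tab[order(tab$p_two_sided,
                                          -abs(log(tab$fold_change))), ], 10))
  class(out) <- "summary.ac_test"
  out
}

#' @export
print.summary.ac_test <- function(x, ...) {
  cat(sprintf("%d genes tested (N1 = %s, N2 = %s): %d up-, %d down-regulated\n",
              x$n_genes, format(x$lib_sizes[["n1"]], big.mark = ","),
              format(x$lib_sizes[["n2"]], big.mark = ","), x$n_up, x$n_down))
  cat("Top genes by p-value:\n")
  print(x$top, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.ac_test <- function(x, ...) x$table

#' MA-style plot of a two-library test
#'
#' Mean normalized level (log10) against log2 fold change, with
#' differentially transcribed genes highlighted.
#'
#' @param x An `"ac_test"` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ac_test <- function(x, ...) {
  tab <- x$table
  n1 <- x$lib_sizes[["n1"]]; n2 <- x$lib_sizes[["n2"]]
  a <- log10(((tab$x + 0.5) / n1 + (tab$y + 0.5) / n2) / 2)
  m <- log2(tab$fold_change)
  graphics::plot(a, m, pch = 20, cex = 0.4,
                 col = ifelse(tab$is_de, "firebrick", "grey50"),
                 xlab = "log10 mean normalized level",
                 ylab = "log2 fold change (group 1 / group 2)", ...)
  graphics::abline(h = c(-1, 0, 1) * log2(x$config$fold_threshold),
                   lty = c(2, 1, 2), col = "grey30")
  invisible(x)
}
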