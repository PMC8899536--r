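# Shared fixtures, built in code.

make_counts <- function(x, y, ids = sprintf("g%03d", seq_along(x))) {
  data.frame(gene_id = ids, count_group1 = x, count_group2 = y,
             stringsAsFactors = FALSE)
}

make_annotations <- function(ids, kegg = NA_character_, go = NA_character_,
                             label = "Lipase") {
  data.frame(gene_id = ids, annotation = label, kegg_ko = kegg,
             go_terms = go, stringsAsFactors = FALSE)
}

# independent reference for the conditional law: p(y|x) is negative binomial
# with size x+1 and success probability n1/(n1+n2)
nb_pmf <- function(x, y, n1, n2) dnbinom(y, size = x + 1, prob = n1 / (n1 + n2))
nb_cdf <- function(x, y, n1, n2) pnbinom(y, size = x + 1, prob = n1 / (n1 + n2))

# independent step-up BH oracle (re-derived, not via p.adjust)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}
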