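#' GO-term over-representation by Fisher's exact test
#'
#' For every annotation term, tests whether the foreground protein set is
#' enriched for the term relative to a background of all unique leading
#' razor proteins, using the one-sided hypergeometric upper tail
#' P[X >= k] (the over-representation side of Fisher's exact test).
#' The enrichment factor is (k/n) / (K/N). A term is called significant when
#' p <= `p_cutoff` and at least `min_proteins` foreground proteins carry it;
#' no multiple-testing correction is applied on top of this rule.
#'
#' @param foreground Character vector of foreground protein ids (must be a
#'   subset of the background).
#' @param background Character vector of background protein ids.
#' @param annotations Data frame with columns `protein`, `term`.
#' @param p_cutoff Significance cutoff on the Fisher p (default 0.01).
#' @param min_proteins Minimum foreground proteins with the term (default 3).
#' @return Data frame sorted by p: term, k, n, K, N, enrichment_factor, p,
#'   significant.
#' @export
fisher_enrichment <- function(foreground, background, annotations,
                              p_cutoff = 0.01, min_proteins = 3L) {
  foreground <- unique(foreground)
  background <- unique(background)
  if (length(background) == 0) stop("background is empty")
  outside <- setdiff(foreground, background)
  if (length(outside) > 0)
    stop("foreground proteins absent from background: ",
         paste(outside, collapse = ", "))
  ann <- annotations[annotations$protein %in% background, , drop = FALSE]
  ann <- unique(ann[, c("protein", "term")])
  n <- length(foreground)
  N <- length(background)
  terms <- unique(ann$term)
  rows <- lapply(terms, function(tm) {
    carriers <- ann$protein[ann$term == tm]
    K <- length(carriers)
    k <- sum(foreground %in% carriers)
    # upper-tail hypergeometric: P[X >= k] drawing n from K carriers / N
    p <- if (k == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, n = n, K = K, N = N,
               enrichment_factor = (k / n) / (K / N), p = p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(),
                      enrichment_factor = numeric(), p = numeric())
  out$significant <- out$p <= p_cutoff & out$k >= min_proteins
  out <- out[order(out$p, -out$enrichment_factor), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bin protein-protein interaction edges by combined score
#'
#' Drops edges below the score threshold and assigns the remaining edges to
#' the confidence bins used for STRING combined scores: [150, 400) low,
#' [400, 700) medium, [700, 900] high, (900, 1000] very_high. The
#' half-open convention at the touching bin edges is this package's; the
#' bins partition [threshold, 1000] so every retained edge gets exactly one.
#'
#' @param edges Data frame with columns `protein_a`, `protein_b`,
#'   `combined_score` (integer 0-1000).
#' @param threshold Minimum combined score retained (default 150).
#' @return `edges` filtered, with a `bin` factor column.
#' @export
bin_ppi <- function(edges, threshold = 150) {
  stopifnot(all(edges$combined_score >= 0 & edges$combined_score <= 1000))
  out <- edges[edges$combined_score >= threshold, , drop = FALSE]
  s <- out$combined_score
  bin <- ifelse(s < 400, "low",
         ifelse(s < 700, "medium",
         ifelse(s <= 900, "high", "very_high")))
  out$bin <- factor(bin, levels = c("low", "medium", "high", "very_high"))
  rownames(out) <- NULL
  out
}
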