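# Simplified differential-expression stage: median-of-ratios normalization,
# per-gene Welch t-tests on log2(normalized + 1), Benjamini-Hochberg FDR,
# fold-change + FDR filtering, and the log-space hypergeometric
# signature-overlap test.

#' Median-of-ratios count normalization
#'
#' Size factor per sample = median over reference genes of the ratio of the
#' sample's count to the gene's geometric mean across samples; reference
#' genes are those with all-positive counts. Factors are rescaled to
#' geometric mean 1 and each sample's counts divided by its factor.
#'
#' @param expr raw-count [expression_matrix()], at least 2 samples.
#' @return a `normalized`-flavor [expression_matrix()] with attribute
#'   `size_factors`.
#' @export
normalize_counts <- function(expr) {
  if (expr_flavor(expr) != "raw_counts") stop_sf("normalize_counts expects raw counts")
  if (ncol(expr) < 2L) stop_sf("need >= 2 samples")
  m <- unclass(expr)
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref)) {
    stop_sf(paste("no gene has all-positive counts; supply a filtered matrix",
                  "or use a pseudo-reference upstream"))
  }
  log_geo <- rowMeans(log(m[ref, , drop = FALSE]))
  sf <- apply(m[ref, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - log_geo))
  })
  sf <- sf / exp(mean(log(sf)))
  out <- sweep(m, 2, sf, "/")
  res <- expression_matrix(out, "normalized")
  attr(res, "size_factors") <- sf
  sf_log("normalize", "size factors: ",
         paste(sprintf("%.3f", sf[seq_len(min(5, length(sf)))]), collapse = " "))
  res
}

#' Log2 transform of a normalized matrix
#'
#' `log2(x + 1)` with the pseudocount applied only at this step (never in
#' size-factor estimation).
#'
#' @param expr a `normalized` (or `raw_counts`) [expression_matrix()].
#' @return a `log_normalized` [expression_matrix()].
#' @export
log_transform <- function(expr) {
  if (!expr_flavor(expr) %in% c("normalized", "raw_counts")) {
    stop_sf("log_transform expects normalized or raw counts")
  }
  expression_matrix(log2(unclass(expr) + 1), "log_normalized")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control with monotonicity enforcement, input order preserved.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues) || anyNA(pvalues)) stop_sf("p-values must be numeric, no NA")
  if (any(pvalues < 0 | pvalues > 1)) stop_sf("p-values outside [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Two-group differential expression with fold-change and FDR filters
#'
#' Per-gene Welch t-test on `log2(normalized + 1)`; `log2_fold_change` is
#' mean(log2 group B) - mean(log2 group A). Direction is `up` iff
#' `log2_fold_change > log2(fc_thresh)` and `fdr_q < fdr_thresh` (strict
#' inequalities), symmetric for `down`, otherwise `ns`. Genes with zero
#' variance in both groups get p = 1 with a logged warning count.
#'
#' @param expr a `normalized` [expression_matrix()] (raw counts are
#'   normalized first).
#' @param group_labels factor/character per sample with exactly 2 levels;
#'   the comparison is level 2 ("B") versus level 1 ("A"), levels in sort
#'   order unless a factor is supplied.
#' @param fc_thresh linear fold-change threshold (default 1.5).
#' @param fdr_thresh FDR threshold (default 0.05).
#' @return a `deg_table` data.frame: gene, log2_fold_change, raw_p, fdr_q,
#'   direction.
#' @export
differential_expression <- function(expr, group_labels, fc_thresh = 1.5,
                                    fdr_thresh = 0.05) {
  if (expr_flavor(expr) == "raw_counts") expr <- normalize_counts(expr)
  if (expr_flavor(expr) != "normalized") stop_sf("expected normalized expression")
  if (length(group_labels) != ncol(expr)) stop_sf("one group label per sample required")
  f <- if (is.factor(group_labels)) droplevels(group_labels) else factor(group_labels)
  if (nlevels(f) != 2L) stop_sf("exactly two groups required")
  a <- unclass(expr)[, f == levels(f)[1], drop = FALSE]
  b <- unclass(expr)[, f == levels(f)[2], drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L) stop_sf("each group needs n >= 2")
  la <- log2(a + 1); lb <- log2(b + 1)
  na <- ncol(la); nb <- ncol(lb)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- rowSums((la - ma)^2) / (na - 1)
  vb <- rowSums((lb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    p[degenerate] <- 1
    sf_log("de", sum(degenerate), " gene(s) with zero variance in both groups; p set to 1")
  }
  q <- bh_adjust(p)
  l2fc <- mb - ma
  dir <- rep("ns", nrow(expr))
  dir[l2fc > log2(fc_thresh) & q < fdr_thresh] <- "up"
  dir[l2fc < -log2(fc_thresh) & q < fdr_thresh] <- "down"
  structure(data.frame(gene = rownames(expr), log2_fold_change = l2fc,
                       raw_p = p, fdr_q = q, direction = dir,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("deg_table", "data.frame"),
            contrast = paste(levels(f)[2], "vs", levels(f)[1]))
}

#' Hypergeometric overlap of two gene signatures
#'
#' Upper-tail p-value `P(X >= k)` for `X ~ Hypergeom(N, |A|, |B|)` with
#' `k = |A intersect B|`, computed in log space so that p-values near
#' 1e-300 remain representable.
#'
#' @param list_a,list_b character vectors of gene IDs (deduplicated).
#' @param background_n size of the gene universe; must be at least
#'   `max(|A|, |B|)`. Recommended: the number of genes tested for
#'   differential expression.
#' @return an `overlap_result` list: `overlap_genes`, `k`, `n_a`, `n_b`,
#'   `background_n`, `p`, `log10_p`.
#' @export
overlap_signatures <- function(list_a, list_b, background_n) {
  a <- unique(as.character(list_a)); b <- unique(as.character(list_b))
  if (background_n < max(length(a), length(b))) {
    stop_sf("background_n (%d) smaller than a signature (%d, %d)",
            background_n, length(a), length(b))
  }
  k <- length(intersect(a, b))
  log_p <- if (k == 0) 0 else {
    stats::phyper(k - 1, length(a), background_n - length(a), length(b),
                  lower.tail = FALSE, log.p = TRUE)
  }
  structure(list(overlap_genes = sort(intersect(a, b)), k = k,
                 n_a = length(a), n_b = length(b),
                 background_n = background_n,
                 p = exp(log_p), log10_p = log_p / log(10)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap: k = %d of |A| = %d, |B| = %d (N = %d); p = %.3g (log10 p = %.1f)\n",
              x$k, x$n_a, x$n_b, x$background_n, x$p, x$log10_p))
  invisible(x)
}

#' Significant genes from a DEG table
#' @param deg a `deg_table`.
#' @param direction "up", "down" or "both".
#' @return character vector of gene IDs.
#' @export
deg_genes <- function(deg, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  keep <- if (direction == "both") deg$direction != "ns" else deg$direction == direction
  deg$gene[keep]
}
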