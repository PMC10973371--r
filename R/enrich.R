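# Enrichment statistics: hypergeometric over-representation analysis (ORA)
# sharing the log-space kernel with the signature-overlap test, and a
# preranked weighted Kolmogorov-Smirnov enrichment statistic with a
# gene-label permutation null (the correct null for preranked input).

#' Over-representation analysis
#'
#' Upper-tail hypergeometric p per gene set (each set intersected with the
#' background first), Benjamini-Hochberg q across sets.
#'
#' @param query_genes character vector (e.g. a module or DEG list); must be
#'   a subset of `background`.
#' @param collection a `geneset_collection`.
#' @param background character vector: the gene universe.
#' @return data.frame: set, set_size, overlap_k, p, q, sorted by p.
#' @export
ora <- function(query_genes, collection, background) {
  query <- unique(as.character(query_genes))
  background <- unique(as.character(background))
  if (!length(query)) stop_sf("empty query")
  if (!length(background)) stop_sf("empty background")
  bad <- setdiff(query, background)
  if (length(bad)) stop_sf("query gene(s) outside background: %s",
                           paste(utils::head(bad, 3), collapse = ", "))
  rows <- lapply(names(collection), function(nm) {
    members <- intersect(collection[[nm]]$genes, background)
    k <- length(intersect(query, members))
    res <- overlap_signatures(query, members, length(background))
    data.frame(set = nm, set_size = length(members), overlap_k = k,
               p = res$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out[order(out$p, out$set), , drop = FALSE]
}

#' Preranked enrichment statistic
#'
#' Weighted Kolmogorov-Smirnov running sum over the metric-ranked gene list:
#' hits contribute `|metric|^weight_p` normalized to sum 1, misses
#' `1/(N - n_set)`; the enrichment score (ES) is the extremum of the running
#' sum. NES and permutation p/q come from a seeded gene-label permutation
#' null (ES divided by the mean |ES| of same-sign permutations).
#'
#' @param ranked_metric named numeric vector (gene -> score); ranked
#'   internally in decreasing order, ties broken by gene ID.
#' @param collection a `geneset_collection` (members absent from the ranked
#'   list are dropped with a log note).
#' @param weight_p metric weight exponent (default 1; 0 = classic KS).
#' @param n_perm permutations (default 1000).
#' @param seed integer seed for the permutation null.
#' @return data.frame: set, n_genes, es, nes, p, q.
#' @export
preranked_enrichment <- function(ranked_metric, collection, weight_p = 1,
                                 n_perm = 1000, seed = 1) {
  if (is.null(names(ranked_metric))) stop_sf("ranked_metric must be named by gene")
  ord <- order(-ranked_metric, names(ranked_metric))
  metric <- ranked_metric[ord]
  genes <- names(metric)
  n <- length(genes)
  set_idx <- lapply(names(collection), function(nm) {
    members <- intersect(collection[[nm]]$genes, genes)
    dropped <- length(collection[[nm]]$genes) - length(members)
    if (dropped) sf_log("enrich", "set '", nm, "': ", dropped,
                        " member(s) absent from ranked list")
    if (!length(members)) stop_sf("set '%s' has no gene in the ranked list", nm)
    if (length(members) == n) {
      sf_log("enrich", "set '", nm, "' covers the whole ranked list")
    }
    match(members, genes)
  })
  names(set_idx) <- names(collection)
  es_obs <- vapply(set_idx, function(ix) running_sum_es(metric, ix, weight_p),
                   numeric(1))
  perms <- with_seed(child_seed(seed, "gsea-perm"), {
    lapply(seq_len(n_perm), function(i) sample.int(n))
  })
  out <- lapply(names(set_idx), function(nm) {
    ix <- set_idx[[nm]]
    sz <- length(ix)
    es_null <- vapply(perms, function(pp) {
      running_sum_es(metric, sort(pp[seq_len(sz)]), weight_p)
    }, numeric(1))
    es <- es_obs[[nm]]
    same <- es_null[sign(es_null) == sign(es)]
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    pval <- if (es >= 0) {
      (1 + sum(es_null >= es)) / (1 + sum(es_null >= 0))
    } else {
      (1 + sum(es_null <= es)) / (1 + sum(es_null < 0))
    }
    data.frame(set = nm, n_genes = sz, es = es, nes = nes, p = min(pval, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

# ES of a set given positions `idx` (sorted) in the metric-ranked list.
running_sum_es <- function(metric, idx, weight_p) {
  n <- length(metric)
  hit <- logical(n)
  hit[idx] <- TRUE
  w <- abs(metric)^weight_p
  wh <- w * hit
  denom_hit <- sum(wh)
  if (denom_hit == 0) {            # all-zero metric inside the set
    wh[hit] <- 1
    denom_hit <- sum(wh)
  }
  n_miss <- n - length(idx)
  if (n_miss == 0) return(1)       # no misses: the sum climbs to exactly 1
  steps <- wh / denom_hit - (!hit) / n_miss
  rs <- cumsum(steps)
  rs[which.max(abs(rs))]
}
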