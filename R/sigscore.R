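# Signature activity scoring: per-gene z-scores across samples, per-patient
# activity = sum of up-gene z minus sum of down-gene z, and tertile risk
# stratification (top third = high risk for a poor-prognosis signature).

#' Construct a gene signature
#'
#' @param name signature name.
#' @param up_genes,down_genes character vectors; disjoint, at least one gene
#'   in total.
#' @param provenance free-text note on where the lists came from.
#' @return a `gene_signature` list.
#' @export
gene_signature <- function(name, up_genes = character(),
                           down_genes = character(), provenance = "") {
  up <- unique(as.character(up_genes)); down <- unique(as.character(down_genes))
  if (length(intersect(up, down))) {
    stop_sf("signature '%s': up and down lists overlap (%s)", name,
            paste(utils::head(intersect(up, down), 3), collapse = ", "))
  }
  if (!length(up) && !length(down)) stop_sf("signature '%s' is empty", name)
  structure(list(name = name, up_genes = up, down_genes = down,
                 provenance = provenance),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature '%s': %d up, %d down\n", x$name,
              length(x$up_genes), length(x$down_genes)))
  invisible(x)
}

#' Read a signature from a two-column TSV (gene, direction)
#'
#' `direction` must be `up` or `down`.
#'
#' @param path file path.
#' @param name signature name (default: file base name).
#' @return a `gene_signature`.
#' @export
read_signature <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("gene", "direction") %in% names(df))) {
    stop_sf("%s: signature file needs columns 'gene' and 'direction'", path)
  }
  if (!all(df$direction %in% c("up", "down"))) {
    stop_sf("%s: direction must be 'up' or 'down'", path)
  }
  gene_signature(name, df$gene[df$direction == "up"],
                 df$gene[df$direction == "down"],
                 provenance = paste("read from", basename(path)))
}

#' Write a signature as a two-column TSV
#' @param signature a `gene_signature`.
#' @param path output path.
#' @export
write_signature <- function(signature, path) {
  df <- data.frame(gene = c(signature$up_genes, signature$down_genes),
                   direction = rep(c("up", "down"),
                                   c(length(signature$up_genes),
                                     length(signature$down_genes))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The 13-gene hub signature
#'
#' The dual-centrality hub signature for localized osteosarcoma prognosis:
#' six genes elevated in poor-prognosis patients (MYOM2, VEGFA, MUC1, IHH,
#' GLI1, GRIA1) and seven reduced (VCAM1, EGFR, GPC3, IGF2, GNG12, GNGT1,
#' C3). Shipped as `extdata/signatures/hub13.tsv`.
#'
#' @return a `gene_signature`.
#' @export
hub13_signature <- function() {
  read_signature(system.file("extdata", "signatures", "hub13.tsv",
                             package = "sigforge", mustWork = TRUE),
                 name = "hub13")
}

#' Per-gene z-scores across samples
#'
#' Each gene's expression is centered and scaled across samples using the
#' population (divide by n) standard deviation; zero-variance genes become
#' all-zero rows with a logged warning count.
#'
#' @param expr a `log_normalized` [expression_matrix()] (other flavors are
#'   accepted with a log note; z-scoring raw counts is rarely sensible).
#' @return a `zscore`-flavor [expression_matrix()].
#' @export
zscore_by_gene <- function(expr) {
  if (ncol(expr) < 2L) stop_sf("z-scores undefined for a single sample")
  m <- unclass(expr)
  mu <- rowMeans(m)
  sdv <- sqrt(rowMeans((m - mu)^2))   # population sd
  z <- (m - mu) / sdv
  flat <- sdv == 0
  if (any(flat)) {
    z[flat, ] <- 0
    sf_log("zscore", sum(flat), " zero-variance gene(s) set to z = 0")
  }
  expression_matrix(z, "zscore")
}

#' Signature activity score per patient
#'
#' Raw sum (not mean) of the z-scores of the signature's up genes minus the
#' z-scores of its down genes. Signature genes absent from the matrix are
#' skipped and counted, never silently dropped.
#'
#' @param zmat a `zscore` [expression_matrix()].
#' @param signature a `gene_signature`.
#' @param average if TRUE divide by the number of signature genes used
#'   (off by default; the raw sum is the reference definition).
#' @return an `activity_scores` data.frame: patient_id, score; attributes
#'   `n_up_used`, `n_down_used`, `missing_genes`.
#' @export
activity_score <- function(zmat, signature, average = FALSE) {
  if (expr_flavor(zmat) != "zscore") stop_sf("activity_score expects z-scored expression")
  up <- intersect(signature$up_genes, rownames(zmat))
  down <- intersect(signature$down_genes, rownames(zmat))
  missing <- setdiff(c(signature$up_genes, signature$down_genes), rownames(zmat))
  if (!length(up) && !length(down)) {
    stop_sf("no gene of signature '%s' present in the matrix", signature$name)
  }
  if (length(missing)) {
    sf_log("score", length(missing), " signature gene(s) absent from matrix")
  }
  m <- unclass(zmat)
  s <- (if (length(up)) colSums(m[up, , drop = FALSE]) else 0) -
       (if (length(down)) colSums(m[down, , drop = FALSE]) else 0)
  if (average) s <- s / (length(up) + length(down))
  structure(data.frame(patient_id = colnames(zmat), score = as.numeric(s),
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("activity_scores", "data.frame"),
            signature = signature$name,
            n_up_used = length(up), n_down_used = length(down),
            missing_genes = missing)
}

#' Tertile risk stratification
#'
#' Patients are rank-sorted by score (ties broken by patient ID, stable);
#' the bottom `floor(n/3)` are labelled `low`, the top `floor(n/3)` `high`,
#' the remainder `middle`. The middle stratum is retained but excluded from
#' two-group survival contrasts downstream.
#'
#' @param scores an `activity_scores` data.frame (or any data.frame with
#'   patient_id and score).
#' @return a `risk_strata` data.frame: patient_id, score, risk; attribute
#'   `cut_points` (highest low score, lowest high score).
#' @export
tertile_stratify <- function(scores) {
  n <- nrow(scores)
  if (n < 3L) stop_sf("tertile stratification needs n >= 3 (got %d)", n)
  ord <- order(scores$score, scores$patient_id)
  k <- floor(n / 3)
  risk <- rep("middle", n)
  risk[ord[seq_len(k)]] <- "low"
  risk[ord[n + 1 - seq_len(k)]] <- "high"
  cuts <- c(lower = scores$score[ord[k]],
            upper = scores$score[ord[n + 1 - k]])
  structure(data.frame(patient_id = scores$patient_id, score = scores$score,
                       risk = factor(risk, levels = c("low", "middle", "high")),
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("risk_strata", "data.frame"), cut_points = cuts)
}
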