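# Readers/writers for every external format the pipeline touches, with strict
# validation: expression TSV (genes x samples), clinical TSV, GMT gene sets,
# STRING-style edge lists. Readers never silently coerce — any violated
# invariant is an error, not a warning.

EXPR_FLAVORS <- c("raw_counts", "normalized", "log_normalized", "zscore")

#' Construct a validated expression matrix
#'
#' The pipeline's central container: a numeric genes-by-samples matrix with a
#' `flavor` attribute recording which processing stage produced it
#' (`raw_counts`, `normalized`, `log_normalized` or `zscore`).
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene IDs) and colnames (sample IDs).
#' @param flavor one of `r paste(EXPR_FLAVORS, collapse=", ")`.
#' @return an `expression_matrix` object (a matrix with class and flavor).
#' @export
expression_matrix <- function(values, flavor) {
  flavor <- match.arg(flavor, EXPR_FLAVORS)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_sf("expression values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_sf("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1]
    stop_sf("duplicate gene identifier: '%s'", dup)
  }
  if (anyDuplicated(colnames(values))) {
    dup <- colnames(values)[duplicated(colnames(values))][1]
    stop_sf("duplicate sample identifier: '%s'", dup)
  }
  if (any(!is.finite(values))) stop_sf("expression matrix contains non-finite values")
  if (flavor == "raw_counts") {
    if (any(values < 0)) stop_sf("raw counts must be non-negative")
    if (any(values != round(values))) stop_sf("raw counts must be integer-valued")
  }
  structure(values, class = c("expression_matrix", class(values)),
            flavor = flavor)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix [%s]: %d genes x %d samples\n",
              attr(x, "flavor"), nrow(x), ncol(x)))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x object to query.
#' @export
expr_flavor <- function(x) attr(x, "flavor")

#' Read a genes-by-samples expression table
#'
#' Tab-separated, first column gene IDs, header row of sample IDs. Duplicate
#' gene rows, non-numeric cells and malformed headers are rejected with the
#' offending line named.
#'
#' @param path file path.
#' @param flavor declared flavor of the stored values (see
#'   [expression_matrix()]).
#' @return an `expression_matrix`.
#' @export
read_expression <- function(path, flavor = "raw_counts") {
  flavor <- match.arg(flavor, EXPR_FLAVORS)
  lines <- readLines(path)
  if (length(lines) < 1L) stop_sf("%s: empty file", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L) stop_sf("%s: malformed header (need gene column + >=1 sample)", path)
  sample_ids <- header[-1]
  body <- lines[-1]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  n_col <- length(header)
  genes <- character(length(fields))
  vals <- matrix(NA_real_, length(fields), length(sample_ids))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) != n_col) {
      stop_sf("%s: line %d has %d fields, expected %d", path, i + 1L, length(f), n_col)
    }
    genes[i] <- f[1]
    v <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(v)) {
      stop_sf("%s: line %d (gene '%s'): non-numeric cell", path, i + 1L, f[1])
    }
    vals[i, ] <- v
  }
  if (anyDuplicated(genes)) {
    dup <- genes[duplicated(genes)][1]
    stop_sf("%s: duplicated gene row '%s'", path, dup)
  }
  rownames(vals) <- genes
  colnames(vals) <- sample_ids
  expression_matrix(vals, flavor)
}

#' Write an expression matrix as TSV
#' @param expr an `expression_matrix`.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a validated clinical table
#'
#' Per-patient survival and relapse endpoints plus the metastatic flag. Extra
#' numeric columns are preserved as auxiliary traits. When
#' `enforce_relapse_before_death = TRUE` (the localized-cohort constraint:
#' every deceased patient relapsed), a deceased patient without a relapse
#' event is an error.
#'
#' @param df data.frame with columns patient_id, os_time, os_event, rfs_time,
#'   rfs_event, metastatic; any further numeric columns become extra traits.
#' @param enforce_relapse_before_death logical.
#' @return a `clinical_table` (data.frame subclass).
#' @export
clinical_table <- function(df, enforce_relapse_before_death = FALSE) {
  req <- c("patient_id", "os_time", "os_event", "rfs_time", "rfs_event", "metastatic")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop_sf("clinical table missing column(s): %s", paste(miss, collapse = ", "))
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id)) {
    stop_sf("duplicate patient_id: '%s'", df$patient_id[duplicated(df$patient_id)][1])
  }
  for (tc in c("os_time", "rfs_time")) {
    if (!is.numeric(df[[tc]]) || any(!is.finite(df[[tc]]))) stop_sf("%s must be finite numeric", tc)
    if (any(df[[tc]] < 0)) stop_sf("%s contains negative times", tc)
  }
  for (ec in c("os_event", "rfs_event", "metastatic")) df[[ec]] <- check_flag01(df[[ec]], ec)
  extra <- setdiff(names(df), req)
  for (xc in extra) {
    if (!is.numeric(df[[xc]])) stop_sf("extra trait '%s' must be numeric", xc)
  }
  if (enforce_relapse_before_death &&
      any(df$os_event == 1L & df$metastatic == 0L & df$rfs_event != 1L)) {
    stop_sf("cohort constraint violated: a deceased localized patient lacks a relapse event")
  }
  structure(df, class = c("clinical_table", "data.frame"),
            extra_traits = extra)
}

#' Read a clinical TSV
#' @param path file path.
#' @param ... passed to [clinical_table()].
#' @return a `clinical_table`.
#' @export
read_clinical <- function(path, ...) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  clinical_table(df, ...)
}

#' Write a clinical table as TSV
#' @param clin a `clinical_table`.
#' @param path output path.
#' @export
write_clinical <- function(clin, path) {
  utils::write.table(as.data.frame(clin), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Extra-trait column names of a clinical table
#' @param clin a `clinical_table`.
#' @export
extra_traits <- function(clin) attr(clin, "extra_traits")

#' Read a GMT gene-set collection
#'
#' One set per line: `name TAB description TAB member...`. Lines with fewer
#' than three fields are a parse error; set order is preserved.
#'
#' @param path file path.
#' @return a `geneset_collection`: named list of lists with `description` and
#'   `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop_sf("%s: line %d has < 3 fields", path, i)
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop_sf("%s: line %d: empty member list", path, i)
    if (anyDuplicated(genes)) stop_sf("%s: line %d: duplicated member in set '%s'", path, i, f[1])
    nms[i] <- f[1]
    sets[[i]] <- list(description = f[2], genes = genes)
  }
  names(sets) <- nms
  structure(sets, class = "geneset_collection")
}

#' Write a gene-set collection as GMT
#' @param collection a `geneset_collection`.
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(seq_along(collection), function(i) {
    s <- collection[[i]]
    paste(c(names(collection)[i], s$description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat(sprintf("geneset_collection: %d sets (sizes %s)\n", length(x),
              paste(range(vapply(x, function(s) length(s$genes), 1L)), collapse = "-")))
  invisible(x)
}

#' Read a STRING-style interaction edge list
#'
#' Tab-separated `gene_a TAB gene_b TAB combined_score` with scores on the
#' STRING 0-1000 scale. Edges below `min_confidence` are dropped, self-loops
#' removed and symmetric duplicates collapsed to a single undirected edge
#' (keeping the maximum score).
#'
#' @param path file path.
#' @param min_confidence minimum combined score to retain (default 400,
#'   STRING's medium confidence).
#' @return an `edge_list` data.frame with columns gene_a, gene_b, confidence.
#' @export
read_edge_list <- function(path, min_confidence = 400) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (ncol(df) < 3L) stop_sf("%s: edge list needs 3 columns (gene_a, gene_b, score)", path)
  names(df)[1:3] <- c("gene_a", "gene_b", "confidence")
  edge_list(df[, 1:3], min_confidence = min_confidence)
}

#' @rdname read_edge_list
#' @param df data.frame of raw edges.
#' @export
edge_list <- function(df, min_confidence = 0) {
  if (!is.numeric(df$confidence) || anyNA(df$confidence)) {
    stop_sf("edge confidence must be numeric")
  }
  if (any(df$confidence < 0 | df$confidence > 1000)) {
    stop_sf("edge confidence outside [0, 1000]")
  }
  df$gene_a <- as.character(df$gene_a)
  df$gene_b <- as.character(df$gene_b)
  df <- df[df$confidence >= min_confidence, , drop = FALSE]
  df <- df[df$gene_a != df$gene_b, , drop = FALSE]
  if (nrow(df)) {
    key <- ifelse(df$gene_a < df$gene_b,
                  paste(df$gene_a, df$gene_b, sep = "\r"),
                  paste(df$gene_b, df$gene_a, sep = "\r"))
    ord <- order(key, -df$confidence)
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(key[ord]), , drop = FALSE]
    ab <- t(apply(df[, c("gene_a", "gene_b")], 1, sort))
    df$gene_a <- ab[, 1]; df$gene_b <- ab[, 2]
  }
  rownames(df) <- NULL
  structure(df, class = c("edge_list", "data.frame"))
}

#' Write an edge list as TSV
#' @param edges an `edge_list`.
#' @param path output path.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(as.data.frame(edges), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
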