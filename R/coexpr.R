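# Weighted co-expression analysis: unsigned soft-threshold adjacency
# |cor|^beta, scale-free topology scan, topological overlap matrix (TOM),
# module detection by average-linkage clustering on 1 - TOM with a static
# cut, size filter and eigengene merging, module eigengenes / membership,
# and module-trait correlation. Module labels follow the conventional
# color vocabulary (largest module = turquoise, then blue, brown, ...).

MODULE_COLORS <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                   "black", "pink", "magenta", "purple", "greenyellow",
                   "tan", "salmon", "cyan", "midnightblue", "lightcyan",
                   "grey60", "lightgreen", "lightyellow", "royalblue")

drop_constant_genes <- function(expr) {
  m <- unclass(expr)
  v <- apply(m, 1, stats::var)
  if (any(v == 0)) {
    sf_log("coexpr", sum(v == 0), " constant gene(s) excluded")
    m <- m[v > 0, , drop = FALSE]
  }
  m
}

#' Scan soft-threshold powers for scale-free topology
#'
#' For each candidate power beta the unsigned adjacency `|cor|^beta` is
#' formed, per-gene connectivity `k_i = sum_{j != i} a_ij` computed, and the
#' scale-free fit measured as the R-squared of the `log10 p(k)` versus
#' `log10 k` regression over binned connectivities. The chosen power is the
#' smallest with fit >= `rsq_target`, else the argmax; a fixed override
#' (e.g. 4) can be passed downstream regardless.
#'
#' @param expr a log-scale [expression_matrix()] (>= 8 samples, >= 30 genes
#'   recommended).
#' @param powers candidate integer powers.
#' @param rsq_target scale-free fit target (default 0.8).
#' @param n_bins connectivity histogram bins (>= 8).
#' @return a `soft_threshold_scan` list: `table` (power, rsq,
#'   mean_connectivity) and `chosen_power`.
#' @export
soft_threshold_scan <- function(expr, powers = 1:12, rsq_target = 0.8,
                                n_bins = 10) {
  if (n_bins < 8) stop_sf("need >= 8 connectivity bins")
  m <- drop_constant_genes(expr)
  cc <- abs(stats::cor(t(m)))
  diag(cc) <- 0
  res <- lapply(powers, function(beta) {
    a <- cc^beta
    k <- rowSums(a)
    rsq <- scale_free_rsq(k, n_bins)
    c(power = beta, rsq = rsq, mean_connectivity = mean(k))
  })
  tab <- as.data.frame(do.call(rbind, res))
  ok <- which(!is.na(tab$rsq) & tab$rsq >= rsq_target)
  chosen <- if (length(ok)) tab$power[ok[1]] else tab$power[which.max(tab$rsq)]
  structure(list(table = tab, chosen_power = chosen),
            class = "soft_threshold_scan")
}

scale_free_rsq <- function(k, n_bins) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(NA_real_)
  brk <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, brk, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  kmid <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3) return(NA_real_)
  fit <- stats::lm(log10(freq[keep] / sum(freq[keep])) ~ log10(kmid[keep]))
  summary(fit)$r.squared
}

#' Topological overlap matrix
#'
#' Unsigned adjacency `a = |cor|^power`;
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' unit diagonal. Symmetric by construction.
#'
#' @param expr a log-scale [expression_matrix()].
#' @param power soft-threshold power (>= 1).
#' @return symmetric gene-by-gene TOM matrix.
#' @export
tom_similarity <- function(expr, power) {
  if (power < 1) stop_sf("power must be >= 1")
  m <- drop_constant_genes(expr)
  a <- abs(stats::cor(t(m)))^power
  if (any(!is.finite(a))) stop_sf("non-finite correlations in adjacency")
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  minK <- outer(k, k, pmin)
  tom <- (l + a) / (minK + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- list(rownames(m), rownames(m))
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on dissimilarity `1 - TOM`, a
#' static tree cut at `cut_height`, clusters below `min_size` relabelled
#' grey (unassigned), then iterative merging of modules whose eigengenes
#' correlate above `1 - merge_cut`. Module labels are assigned by
#' descending size through the conventional color list.
#'
#' @param tom TOM matrix from [tom_similarity()].
#' @param expr the expression matrix the TOM came from (needed for
#'   eigengene merging).
#' @param min_size minimum module size (default 30).
#' @param merge_cut eigengene-dissimilarity merge threshold (default 0.25,
#'   i.e. merge when cor > 0.75).
#' @param cut_height static cut height on 1 - TOM (default 0.99).
#' @return a `module_assignment` list: `labels` (named color per gene,
#'   "grey" = unassigned), `sizes`, `eigengenes` (sample x module matrix),
#'   `module_membership` (per gene: correlation with its own module
#'   eigengene; NA for grey).
#' @export
detect_modules <- function(tom, expr, min_size = 30, merge_cut = 0.25,
                           cut_height = 0.99) {
  genes <- rownames(tom)
  m <- unclass(expr)[genes, , drop = FALSE]
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  cl[cl %in% as.integer(names(sizes)[sizes < min_size])] <- 0L
  if (all(cl == 0L)) {
    labels <- stats::setNames(rep("grey", length(genes)), genes)
    return(structure(list(labels = labels, sizes = c(grey = length(genes)),
                          eigengenes = NULL, module_membership = NULL),
                     class = "module_assignment"))
  }
  if (length(unique(cl[cl != 0L])) == 1L && !any(cl == 0L)) {
    sf_log("modules", "all genes fell into a single module")
  }
  # iterative eigengene merging
  repeat {
    mods <- sort(unique(cl[cl != 0L]))
    if (length(mods) < 2L) break
    eg <- vapply(mods, function(mi) {
      module_eigengene(expr, genes[cl == mi])$eigengene
    }, numeric(ncol(m)))
    cmat <- stats::cor(eg)
    diag(cmat) <- -Inf
    best <- which(cmat == max(cmat), arr.ind = TRUE)[1, ]
    if (max(cmat) <= 1 - merge_cut) break
    cl[cl == mods[best[2]]] <- mods[best[1]]
  }
  mods <- sort(unique(cl[cl != 0L]))
  # size ties broken by the lexicographically smallest member gene, so labels
  # are invariant to gene order
  first_gene <- vapply(mods, function(mi) min(genes[cl == mi]), character(1))
  ord <- order(-vapply(mods, function(mi) sum(cl == mi), 1), first_gene)
  color_of <- stats::setNames(MODULE_COLORS[seq_along(mods)], mods[ord])
  labels <- rep("grey", length(genes))
  names(labels) <- genes
  for (mi in mods) labels[cl == mi] <- color_of[[as.character(mi)]]
  mod_colors <- MODULE_COLORS[seq_along(mods)]
  eigengenes <- vapply(mod_colors, function(colr) {
    module_eigengene(expr, genes[labels == colr])$eigengene
  }, numeric(ncol(m)))
  rownames(eigengenes) <- colnames(m)
  mm <- rep(NA_real_, length(genes))
  names(mm) <- genes
  for (colr in mod_colors) {
    members <- genes[labels == colr]
    mm[members] <- as.numeric(stats::cor(t(m[members, , drop = FALSE]),
                                         eigengenes[, colr]))
  }
  sizes <- c(sort(table(labels[labels != "grey"]), decreasing = TRUE),
             grey = sum(labels == "grey"))
  structure(list(labels = labels, sizes = sizes, eigengenes = eigengenes,
                 module_membership = mm),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  cat("module_assignment:",
      paste(sprintf("%s=%d", names(x$sizes), x$sizes), collapse = ", "), "\n")
  invisible(x)
}

#' Module eigengene and module membership
#'
#' The eigengene is the first principal component of the standardized
#' (per-gene z-scored) module submatrix, as a unit-norm per-sample vector
#' with sign fixed so that it correlates non-negatively with the mean
#' standardized expression of the module. Module membership (MM) of a gene
#' is its Pearson correlation with the eigengene. A single-gene module
#' returns the standardized gene itself (normalized) with MM = 1.
#'
#' @param expr an [expression_matrix()] containing the module genes.
#' @param module_genes character vector of member genes.
#' @return list: `eigengene` (per sample, unit norm), `module_membership`
#'   (named per gene), `var_explained`.
#' @export
module_eigengene <- function(expr, module_genes) {
  if (!length(module_genes)) stop_sf("empty module")
  miss <- setdiff(module_genes, rownames(expr))
  if (length(miss)) stop_sf("module gene(s) absent: %s",
                            paste(utils::head(miss, 3), collapse = ", "))
  m <- unclass(expr)[module_genes, , drop = FALSE]
  zs <- t(scale(t(m)))   # per-gene standardization
  zs[!is.finite(zs)] <- 0
  if (length(module_genes) == 1L) {
    v <- as.numeric(zs)
    e <- v / sqrt(sum(v^2))
    return(list(eigengene = stats::setNames(e, colnames(m)),
                module_membership = stats::setNames(1, module_genes),
                var_explained = 1))
  }
  sv <- svd(t(zs))
  e <- sv$u[, 1]
  avg <- colMeans(zs)
  if (stats::cor(e, avg) < 0) e <- -e
  mm <- as.numeric(stats::cor(t(m), e))
  names(mm) <- module_genes
  list(eigengene = stats::setNames(e, colnames(m)),
       module_membership = mm,
       var_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' Module-trait correlation matrix
#'
#' Pearson r and two-sided p for every module eigengene against every
#' clinical trait (vital_status = os_event, first_event = rfs_event,
#' metastatic, plus any extra numeric traits). Constant traits are flagged
#' as undefined rather than propagating NaN.
#'
#' @param assignment a `module_assignment` with eigengenes.
#' @param clinical a [clinical_table()] whose patients match the eigengene
#'   samples (by patient_id).
#' @return a `module_trait_matrix` list of matrices `r`, `p` and logical
#'   `undefined` (module x trait).
#' @export
module_trait_correlation <- function(assignment, clinical) {
  if (is.null(assignment$eigengenes)) stop_sf("assignment has no modules")
  eg <- assignment$eigengenes
  idx <- match(rownames(eg), clinical$patient_id)
  if (anyNA(idx)) stop_sf("eigengene samples missing from clinical table")
  traits <- data.frame(vital_status = clinical$os_event[idx],
                       first_event = clinical$rfs_event[idx],
                       metastatic = clinical$metastatic[idx])
  for (xc in extra_traits(clinical)) traits[[xc]] <- clinical[[xc]][idx]
  mods <- colnames(eg)
  r <- p <- matrix(NA_real_, length(mods), ncol(traits),
                   dimnames = list(mods, names(traits)))
  undef <- matrix(FALSE, length(mods), ncol(traits),
                  dimnames = dimnames(r))
  for (tr in names(traits)) {
    if (stats::sd(traits[[tr]]) == 0) {
      undef[, tr] <- TRUE
      next
    }
    for (mo in mods) {
      ct <- trait_correlation(eg[, mo], traits[[tr]])
      r[mo, tr] <- ct$r
      p[mo, tr] <- ct$p
    }
  }
  structure(list(r = r, p = p, undefined = undef,
                 significant = !undef & p < 0.05),
            class = "module_trait_matrix")
}
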