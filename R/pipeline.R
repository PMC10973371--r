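# End-to-end orchestration of the discovery analysis on any cohort:
# normalize -> differential expression (death and relapse contrasts) ->
# signature overlap -> hub selection -> activity scoring -> tertile KM /
# log-rank -> time-dependent AUC -> correlation with time-to-death ->
# co-expression modules + trait correlation -> enrichment. Every artifact
# is written under a stage-numbered run directory with a manifest, and the
# run is a pure function of (inputs, params, seed).

#' Default discovery parameters
#'
#' @return named list of tunables: fold-change and FDR thresholds, the
#'   3-year death-contrast rule, STRING confidence cutoff, hub top-k,
#'   soft-threshold power (4) and minimum module size (30), merge cut,
#'   AUC horizons in years.
#' @export
discovery_params <- function() {
  list(fc_thresh = 1.5, fdr_thresh = 0.05,
       death_contrast_years = 3, exclude_early_censored = TRUE,
       min_confidence = 400, k_hubs = 10,
       power = 4, min_module_size = 30, merge_cut = 0.25,
       cut_height = 0.99, horizons_years = c(3, 5, 10),
       n_perm = 1000)
}

# deceased-within-w-years vs alive-at-study-end group labels (NA = excluded)
death_contrast_groups <- function(clinical, years = 3,
                                  exclude_early_censored = TRUE) {
  cutoff <- years_to_days(years)
  grp <- rep(NA_character_, nrow(clinical))
  grp[clinical$os_event == 1L & clinical$os_time <= cutoff] <- "deceased"
  alive <- clinical$os_event == 0L
  if (exclude_early_censored) alive <- alive & clinical$os_time >= cutoff
  grp[alive] <- "alive"
  factor(grp, levels = c("alive", "deceased"))
}

relapse_contrast_groups <- function(clinical) {
  factor(ifelse(clinical$rfs_event == 1L, "relapse", "eventfree"),
         levels = c("eventfree", "relapse"))
}

run_de_contrast <- function(norm, clinical, grp, params) {
  keep <- !is.na(grp)
  sub <- expression_matrix(unclass(norm)[, clinical$patient_id[keep],
                                         drop = FALSE], "normalized")
  differential_expression(sub, droplevels(grp[keep]),
                          fc_thresh = params$fc_thresh,
                          fdr_thresh = params$fdr_thresh)
}

#' Run the full discovery analysis
#'
#' Executes the complete pipeline on one cohort and writes every artifact
#' under `out_dir` in stage-numbered subdirectories, plus `manifest.json`.
#' Stages whose optional inputs (edge list, gene sets) are absent are
#' recorded as skipped. Any stage failure aborts with the stage name;
#' artifacts of completed stages are preserved.
#'
#' @param expr raw-count [expression_matrix()].
#' @param clinical a [clinical_table()]; only localized (metastatic = 0)
#'   patients enter the survival contrasts.
#' @param out_dir run directory (created).
#' @param edges optional [edge_list()] for hub selection.
#' @param genesets optional `geneset_collection` for enrichment.
#' @param params list from [discovery_params()] (partial overrides merged).
#' @param seed integer seed (permutation nulls).
#' @return invisible list with the in-memory results of every stage and
#'   `manifest`.
#' @export
run_discovery <- function(expr, clinical, out_dir, edges = NULL,
                          genesets = NULL, params = list(), seed = 1) {
  params <- utils::modifyList(discovery_params(), params)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "sigforge",
                   version = as.character(utils::packageVersion("sigforge")),
                   seed = seed, params = params,
                   n_patients = nrow(clinical), n_genes = nrow(expr),
                   stages = list())
  res <- list()
  stage_dir <- function(i, name) {
    d <- file.path(out_dir, sprintf("%02d_%s", i, name))
    dir.create(d, showWarnings = FALSE)
    d
  }
  run_stage <- function(i, name, fun) {
    out <- tryCatch(fun(), error = function(e) {
      stop_sf("stage %02d (%s) failed: %s", i, name, conditionMessage(e))
    })
    manifest$stages[[name]] <<- list(index = i, status = "done")
    out
  }
  loc <- clinical[clinical$metastatic == 0L, , drop = FALSE]
  loc <- clinical_table(as.data.frame(loc))
  expr <- expression_matrix(unclass(expr)[, loc$patient_id, drop = FALSE],
                            expr_flavor(expr))

  res$normalized <- run_stage(1, "normalize", function() {
    norm <- normalize_counts(expr)
    d <- stage_dir(1, "normalize")
    write_expression(norm, file.path(d, "normalized.tsv"))
    norm
  })

  res$de <- run_stage(2, "differential_expression", function() {
    d <- stage_dir(2, "differential_expression")
    surv_grp <- death_contrast_groups(loc, params$death_contrast_years,
                                      params$exclude_early_censored)
    de_surv <- run_de_contrast(res$normalized, loc, surv_grp, params)
    de_rel <- run_de_contrast(res$normalized, loc,
                              relapse_contrast_groups(loc), params)
    utils::write.table(de_surv, file.path(d, "deg_survival.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(de_rel, file.path(d, "deg_relapse.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(survival = de_surv, relapse = de_rel)
  })

  res$overlap <- run_stage(3, "overlap", function() {
    d <- stage_dir(3, "overlap")
    bg <- nrow(res$normalized)
    up <- overlap_signatures(deg_genes(res$de$survival, "up"),
                             deg_genes(res$de$relapse, "up"), bg)
    down <- overlap_signatures(deg_genes(res$de$survival, "down"),
                               deg_genes(res$de$relapse, "down"), bg)
    out <- list(up = unclass(up), down = unclass(down))
    jsonlite::write_json(out, file.path(d, "overlap.json"),
                         auto_unbox = TRUE, digits = NA)
    list(up = up, down = down,
         genes = c(up$overlap_genes, down$overlap_genes))
  })

  in_edges <- unique(c(edges$gene_a, edges$gene_b))
  res$hubs <- if (!is.null(edges) &&
                  length(intersect(res$overlap$genes, in_edges)) >= params$k_hubs) {
    run_stage(4, "hubs", function() {
      d <- stage_dir(4, "hubs")
      g <- build_graph(edges, res$overlap$genes)
      cent <- centrality_table(g)
      hubs <- select_hubs(cent, k = params$k_hubs)
      utils::write.table(cent, file.path(d, "centrality.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(hubs, file.path(d, "hubs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      hubs
    })
  } else {
    manifest$stages[["hubs"]] <- list(
      index = 4,
      status = if (is.null(edges)) "skipped (no edge list)" else
        "skipped (fewer overlap genes in the network than k)")
    NULL
  }

  res$signature <- run_stage(5, "signature", function() {
    d <- stage_dir(5, "signature")
    sig <- if (!is.null(res$hubs)) {
      hubs_to_signature(res$hubs, res$de$survival, name = "hub_signature")
    } else if (length(res$overlap$genes)) {
      gene_signature("overlap_signature",
                     res$overlap$up$overlap_genes,
                     res$overlap$down$overlap_genes,
                     provenance = "overlap of survival and relapse DEG lists")
    } else {
      # empty overlap (underpowered contrast): fall back to the strongest
      # survival-contrast genes so downstream stages stay exercised
      de <- res$de$survival
      top <- de[order(de$raw_p), ][seq_len(min(25, nrow(de))), ]
      gene_signature("top_survival_genes",
                     top$gene[top$log2_fold_change > 0],
                     top$gene[top$log2_fold_change <= 0],
                     provenance = "fallback: top genes of the survival contrast by p-value")
    }
    write_signature(sig, file.path(d, "signature.tsv"))
    sig
  })

  res$scores <- run_stage(6, "scores", function() {
    d <- stage_dir(6, "scores")
    z <- zscore_by_gene(log_transform(res$normalized))
    sc <- activity_score(z, res$signature)
    strata <- tertile_stratify(sc)
    utils::write.table(strata, file.path(d, "scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(zscores = z, scores = sc, strata = strata)
  })

  res$survival <- run_stage(7, "survival", function() {
    d <- stage_dir(7, "survival")
    strata <- res$scores$strata
    idx <- match(strata$patient_id, loc$patient_id)
    out <- list()
    for (ep in c("os", "rfs")) {
      tms <- loc[[paste0(ep, "_time")]][idx]
      evs <- loc[[paste0(ep, "_event")]][idx]
      hi <- strata$risk == "high"; lo <- strata$risk == "low"
      km_hi <- kaplan_meier(tms[hi], evs[hi])
      km_lo <- kaplan_meier(tms[lo], evs[lo])
      lr <- logrank_test(tms[hi], evs[hi], tms[lo], evs[lo])
      utils::write.table(km_hi, file.path(d, sprintf("km_%s_high.tsv", ep)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(km_lo, file.path(d, sprintf("km_%s_low.tsv", ep)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out[[ep]] <- list(km_high = km_hi, km_low = km_lo, logrank = lr)
    }
    jsonlite::write_json(list(os = out$os$logrank, rfs = out$rfs$logrank),
                         file.path(d, "logrank.json"),
                         auto_unbox = TRUE, digits = NA)
    out
  })

  res$time_roc <- run_stage(8, "time_roc", function() {
    d <- stage_dir(8, "time_roc")
    sc <- res$scores$scores
    idx <- match(sc$patient_id, loc$patient_id)
    aucs <- lapply(params$horizons_years, function(y) {
      tryCatch(unclass(time_dependent_auc(sc$score, loc$os_time[idx],
                                          loc$os_event[idx],
                                          years_to_days(y))),
               error = function(e) list(horizon = years_to_days(y),
                                        auc = NA, error = conditionMessage(e)))
    })
    names(aucs) <- paste0("y", params$horizons_years)
    jsonlite::write_json(aucs, file.path(d, "auc.json"),
                         auto_unbox = TRUE, digits = NA)
    aucs
  })

  res$death_correlation <- run_stage(9, "death_correlation", function() {
    d <- stage_dir(9, "death_correlation")
    sc <- res$scores$scores
    idx <- match(sc$patient_id, loc$patient_id)
    dead <- loc$os_event[idx] == 1L
    out <- if (sum(dead) >= 3) {
      trait_correlation(sc$score[dead], loc$os_time[idx][dead])
    } else list(r = NA, p = NA, n = sum(dead))
    jsonlite::write_json(out, file.path(d, "death_correlation.json"),
                         auto_unbox = TRUE, digits = NA)
    out
  })

  res$modules <- run_stage(10, "modules", function() {
    d <- stage_dir(10, "modules")
    genes <- intersect(res$overlap$genes, rownames(res$normalized))
    if (length(genes) < params$min_module_size) {
      return(list(skipped = sprintf("only %d overlap genes", length(genes))))
    }
    lg <- log_transform(res$normalized)
    sub <- expression_matrix(unclass(lg)[genes, , drop = FALSE],
                             "log_normalized")
    tom <- tom_similarity(sub, params$power)
    assign <- detect_modules(tom, sub, min_size = params$min_module_size,
                             merge_cut = params$merge_cut,
                             cut_height = params$cut_height)
    utils::write.table(data.frame(gene = names(assign$labels),
                                  module = assign$labels),
                       file.path(d, "modules.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    traits <- if (!is.null(assign$eigengenes)) {
      utils::write.table(data.frame(patient_id = rownames(assign$eigengenes),
                                    assign$eigengenes),
                         file.path(d, "eigengenes.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      mt <- module_trait_correlation(assign, loc)
      utils::write.table(data.frame(module = rownames(mt$r), mt$r),
                         file.path(d, "module_trait_r.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      mt
    } else NULL
    list(assignment = assign, trait_correlation = traits)
  })

  res$enrichment <- if (!is.null(genesets)) run_stage(11, "enrichment", function() {
    d <- stage_dir(11, "enrichment")
    bg <- rownames(res$normalized)
    query <- intersect(res$overlap$genes, bg)
    ora_res <- if (length(query)) ora(query, genesets, bg) else NULL
    if (!is.null(ora_res)) {
      utils::write.table(ora_res, file.path(d, "ora.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    ranks <- stats::setNames(res$de$survival$log2_fold_change,
                             res$de$survival$gene)
    pre <- preranked_enrichment(ranks, genesets, n_perm = params$n_perm,
                                seed = seed)
    utils::write.table(pre, file.path(d, "preranked.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(ora = ora_res, preranked = pre)
  }) else {
    manifest$stages[["enrichment"]] <- list(index = 11,
                                            status = "skipped (no gene sets)")
    NULL
  }

  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

#' Compare several signatures on one cohort
#'
#' For each signature: activity-score Pearson r/p against time to death
#' (deceased subset), against overall-survival time and first-event time;
#' top-versus-bottom tertile log-rank p; and time-dependent AUC at the
#' requested horizons. A signature with zero matrix coverage is flagged in
#' its row, never dropped silently.
#'
#' @param signatures list of `gene_signature` objects.
#' @param expr raw-count or normalized [expression_matrix()].
#' @param clinical a [clinical_table()].
#' @param horizons_years AUC horizons (default 3, 5, 10).
#' @return data.frame, one row per signature.
#' @export
compare_signatures <- function(signatures, expr, clinical,
                               horizons_years = c(3, 5, 10)) {
  if (length(signatures) < 2) stop_sf("need >= 2 signatures to compare")
  if (expr_flavor(expr) == "raw_counts") expr <- normalize_counts(expr)
  z <- zscore_by_gene(log_transform(expr))
  rows <- lapply(signatures, function(sig) {
    covered <- length(intersect(c(sig$up_genes, sig$down_genes), rownames(z)))
    base <- data.frame(signature = sig$name, n_genes_covered = covered)
    if (covered == 0) {
      base$flag <- "zero matrix coverage"
      return(base)
    }
    sc <- activity_score(z, sig)
    idx <- match(sc$patient_id, clinical$patient_id)
    dead <- clinical$os_event[idx] == 1L
    ttd <- if (sum(dead) >= 3) {
      trait_correlation(sc$score[dead], clinical$os_time[idx][dead])
    } else list(r = NA_real_, p = NA_real_)
    cos <- trait_correlation(sc$score, clinical$os_time[idx])
    crf <- trait_correlation(sc$score, clinical$rfs_time[idx])
    strata <- tertile_stratify(sc)
    hi <- strata$risk == "high"; lo <- strata$risk == "low"
    lr <- logrank_test(clinical$os_time[idx][hi], clinical$os_event[idx][hi],
                       clinical$os_time[idx][lo], clinical$os_event[idx][lo])
    base$r_time_to_death <- ttd$r; base$p_time_to_death <- ttd$p
    base$r_os_time <- cos$r; base$r_first_event_time <- crf$r
    base$logrank_p <- lr$p
    for (y in horizons_years) {
      auc <- tryCatch(time_dependent_auc(sc$score, clinical$os_time[idx],
                                         clinical$os_event[idx],
                                         years_to_days(y))$auc,
                      error = function(e) NA_real_)
      base[[sprintf("auc_%dy", y)]] <- auc
    }
    base$flag <- ""
    base
  })
  out <- do.call(rbind, lapply(rows, function(r) {
    # pad rows that lack columns (zero-coverage flag rows)
    template <- rows[[which.max(vapply(rows, ncol, 1L))]]
    for (nm in setdiff(names(template), names(r))) r[[nm]] <- NA
    r[names(template)]
  }))
  rownames(out) <- NULL
  out
}

#' Deterministic synthetic stand-in for a pair of published DEG signatures
#'
#' Builds two gene signatures over a synthetic gene universe with chosen
#' up/down sizes and a chosen shared-gene structure, for exercising the
#' set-overlap arithmetic at realistic scale. This is a synthetic stand-in
#' (the gene identifiers are generated), not any published gene list.
#'
#' @param n_a_up,n_a_down sizes of signature A.
#' @param n_b_up,n_b_down sizes of signature B.
#' @param k_up,k_down number of genes shared between the respective lists.
#' @param background_n size of the synthetic gene universe.
#' @return list: `sig_a`, `sig_b` (gene_signatures), `background` (character
#'   vector of the universe).
#' @export
synthetic_signature_pair <- function(n_a_up = 488, n_a_down = 475,
                                     n_b_up = 960, n_b_down = 526,
                                     k_up = 264, k_down = 214,
                                     background_n = 20000) {
  if (k_up > min(n_a_up, n_b_up) || k_down > min(n_a_down, n_b_down)) {
    stop_sf("shared counts exceed list sizes")
  }
  need <- (n_a_up + n_b_up - k_up) + (n_a_down + n_b_down - k_down)
  if (need > background_n) stop_sf("universe too small for requested lists")
  universe <- sprintf("SYN%05d", seq_len(background_n))
  take <- function(n, used) setdiff(universe, used)[seq_len(n)]
  a_up <- take(n_a_up, character())
  b_up <- c(a_up[seq_len(k_up)], take(n_b_up - k_up, a_up))
  used <- union(a_up, b_up)
  a_down <- take(n_a_down, used)
  b_down <- c(a_down[seq_len(k_down)],
              take(n_b_down - k_down, union(used, a_down)))
  list(sig_a = gene_signature("synthetic_survival", a_up, a_down,
                              provenance = "synthetic stand-in"),
       sig_b = gene_signature("synthetic_relapse", b_up, b_down,
                              provenance = "synthetic stand-in"),
       background = universe)
}
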