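# Synthetic cohort generator: negative-binomial expression with a planted
# up/down prognostic signature whose latent activity drives a Weibull
# proportional-hazards death/relapse process, planted co-expressed gene
# blocks, and independent censoring. Emulates a localized-osteosarcoma
# cohort: ~65 patients, ~15 deaths within the study window, and every
# deceased patient preceded by relapse.

#' Simulation specification for a synthetic cohort
#'
#' Defaults encode the emulated cohort: 65 localized patients with hazard
#' calibrated to about 15 deaths within a 10-year window, bulk-RNA-seq-like
#' negative-binomial counts (variance mu + alpha*mu^2, alpha = 0.1), a
#' 30 up + 30 down planted signature with 1 log2-unit of effect per SD of
#' latent risk, and two 40-gene co-expressed blocks (intra-correlation 0.8),
#' the first of which is linked to the latent risk.
#'
#' @param n_patients cohort size.
#' @param n_genes total gene count.
#' @param n_up_signature,n_down_signature planted signature sizes.
#' @param log2_effect planted log2 expression shift per SD of latent risk
#'   (up genes +, down genes -).
#' @param nb_dispersion negative-binomial dispersion alpha.
#' @param baseline_mean_logscale length-2 numeric (meanlog, sdlog) of the
#'   log-normal draw of per-gene baseline means (natural-log scale).
#' @param hazard_beta log-hazard per SD of the standardized true activity
#'   score.
#' @param baseline_weibull length-2 numeric (shape, scale in days) of the
#'   baseline event-time distribution.
#' @param follow_up_max maximum administrative follow-up (days).
#' @param censoring_rate probability of early (pre-administrative) random
#'   censoring per patient.
#' @param module_blocks list of blocks, each `list(size, rho, trait_cor)`:
#'   block size, intra-block correlation of the latent signal, and the
#'   correlation of the block factor with the latent risk.
#' @param seed integer seed; all randomness flows from it through named
#'   sub-streams (expression / survival / graph).
#' @return a `simulation_spec` list.
#' @export
simulation_spec <- function(n_patients = 65,
                            n_genes = 1000,
                            n_up_signature = 30,
                            n_down_signature = 30,
                            log2_effect = 1,
                            nb_dispersion = 0.1,
                            baseline_mean_logscale = c(meanlog = 5, sdlog = 1.5),
                            hazard_beta = 1,
                            baseline_weibull = c(shape = 1.2, scale = 10000),
                            follow_up_max = 3652.5,
                            censoring_rate = 0.15,
                            module_blocks = list(
                              list(size = 40, rho = 0.8, trait_cor = 0.7),
                              list(size = 40, rho = 0.8, trait_cor = 0)),
                            seed = 1) {
  spec <- list(n_patients = n_patients, n_genes = n_genes,
               n_up_signature = n_up_signature,
               n_down_signature = n_down_signature,
               log2_effect = log2_effect, nb_dispersion = nb_dispersion,
               baseline_mean_logscale = baseline_mean_logscale,
               hazard_beta = hazard_beta, baseline_weibull = baseline_weibull,
               follow_up_max = follow_up_max, censoring_rate = censoring_rate,
               module_blocks = module_blocks, seed = seed)
  if (n_patients < 2 || n_genes < 1) stop_sf("counts must be positive")
  if (n_up_signature + n_down_signature > n_genes) {
    stop_sf("signature sizes exceed n_genes")
  }
  block_total <- sum(vapply(module_blocks, function(b) b$size, 1))
  if (n_up_signature + n_down_signature + block_total > n_genes) {
    stop_sf("module blocks exceed n_genes after signature genes")
  }
  for (b in module_blocks) {
    if (b$rho < 0 || b$rho >= 1) stop_sf("intra-correlation must be in [0, 1)")
  }
  if (censoring_rate < 0 || censoring_rate >= 1) {
    stop_sf("censoring_rate must be in [0, 1)")
  }
  if (nb_dispersion < 0) stop_sf("nb_dispersion must be >= 0")
  structure(spec, class = "simulation_spec")
}

block_trait_cor <- function(b) if (is.null(b$trait_cor)) 0 else b$trait_cor

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws per-gene baseline means from a log-normal, a standard-normal latent
#' risk per patient, shifts the planted up/down signature genes by
#' `+/- log2_effect` per SD of latent risk, adds co-expressed blocks through
#' shared latent factors, samples negative-binomial counts, and generates
#' death and relapse times from a Weibull proportional-hazards model whose
#' linear predictor is `hazard_beta` times the standardized latent risk.
#' Relapse precedes death for every deceased patient (the localized-cohort
#' constraint); survivors get an independent relapse process. Deterministic
#' under the spec seed.
#'
#' @param spec a [simulation_spec()].
#' @return list with elements `expr` (raw-count [expression_matrix()]),
#'   `clinical` ([clinical_table()]) and `truth` (list: `true_up_genes`,
#'   `true_down_genes`, `true_module_labels`, `true_activity_scores`,
#'   `hazard_beta`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  n <- spec$n_patients
  g <- spec$n_genes
  genes <- sprintf("G%04d", seq_len(g))
  patients <- sprintf("P%03d", seq_len(n))
  up <- genes[seq_len(spec$n_up_signature)]
  down <- genes[spec$n_up_signature + seq_len(spec$n_down_signature)]

  # block layout after the signature genes; label 0 = background
  labels <- integer(g)
  names(labels) <- genes
  offset <- spec$n_up_signature + spec$n_down_signature
  for (i in seq_along(spec$module_blocks)) {
    sz <- spec$module_blocks[[i]]$size
    labels[offset + seq_len(sz)] <- i
    offset <- offset + sz
  }

  risk <- with_seed(child_seed(spec$seed, "risk"), stats::rnorm(n))
  risk_std <- as.numeric(scale(risk))   # standardized true activity score
  names(risk_std) <- patients

  counts <- with_seed(child_seed(spec$seed, "expression"), {
    mu0 <- stats::rlnorm(g, meanlog = spec$baseline_mean_logscale[[1]],
                         sdlog = spec$baseline_mean_logscale[[2]])
    log2off <- matrix(0, g, n)
    sig_idx <- match(c(up, down), genes)
    sig_sign <- rep(c(1, -1), c(length(up), length(down)))
    log2off[sig_idx, ] <- outer(sig_sign * spec$log2_effect, risk_std)
    for (i in seq_along(spec$module_blocks)) {
      b <- spec$module_blocks[[i]]
      tc <- block_trait_cor(b)
      f <- tc * risk_std + sqrt(1 - tc^2) * stats::rnorm(n)
      idx <- which(labels == i)
      noise <- matrix(stats::rnorm(length(idx) * n), length(idx), n)
      # unit-variance log2 signal with intra-block correlation rho
      log2off[idx, ] <- log2off[idx, ] +
        sqrt(b$rho) * matrix(f, length(idx), n, byrow = TRUE) +
        sqrt(1 - b$rho) * noise
    }
    mu <- mu0 * 2^log2off
    k <- matrix(stats::rnbinom(g * n, mu = mu,
                               size = if (spec$nb_dispersion > 0)
                                 1 / spec$nb_dispersion else Inf),
                g, n)
    dimnames(k) <- list(genes, patients)
    k
  })

  clin <- with_seed(child_seed(spec$seed, "survival"), {
    shape <- spec$baseline_weibull[[1]]
    scale <- spec$baseline_weibull[[2]]
    eta <- spec$hazard_beta * risk_std
    t_death <- scale * (-log(stats::runif(n)) / exp(eta))^(1 / shape)
    cens <- stats::runif(n, 0.5, 1) * spec$follow_up_max
    early <- stats::runif(n) < spec$censoring_rate
    cens[early] <- stats::runif(sum(early)) * cens[early]
    os_event <- as.integer(t_death <= cens)
    os_time <- pmin(t_death, cens)
    # relapse: deceased patients relapse an exponential lag before death;
    # survivors get an independent (faster-baseline) relapse process
    lag <- stats::rexp(n, rate = 1 / 180)
    t_rel_dead <- pmax(t_death - lag, 0)
    t_rel_alive <- 0.7 * scale * (-log(stats::runif(n)) / exp(eta))^(1 / shape)
    rfs_event <- integer(n)
    rfs_time <- numeric(n)
    dead <- os_event == 1L
    rfs_event[dead] <- 1L
    rfs_time[dead] <- pmin(t_rel_dead, os_time)[dead]
    rfs_event[!dead] <- as.integer(t_rel_alive[!dead] <= os_time[!dead])
    rfs_time[!dead] <- pmin(t_rel_alive, os_time)[!dead]
    clinical_table(data.frame(patient_id = patients,
                              os_time = os_time, os_event = os_event,
                              rfs_time = rfs_time, rfs_event = rfs_event,
                              metastatic = 0L,
                              stringsAsFactors = FALSE),
                   enforce_relapse_before_death = TRUE)
  })

  truth <- list(true_up_genes = up, true_down_genes = down,
                true_module_labels = labels,
                true_activity_scores = risk_std,
                hazard_beta = spec$hazard_beta)
  list(expr = expression_matrix(counts, "raw_counts"),
       clinical = clin, truth = truth)
}

#' Generate a synthetic interaction edge list with designated hubs
#'
#' Random undirected graph over the planted signature genes plus background
#' genes in which designated hub genes receive elevated degree; used to test
#' hub recovery. With `n_hubs = 0` this is a plain Erdos-Renyi graph with
#' edge probability `noise_prob`.
#'
#' @param truth ground truth from [generate_cohort()].
#' @param n_hubs number of designated hub genes (taken alternately from the
#'   planted up and down lists).
#' @param hub_degree extra random attachments per hub.
#' @param noise_prob background edge probability.
#' @param n_background non-signature genes added as network context.
#' @param seed integer seed.
#' @return an [edge_list()] with attribute `designated_hubs`.
#' @export
generate_edge_list <- function(truth, n_hubs = 10, hub_degree = 15,
                               noise_prob = 0.03, n_background = 40,
                               seed = 1) {
  sig <- c(rbind(c(truth$true_up_genes,
                   rep(NA, max(0, length(truth$true_down_genes) -
                                    length(truth$true_up_genes)))),
                 c(truth$true_down_genes,
                   rep(NA, max(0, length(truth$true_up_genes) -
                                    length(truth$true_down_genes))))))
  sig <- sig[!is.na(sig)]
  if (n_hubs > length(sig)) stop_sf("n_hubs exceeds planted signature size")
  hubs <- sig[seq_len(n_hubs)]
  background <- setdiff(names(truth$true_module_labels), sig)
  nodes <- c(sig, utils::head(background, n_background))
  edges <- with_seed(child_seed(seed, "graph"), {
    m <- length(nodes)
    pairs <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
    keep <- stats::runif(nrow(pairs)) < noise_prob
    ea <- nodes[pairs[keep, 1]]
    eb <- nodes[pairs[keep, 2]]
    for (h in hubs) {
      targets <- sample(setdiff(nodes, h), hub_degree)
      ea <- c(ea, rep(h, hub_degree))
      eb <- c(eb, targets)
    }
    data.frame(gene_a = ea, gene_b = eb,
               confidence = round(stats::runif(length(ea), 400, 999)),
               stringsAsFactors = FALSE)
  })
  out <- edge_list(edges)
  attr(out, "designated_hubs") <- hubs
  out
}

#' Generate gene-set collections matched to the planted truth
#'
#' One set of the planted up genes, one of the planted down genes, plus
#' `n_decoys` random sets of matched sizes drawn without replacement from
#' the full gene background; used to test enrichment calibration/recovery.
#'
#' @param truth ground truth from [generate_cohort()].
#' @param n_decoys number of random decoy sets.
#' @param seed integer seed.
#' @return a `geneset_collection`.
#' @export
generate_genesets <- function(truth, n_decoys = 50, seed = 1) {
  all_genes <- names(truth$true_module_labels)
  sets <- list(
    planted_up = list(description = "planted upregulated signature genes",
                      genes = truth$true_up_genes),
    planted_down = list(description = "planted downregulated signature genes",
                        genes = truth$true_down_genes))
  if (n_decoys > 0) {
    sizes <- rep(c(length(truth$true_up_genes), length(truth$true_down_genes)),
                 length.out = n_decoys)
    decoys <- with_seed(child_seed(seed, "genesets"), {
      lapply(sizes, function(sz) sample(all_genes, sz))
    })
    names(decoys) <- sprintf("decoy_%03d", seq_len(n_decoys))
    sets <- c(sets, lapply(decoys, function(gs) {
      list(description = "random decoy set", genes = gs)
    }))
  }
  structure(sets, class = "geneset_collection")
}
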