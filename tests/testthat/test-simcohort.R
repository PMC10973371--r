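test_that("cohort generator reproduces the emulated cohort shape and is deterministic", {
  # expected deaths calibrated to ~15 of 65 within the study window
  deaths <- vapply(1:30, function(s) {
    sum(generate_cohort(simulation_spec(n_genes = 150, seed = s,
                                        module_blocks = list()))$clinical$os_event)
  }, numeric(1))
  expect_gt(mean(deaths), 12)
  expect_lt(mean(deaths), 18)

  # every deceased localized patient relapsed, with relapse <= death time
  coh <- generate_cohort(small_cohort_spec(seed = 11))
  dead <- coh$clinical$os_event == 1L
  expect_true(all(coh$clinical$rfs_event[dead] == 1L))
  expect_true(all(coh$clinical$rfs_time[dead] <= coh$clinical$os_time[dead]))

  # fixed seed: bit-identical outputs
  a <- generate_cohort(small_cohort_spec(seed = 42))
  b <- generate_cohort(small_cohort_spec(seed = 42))
  expect_identical(unclass(a$expr), unclass(b$expr))
  expect_identical(as.data.frame(a$clinical), as.data.frame(b$clinical))
  expect_false(identical(unclass(a$expr),
                         unclass(generate_cohort(small_cohort_spec(seed = 43))$expr)))

  # invalid specs rejected
  expect_error(simulation_spec(n_genes = 50, n_up_signature = 40,
                               n_down_signature = 40), "exceed")
  expect_error(simulation_spec(censoring_rate = 1), "censoring_rate")
  expect_error(simulation_spec(module_blocks = list(list(size = 10, rho = 1))),
               "intra-correlation")
})

test_that("null hazard decouples the activity score from survival", {
  rs <- lapply(1:100, function(s) {
    coh <- generate_cohort(simulation_spec(
      n_patients = 60, n_genes = 10, n_up_signature = 2, n_down_signature = 2,
      hazard_beta = 0, module_blocks = list(), seed = s))
    dead <- coh$clinical$os_event == 1L
    if (sum(dead) < 3) return(NULL)
    cbind(coh$truth$true_activity_scores[dead], coh$clinical$os_time[dead])
  })
  pooled <- do.call(rbind, rs)
  expect_gt(nrow(pooled), 200)
  expect_lt(abs(cor(pooled[, 1], pooled[, 2])), 0.1)
})

test_that("under strong hazard the high-risk tertile curve sits below the low one", {
  # relapse endpoint (the event-richer read-out at this cohort size),
  # hazard link 2 per SD — a strong-signal instance of the dominance claim
  n_dominated <- 0; n_ok <- 0
  for (s in 1:50) {
    coh <- generate_cohort(simulation_spec(n_patients = 60, n_genes = 150,
                                           hazard_beta = 2,
                                           module_blocks = list(), seed = s))
    z <- zscore_by_gene(log_transform(normalize_counts(coh$expr)))
    sig <- gene_signature("planted", coh$truth$true_up_genes,
                          coh$truth$true_down_genes)
    strata <- tertile_stratify(activity_score(z, sig))
    idx <- match(strata$patient_id, coh$clinical$patient_id)
    hi <- strata$risk == "high"; lo <- strata$risk == "low"
    km_hi <- kaplan_meier(coh$clinical$rfs_time[idx][hi],
                          coh$clinical$rfs_event[idx][hi])
    km_lo <- kaplan_meier(coh$clinical$rfs_time[idx][lo],
                          coh$clinical$rfs_event[idx][lo])
    ts <- sort(unique(c(km_hi$time, km_lo$time)))
    if (!length(ts)) next
    n_ok <- n_ok + 1
    if (all(km_survival_at(km_hi, ts) <= km_survival_at(km_lo, ts) + 1e-12)) {
      n_dominated <- n_dominated + 1
    }
  }
  expect_gte(n_dominated / n_ok, 0.9)
})

test_that("synthetic edge lists concentrate degree on designated hubs", {
  truth <- list(true_up_genes = sprintf("U%02d", 1:10),
                true_down_genes = sprintf("D%02d", 1:10),
                true_module_labels = stats::setNames(
                  integer(20), c(sprintf("U%02d", 1:10), sprintf("D%02d", 1:10))))
  el <- generate_edge_list(truth, n_hubs = 3, hub_degree = 8,
                           noise_prob = 0.02, n_background = 0, seed = 9)
  deg <- table(c(el$gene_a, el$gene_b))
  hubs <- attr(el, "designated_hubs")
  expect_length(hubs, 3)
  top3 <- names(sort(deg, decreasing = TRUE))[1:3]
  expect_setequal(top3, hubs)
  expect_true(all(deg[hubs] >= 8))

  # no designated hubs: Erdos-Renyi edge count near n(n-1)p/2
  counts <- vapply(1:40, function(s) {
    nrow(generate_edge_list(truth, n_hubs = 0, noise_prob = 0.2,
                            n_background = 0, seed = s))
  }, numeric(1))
  expected <- 20 * 19 / 2 * 0.2
  expect_lt(abs(mean(counts) - expected), 3 * sqrt(expected * 0.8 / 40) + 1)

  # determinism
  expect_identical(as.data.frame(generate_edge_list(truth, seed = 5, n_hubs = 3)),
                   as.data.frame(generate_edge_list(truth, seed = 5, n_hubs = 3)))
})

test_that("generated gene sets contain the planted sets plus distinct decoys", {
  coh <- generate_cohort(small_cohort_spec(seed = 2))
  gs0 <- generate_genesets(coh$truth, n_decoys = 0)
  expect_length(gs0, 2)
  expect_identical(gs0$planted_up$genes, coh$truth$true_up_genes)
  expect_length(gs0$planted_up$genes, 30)

  for (s in 1:5) {
    gs <- generate_genesets(coh$truth, n_decoys = 20, seed = s)
    planted <- list(sort(gs$planted_up$genes), sort(gs$planted_down$genes))
    for (nm in grep("^decoy", names(gs), value = TRUE)) {
      expect_false(list(sort(gs[[nm]]$genes)) %in% planted)
      expect_false(anyDuplicated(gs[[nm]]$genes) > 0)
    }
  }
})
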