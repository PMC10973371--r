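# gene-block generator with heterogeneous factor loadings (realistic module
# membership spread), used across the co-expression tests
gaussian_blocks <- function(sizes, rho, n_samples, n_noise, seed) {
  set.seed(seed)
  blocks <- lapply(sizes, function(m) {
    f <- rnorm(n_samples)
    t(sapply(seq_len(m), function(i) {
      u <- min(sqrt(rho) * runif(1, 0.5, 1.15), 0.99)
      u * f + sqrt(1 - u^2) * rnorm(n_samples)
    }))
  })
  m <- do.call(rbind, c(blocks,
                        list(matrix(rnorm(n_noise * n_samples),
                                    nrow = n_noise, ncol = n_samples))))
  rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  colnames(m) <- sprintf("s%03d", seq_len(n_samples))
  labels <- rep(c(seq_along(sizes), 0), c(sizes, n_noise))
  names(labels) <- rownames(m)
  list(expr = expression_matrix(m, "log_normalized"), labels = labels)
}

test_that("soft-threshold scan finds scale-free fit on block data, not on noise", {
  blk <- gaussian_blocks(c(50, 50), 0.8, 100, 50, seed = 3)
  scan <- soft_threshold_scan(blk$expr)
  expect_gte(max(scan$table$rsq, na.rm = TRUE), 0.8)
  expect_true(scan$chosen_power %in% scan$table$power)
  expect_gte(scan$table$rsq[scan$table$power == scan$chosen_power], 0.8)

  # independent genes: no fit at power 1, connectivity monotone in beta
  set.seed(9)
  noise <- matrix(rnorm(150 * 60), 150, 60,
                  dimnames = list(sprintf("g%03d", 1:150), sprintf("s%02d", 1:60)))
  scan2 <- soft_threshold_scan(expression_matrix(noise, "log_normalized"))
  expect_lt(scan2$table$rsq[1], 0.5)
  expect_true(all(diff(scan2$table$mean_connectivity) < 0))
})

test_that("TOM matches its definition on edge cases and random matrices", {
  # two perfectly correlated genes in isolation
  m <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
  colnames(m) <- sprintf("s%d", 1:4)
  tom <- tom_similarity(expression_matrix(m, "log_normalized"), 4)
  expect_equal(tom["a", "b"], 1)

  # triple-loop oracle on a random 10-gene matrix
  set.seed(2)
  m2 <- matrix(rnorm(10 * 30), 10, 30,
               dimnames = list(sprintf("g%02d", 1:10), sprintf("s%02d", 1:30)))
  tom2 <- tom_similarity(expression_matrix(m2, "log_normalized"), 6)
  adj <- abs(cor(t(m2)))^6
  expect_equal(tom2, oracle_tom(adj), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(tom2, t(tom2), tolerance = 1e-12)
  expect_true(all(tom2 >= 0 & tom2 <= 1 + 1e-12))
})

test_that("module detection recovers planted blocks and respects min_size", {
  blk <- gaussian_blocks(c(40, 40), 0.8, 80, 20, seed = 5)
  tom <- tom_similarity(blk$expr, 4)
  ma <- detect_modules(tom, blk$expr, min_size = 30)
  n_modules <- sum(names(ma$sizes) != "grey")
  expect_identical(n_modules, 2L)
  expect_gte(mclust::adjustedRandIndex(ma$labels, blk$labels), 0.8)
  # conventional color order: largest module is turquoise, then blue
  expect_setequal(setdiff(unique(ma$labels), "grey"), c("turquoise", "blue"))

  # min_size above any cluster: everything grey
  all_grey <- detect_modules(tom, blk$expr, min_size = 99)
  expect_true(all(all_grey$labels == "grey"))

  # permuting gene order leaves the partition unchanged
  set.seed(77)
  perm <- sample(nrow(tom))
  expr_p <- expression_matrix(unclass(blk$expr)[perm, ], "log_normalized")
  ma_p <- detect_modules(tom[perm, perm], expr_p, min_size = 30)
  expect_identical(ma_p$labels[names(ma$labels)], ma$labels)
})

test_that("module eigengenes follow the first-PC definition and sign rule", {
  blk <- gaussian_blocks(c(20), 0.9, 50, 0, seed = 7)
  genes <- rownames(blk$expr)
  eg <- module_eigengene(blk$expr, genes)
  expect_equal(sum(eg$eigengene^2), 1)

  # from-scratch oracle: leading eigenvector of the standardized covariance
  zs <- t(scale(t(unclass(blk$expr))))
  ev <- eigen(crossprod(zs))$vectors[, 1]
  ev <- ev / sqrt(sum(ev^2))
  if (cor(ev, colMeans(zs)) < 0) ev <- -ev
  expect_equal(unname(eg$eigengene), ev, tolerance = 1e-10)

  # identical genes: MM = 1 for all
  m <- matrix(rep(rnorm(30), 5), 5, 30, byrow = TRUE,
              dimnames = list(sprintf("g%d", 1:5), sprintf("s%02d", 1:30)))
  same <- module_eigengene(expression_matrix(m, "log_normalized"),
                           sprintf("g%d", 1:5))
  expect_equal(unname(same$module_membership), rep(1, 5))

  # negating the data flips the eigengene, |MM| unchanged
  neg <- module_eigengene(expression_matrix(-unclass(blk$expr),
                                            "log_normalized"), genes)
  expect_equal(unname(neg$eigengene), -unname(eg$eigengene), tolerance = 1e-8)
  expect_equal(abs(neg$module_membership), abs(eg$module_membership),
               tolerance = 1e-8)

  # single-gene module: standardized gene, MM = 1
  one <- module_eigengene(blk$expr, genes[1])
  expect_equal(unname(one$module_membership), 1)

  # first-PC optimality: no single member gene's direction explains more
  # standardized variance than the eigengene
  explained_by <- function(e) sum((zs %*% e)^2) / sum(zs^2)
  for (g in seq_along(genes)) {
    v <- zs[g, ] / sqrt(sum(zs[g, ]^2))
    expect_gte(eg$var_explained + 1e-10, explained_by(v))
  }
  expect_equal(eg$var_explained, explained_by(eg$eigengene), tolerance = 1e-10)
})

test_that("module-trait correlation flags the survival-linked module", {
  hits <- 0; n_reps <- 25
  for (s in 1:n_reps) {
    coh <- generate_cohort(simulation_spec(n_patients = 60, n_genes = 250,
                                           seed = s))
    lg <- log_transform(normalize_counts(coh$expr))
    labels <- coh$truth$true_module_labels
    egs <- vapply(c(1, 2), function(b) {
      module_eigengene(lg, names(labels)[labels == b])$eigengene
    }, numeric(ncol(lg)))
    colnames(egs) <- c("linked", "unlinked")
    rownames(egs) <- colnames(lg)
    assign <- structure(list(eigengenes = egs), class = "module_assignment")
    mt <- module_trait_correlation(assign, coh$clinical)
    if (abs(mt$r["linked", "first_event"]) >
        abs(mt$r["unlinked", "first_event"])) hits <- hits + 1
  }
  expect_gte(hits / n_reps, 0.85)
})

test_that("module-trait correlation handles identities and degenerate traits", {
  set.seed(31)
  eg <- matrix(rnorm(40), 20, 2,
               dimnames = list(sprintf("P%03d", 1:20), c("turquoise", "blue")))
  assign <- structure(list(eigengenes = eg), class = "module_assignment")
  clin <- clinical_table(data.frame(
    patient_id = sprintf("P%03d", 1:20),
    os_time = seq(100, 2000, by = 100), os_event = rep(c(0L, 1L), 10),
    rfs_time = seq(90, 1990, by = 100), rfs_event = rep(c(0L, 1L), 10),
    metastatic = 0L,
    eigencopy = eg[, "turquoise"]))
  mt <- module_trait_correlation(assign, clin)
  expect_equal(mt$r["turquoise", "eigencopy"], 1)
  # constant trait (metastatic all 0): flagged undefined, no NaN leakage
  expect_true(all(mt$undefined[, "metastatic"]))
  expect_false(anyNA(mt$r[, "eigencopy"]))

  # type-I control: independent random traits flagged at roughly 5%
  n_flag <- 0; n_cell <- 0
  for (s in 1:60) {
    set.seed(1000 + s)
    clin2 <- clinical_table(data.frame(
      patient_id = sprintf("P%03d", 1:20),
      os_time = seq(100, 2000, by = 100), os_event = rep(c(0L, 1L), 10),
      rfs_time = seq(90, 1990, by = 100), rfs_event = rep(c(0L, 1L), 10),
      metastatic = 0L, noise_trait = rnorm(20)))
    mt2 <- module_trait_correlation(assign, clin2)
    n_flag <- n_flag + sum(mt2$significant[, "noise_trait"])
    n_cell <- n_cell + nrow(mt2$significant)
  }
  expect_gt(n_flag / n_cell, 0.005)
  expect_lt(n_flag / n_cell, 0.12)
})
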