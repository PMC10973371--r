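# Small fixtures built in code.

tiny_expression <- function() {
  m <- matrix(c(10, 20,
                5, 5,
                0, 3), nrow = 3, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
  expression_matrix(m, "raw_counts")
}

tiny_clinical <- function() {
  clinical_table(data.frame(
    patient_id = c("P1", "P2", "P3", "P4"),
    os_time = c(100, 400, 900, 1500),
    os_event = c(1L, 1L, 0L, 0L),
    rfs_time = c(80, 300, 900, 1200),
    rfs_event = c(1L, 1L, 0L, 1L),
    metastatic = c(0L, 0L, 0L, 1L),
    stringsAsFactors = FALSE))
}

small_cohort_spec <- function(n_patients = 60, seed = 1, ...) {
  # desk-scale spec for per-test simulation: full signature, both blocks,
  # modest background
  simulation_spec(n_patients = n_patients, n_genes = 250, seed = seed, ...)
}

background_genes <- function(truth) {
  setdiff(names(truth$true_module_labels)[truth$true_module_labels == 0],
          c(truth$true_up_genes, truth$true_down_genes))
}
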