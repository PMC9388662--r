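# Shared simulation helpers for the test suite.

# scaled-down configuration for fast unit tests (the acceptance suite uses
# the full default configuration)
small_config <- function(seed = 11, ...) {
  args <- list(seed = seed, n_samples = 60, n_lnc = 80, n_mrna = 200,
               lnc_cluster_sizes = c(20, 12, 8),
               mrna_cluster_sizes = c(40, 30, 25),
               n_cpg = 300, n_enhancer_pairs = 10, n_decoy_loops = 20,
               n_de_extra = 6, n_prognostic = 4, n_cells_per_type = 30)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# stronger, slightly larger configuration for end-to-end pipeline mechanics:
# recovery at n = 60 is borderline (the Bonferroni bar at small n is high),
# so pipeline unit tests use tight coupling to keep every stage well-posed
pipeline_config <- function(seed = 11, ...) {
  small_config(seed = seed, n_samples = 100,
               strength_range = c(0.9, 1.6),
               mrna_strength_ranges = list(A = c(0.8, 1.4), B = c(0.9, 1.5),
                                           C = c(1.0, 1.6)), ...)
}

# memoized full-scale default run shared by the acceptance tests
.acceptance_cache <- new.env(parent = emptyenv())
acceptance_run <- function() {
  if (is.null(.acceptance_cache$res))
    .acceptance_cache$res <- run_all(sim_config(seed = 1), out_dir = NULL)
  .acceptance_cache$res
}

random_intervals <- function(n, chroms = paste0("chr", 1:3), max_pos = 1e5,
                             labels = NULL) {
  start <- sample.int(max_pos, n, replace = TRUE)
  genomic_intervals(sample(chroms, n, replace = TRUE), start,
                    start + sample.int(500, n, replace = TRUE),
                    if (is.null(labels)) NA_character_ else
                      sample(labels, n, replace = TRUE))
}
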