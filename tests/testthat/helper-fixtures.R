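# Shared fixtures built in code.

# Small fast cohort for smoke/property tests.
small_cohort <- function(n_infants = 20L, seed = 11L, ...) {
  generate_cohort(cohort_config(n_infants = n_infants, ...), seed = seed)
}

# A null configuration: no treatment effect anywhere (hazard ratio 1, all
# test-arm metabolite offsets equal to the control-arm offsets).
null_config <- function(n_infants = 40L) {
  ms <- default_spec_nullified(fctomics:::default_metabolite_spec())
  bs <- default_spec_nullified(fctomics:::default_bile_acid_spec())
  cohort_config(n_infants = n_infants, treatment_hazard_ratio = 1,
                metabolite_spec = ms, bile_acid_spec = bs)
}

default_spec_nullified <- function(spec) {
  for (v in c("V1", "V3", "V6")) {
    spec[[sprintf("off_%s_test", v)]] <- spec[[sprintf("off_%s_control", v)]]
  }
  spec
}

# Toy three-leaf tree used for hand-worked PD values.
toy_tree <- function() {
  ape::read.tree(text = "((A:1,B:2):0.5,C:3);")
}

# Deterministic separable DMM test data: `per` samples per component drawn
# from the generator's default five alpha vectors.
separable_counts <- function(per = 80L, seed = 5L, depth = 3000L) {
  cfg <- cohort_config()
  K <- cfg$n_fct
  counts <- matrix(0L, nrow = per * K, ncol = ncol(cfg$alpha_matrix),
                   dimnames = list(NULL, colnames(cfg$alpha_matrix)))
  truth <- integer(per * K)
  i <- 0L
  for (k in seq_len(K)) {
    for (s in seq_len(per)) {
      i <- i + 1L
      counts[i, ] <- draw_genus_counts(k, depth, cfg,
                                       seed = seed * 100000L + i)
      truth[i] <- k
    }
  }
  rownames(counts) <- sprintf("S%03d", seq_len(nrow(counts)))
  list(counts = counts, truth = truth,
       profiles = cfg$alpha_matrix / rowSums(cfg$alpha_matrix))
}
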