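# Heavy trained-model studies shared by several acceptance checks. Each study
# is trained once per test run and memoized; the seeds are fixed so the whole
# suite is reproducible.

study_cache <- new.env(parent = emptyenv())

# Full pipeline (phase 1 + phase 2) on the default synthetic spec.
get_study <- function(seed, dropout = FALSE) {
  key <- paste0("study_", seed, if (dropout) "_dropout")
  if (is.null(study_cache[[key]])) {
    study_cache[[key]] <- if (dropout) {
      run_integration_study(seed, dropout_p = 0.2, max_dropped = 1L,
                            reuse = get_study(seed))
    } else {
      run_integration_study(seed)
    }
  }
  study_cache[[key]]
}

# A model trained on data whose interaction lives on ONE designated edge,
# with the other graph edge inert (its source modality carries no signal at
# all), for planted-edge recovery by LRP. A control edge must be inert:
# cross-attention edges also transport their source's unimodal signal, so a
# control with real signal would be genuinely (and correctly) important.
get_lrp_study <- function(seed) {
  key <- paste0("lrp_", seed)
  if (is.null(study_cache[[key]])) {
    spec <- synthetic_spec(
      n_samples = 600,
      class_props = c(c1 = 0.25, c2 = 0.25, c3 = 0.25, c4 = 0.25),
      modalities = list(list(name = "cnv", p = 200L, d = 0),
                        list(name = "mrna", p = 200L, d = 0.25),
                        list(name = "prot", p = 200L, d = 0.25)),
      planted_edges = list(
        list(source = "mrna", target = "prot", gamma = 2.0,
             class_signs = c(1, 1, -1, -1)),
        list(source = "mrna", target = "prot", gamma = 2.0,
             class_signs = c(1, -1, 1, -1))),
      noise_sd = 1.0, seed = seed)
    study_cache[[key]] <- run_integration_study(seed, spec = spec,
                                                epochs2 = 40L)
  }
  study_cache[[key]]
}
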