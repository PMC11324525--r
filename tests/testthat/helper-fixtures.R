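# Shared fixtures, built once per test run. Everything is generated in code
# from fixed seeds; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, make(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# a small error-free simulated sample shared across unit tests
small_sim <- function() {
  fixture("small_sim", function() {
    cfg <- sim_config(seed = 42L, n_events = 12L, n_long_reads = 25L,
                      n_chromosomes = 2L, chromosome_length = 50000L)
    refs <- forge_references(cfg)
    ev <- plant_events(refs$host, refs$vector, cfg)
    list(cfg = cfg, refs = refs, ev = ev,
         sr = make_itrseq_reads(ev, refs$host, refs$vector, cfg),
         lr = make_long_reads(ev, refs$host, refs$vector, cfg))
  })
}

small_callset <- function() {
  fixture("small_callset", function() {
    s <- small_sim()
    call_itrseq(s$sr$r1, s$sr$r2, s$refs$host, s$refs$vector,
                sample_id = "unit", input_dna_ng = 100)
  })
}

# independent naive transitive-closure oracle for clone counting: repeatedly
# merge labels of observation pairs sharing an adapter position or a UMI
brute_clone_count <- function(adapter, umi) {
  n <- length(adapter)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (comp[i] != comp[j] &&
            (adapter[i] == adapter[j] || umi[i] == umi[j])) {
          old <- max(comp[i], comp[j])
          new <- min(comp[i], comp[j])
          comp[comp == old] <- new
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  length(unique(comp))
}

# truth/annotation comparison over the per-read structure fields
structure_fields <- c("class", "both_flanks", "n_copies", "n_itrs",
                      "n_intact_itrs", "functional_cdna",
                      "promoter_upstream", "junctions")

# deterministic random DNA for constructed cases
random_dna_fixture <- function(n, seed = 1234L) {
  set.seed(seed + n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

align_by_read <- function(df) {
  df <- df[order(df$read_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}
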