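test_that("reference forging is deterministic and respects the component layout", {
  cfg <- sim_config(seed = 7L, n_chromosomes = 2L, chromosome_length = 20000L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  forge_references(cfg, out_dir = d1)
  forge_references(cfg, out_dir = d2)
  expect_identical(readLines(file.path(d1, "host.fasta")),
                   readLines(file.path(d2, "host.fasta")))
  expect_identical(readLines(file.path(d1, "vector.fasta")),
                   readLines(file.path(d2, "vector.fasta")))

  vm <- vector_model(seed = 7L)
  comp <- vm$components
  expect_identical(comp$start0[1], 0L)
  expect_identical(comp$end0[nrow(comp)], vm$full_length)
  # components tile the vector without gaps or overlaps
  expect_identical(comp$start0[-1], comp$end0[-nrow(comp)])
  expect_identical(vm$itr_intact_window, c(165L, 173L))
  expect_error(forge_host_genome(chromosome_length = 5000L), "10 kb")
})

test_that("planted events honour spacing, clone distributions and non-N placement", {
  s <- small_sim()
  ev <- s$ev$events
  expect_identical(nrow(ev), 12L)
  for (ch in unique(ev$chrom)) {
    p <- sort(ev$pos0[ev$chrom == ch])
    if (length(p) > 1L) {
      expect_true(min(diff(p)) >= s$cfg$min_event_spacing)
    }
  }
  # planted positions never fall in N runs
  for (i in seq_len(nrow(ev))) {
    base <- substr(s$refs$host$seqs[[ev$chrom[i]]], ev$pos0[i] + 1L,
                   ev$pos0[i] + 1L)
    expect_true(base %in% c("A", "C", "G", "T"))
  }
  # degenerate clone distribution: constant 1 means no expansion anywhere
  cfg1 <- sim_config(seed = 3L, n_events = 8L, n_chromosomes = 2L,
                     chromosome_length = 30000L,
                     clone_count_distribution = dist_spec("constant", value = 1))
  refs1 <- forge_references(cfg1)
  ev1 <- plant_events(refs1$host, refs1$vector, cfg1)
  expect_true(all(ev1$events$clone_count == 1L))
  # mass on {2, 3} makes every locus expanded in truth
  cfg2 <- sim_config(seed = 3L, n_events = 8L, n_chromosomes = 2L,
                     chromosome_length = 30000L,
                     clone_count_distribution =
                       dist_spec("table", values = c(2, 3), probs = c(.5, .5)))
  ev2 <- plant_events(refs1$host, refs1$vector, cfg2)
  expect_identical(mean(ev2$events$clone_count >= 2L), 1)
})

test_that("ITR-seq reads carry valid UMIs and the planted duplicate structure", {
  s <- small_sim()
  tr <- s$sr$truth
  expect_true(all(valid_umi(tr$umi)))
  # read-pair count equals sum over clones of 1 + duplicates
  expect_identical(length(s$sr$r1), nrow(tr))
  per_clone <- table(paste(tr$event_id, tr$clone_id))
  expect_identical(sum(per_clone), nrow(tr))
  # within a clone all reads share adapter position and UMI
  sp <- split(tr, paste(tr$event_id, tr$clone_id))
  for (g in sp) {
    expect_identical(length(unique(g$adapter_coord0)), 1L)
    expect_identical(length(unique(g$umi)), 1L)
  }
  # across clones of one event, adapter positions and UMIs are distinct
  first <- tr[tr$dup_id == 0L, ]
  for (e in split(first, first$event_id)) {
    expect_identical(anyDuplicated(e$adapter_coord0), 0L)
    expect_identical(anyDuplicated(e$umi), 0L)
  }
})

test_that("error-free reads are reconstructable from the truth table", {
  s <- small_sim()
  tr <- s$sr$truth
  vm <- s$refs$vector
  host <- s$refs$host
  itr_part <- substr(vm$sequence, 1L, 20L + s$cfg$itr_residual_length)
  len1 <- s$cfg$read_length - nchar(itr_part)
  len2 <- s$cfg$read_length - nchar(s$cfg$barcode) - 8L
  idx <- sample(seq_len(nrow(tr)), 10L)
  for (i in idx) {
    p <- tr$pos0[i]; ch <- host$seqs[[tr$chrom[i]]]; f <- tr$fragment[i]
    if (tr$side[i] == "left") {
      h1 <- revcomp(substr(ch, p - len1 + 1L, p))
      h2 <- substr(ch, p - f + 1L, p - f + len2)
    } else {
      h1 <- substr(ch, p + 1L, p + len1)
      h2 <- revcomp(substr(ch, p + f - len2 + 1L, p + f))
    }
    expect_identical(unname(s$sr$r1[tr$read_id[i]]), paste0(itr_part, h1))
    expect_identical(unname(s$sr$r2[tr$read_id[i]]),
                     paste0(s$cfg$barcode, tr$umi[i], h2))
  }
})

test_that("long reads re-splice exactly from their truth segment lists", {
  s <- small_sim()
  segs <- s$lr$segments_truth
  refs <- c(s$refs$host$seqs, list(vector = s$refs$vector$sequence))
  for (rid in unique(segs$read_id)) {
    g <- segs[segs$read_id == rid, ]
    if (any(!grepl("^M:\\d+$", g$ops))) next  # indel-free re-splice only
    pieces <- vapply(seq_len(nrow(g)), function(i) {
      x <- substr(refs[[g$ref[i]]], g$ref_start0[i] + 1L, g$ref_end0[i])
      if (g$orientation[i] == "-") revcomp(x) else x
    }, character(1))
    expect_identical(paste(pieces, collapse = ""),
                     unname(s$lr$reads[[rid]]))
  }
})

test_that("concatemer orientation patterns produce the defined junction labels in truth", {
  # all-plus copies: every junction head-to-tail
  cfg <- sim_config(seed = 9L, n_events = 4L, n_long_reads = 10L,
                    n_chromosomes = 2L, chromosome_length = 30000L,
                    inversion_prob = 0, episome_fraction = 1,
                    host_only_fraction = 0,
                    concatemer_copy_distribution = dist_spec("constant", value = 3))
  refs <- forge_references(cfg)
  ev <- plant_events(refs$host, refs$vector, cfg)
  lr <- make_long_reads(ev, refs$host, refs$vector, cfg)
  labs <- unlist(strsplit(lr$reads_truth$junctions, ","))
  expect_identical(unique(labs), "head_to_tail")
  expect_identical(length(labs), 2L * nrow(lr$reads_truth))
  # plus then minus adjoined at the vector 3' ends: one tail-to-tail junction
  segs <- data.frame(ref = "vector", orientation = c("+", "-"),
                     read_start0 = c(0L, 100L), read_end0 = c(100L, 200L))
  expect_identical(junction_types(segs), "tail_to_tail")
})
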