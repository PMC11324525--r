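test_that("junction labels follow orientation geometry and adjacency", {
  seg <- function(ori, starts, refs = "vector") {
    n <- length(ori)
    data.frame(ref = rep(refs, length.out = n), orientation = ori,
               read_start0 = starts, read_end0 = starts + 100L)
  }
  expect_identical(junction_types(seg(c("+", "+"), c(0L, 100L))),
                   "head_to_tail")
  expect_identical(junction_types(seg(c("-", "-"), c(0L, 100L))),
                   "head_to_tail")
  expect_identical(junction_types(seg(c("+", "-"), c(0L, 100L))),
                   "tail_to_tail")
  expect_identical(junction_types(seg(c("-", "+"), c(0L, 100L))),
                   "head_to_head")
  # host segment between copies interrupts the junction
  mixed <- data.frame(ref = c("vector", "chr1", "vector"),
                      orientation = c("+", "+", "+"),
                      read_start0 = c(0L, 100L, 200L),
                      read_end0 = c(100L, 200L, 300L))
  expect_identical(junction_types(mixed), character(0))
  # a read gap beyond max_gap also interrupts it
  gapped <- seg(c("+", "+"), c(0L, 300L))
  expect_identical(junction_types(gapped, max_gap = 50L), character(0))
})

test_that("ITR records measure observed lengths against the intact window", {
  vm <- vector_model(seed = 1L)
  full_seg <- data.frame(ref = "vector", ref_start0 = 0L,
                         ref_end0 = vm$full_length, orientation = "+",
                         read_start0 = 0L, read_end0 = vm$full_length)
  r <- itr_records(full_seg, vm)
  expect_identical(nrow(r), 2L)
  expect_identical(r$end, c("5p", "3p"))
  expect_true(all(r$observed_length == 169L))
  expect_true(all(r$intact))
  # 5' truncation retaining 102 bases: not intact, break point recorded
  tr_seg <- full_seg
  tr_seg$ref_start0 <- 169L - 102L
  r2 <- itr_records(tr_seg, vm)
  expect_identical(r2$observed_length[r2$end == "5p"], 102L)
  expect_false(r2$intact[r2$end == "5p"])
  expect_identical(r2$breakpoint_offset[r2$end == "5p"], 102L)
  # on a minus-strand segment the 3' ITR comes first on the read
  minus <- full_seg; minus$orientation <- "-"
  expect_identical(itr_records(minus, vm)$end, c("3p", "5p"))
  # two equally truncated ITRs have homogeneity difference zero
  both_tr <- full_seg
  both_tr$ref_start0 <- 67L; both_tr$ref_end0 <- vm$full_length - 67L
  r3 <- itr_records(both_tr, vm)
  expect_identical(diff(r3$observed_length), 0L)
})

test_that("functional-cassette detection requires full cDNA and an upstream promoter", {
  vm <- vector_model(seed = 1L)
  seg <- function(s, e, ori = "+") {
    data.frame(ref = "vector", ref_start0 = s, ref_end0 = e,
               orientation = ori, read_start0 = 0L, read_end0 = e - s,
               identity = 1)
  }
  # complete ITR-to-ITR copy carries both
  fc <- functional_cassette(seg(0L, vm$full_length), vm)
  expect_true(fc$functional_cdna)
  expect_true(fc$promoter_upstream)
  # copy truncated inside the cDNA carries neither
  cdna <- component_interval <- vm$components[vm$components$label == "cdna", ]
  fc2 <- functional_cassette(seg(0L, cdna$start0 + 500L), vm)
  expect_false(fc2$functional_cdna)
  expect_false(fc2$promoter_upstream)
  # promoter deleted (copy starts in the intron) but cDNA intact
  intron <- vm$components[vm$components$label == "intron", ]
  fc3 <- functional_cassette(seg(intron$start0 + 50L, vm$full_length), vm)
  expect_true(fc3$functional_cdna)
  expect_false(fc3$promoter_upstream)
})

test_that("read classification distinguishes episomes, integrants and host fragments", {
  epi <- data.frame(ref = "vector", ref_start0 = 0L, ref_end0 = 1000L,
                    orientation = "+", read_start0 = 0L, read_end0 = 1000L)
  expect_identical(classify_read(epi)$classification, "vector_only")
  hvh <- data.frame(ref = c("chr1", "vector", "chr1"),
                    ref_start0 = c(0L, 0L, 2000L),
                    ref_end0 = c(500L, 1000L, 2500L),
                    orientation = "+",
                    read_start0 = c(0L, 500L, 1500L),
                    read_end0 = c(500L, 1500L, 2000L))
  c2 <- classify_read(hvh)
  expect_identical(c2$classification, "vector_plus_flank")
  expect_true(c2$both_flanks)
  c3 <- classify_read(hvh[1:2, ])
  expect_identical(c3$classification, "vector_plus_flank")
  expect_false(c3$both_flanks)
  host <- hvh[1, ]
  expect_identical(classify_read(host)$classification, "host_only")
  expect_identical(classify_read(hvh[0, ])$classification, "ambiguous")
  # raising min_flank can only demote flanked reads, never create them
  s <- small_sim()
  st <- annotate_long_reads(s$lr$reads, s$refs$vector, s$refs$host)
  n50 <- sum(st$reads$class == "vector_plus_flank")
  p200 <- longread_params(min_flank = 200L)
  segs_by_read <- split(st$segments, st$segments$read_id)
  n200 <- sum(vapply(segs_by_read, function(g) {
    classify_read(g, p200)$classification == "vector_plus_flank"
  }, logical(1)))
  expect_lte(n200, n50)
})

test_that("flank integrity bookkeeping matches per-op arithmetic", {
  segs <- data.frame(ref = "chr1", ops = "M:60,D:5,M:40")
  fi <- flank_integrity(segs)
  expect_equal(fi$deletion_pct, 100 * 5 / 105)
  expect_equal(fi$match_pct, 100 * 100 / 105)
  expect_equal(fi$insertion_pct, 0)
  # pooling equals length-weighted combination of per-flank op lists
  two <- data.frame(ref = c("chr1", "chr2"),
                    ops = c("M:60,D:5,M:40", "M:95,I:5,M:100"))
  fi2 <- flank_integrity(two)
  expect_equal(fi2$match_pct, 100 * (100 + 195) / (105 + 200))
  expect_equal(fi2$insertion_pct, 100 * 5 / 305)
  expect_true(is.na(flank_integrity(segs[0, ])$match_pct))
})

test_that("cohort summary aggregates flanked-read metrics", {
  s <- small_sim()
  st <- annotate_long_reads(s$lr$reads, s$refs$vector, s$refs$host)
  cs <- summarize_cohort(st)
  expect_identical(cs$total_reads, nrow(st$reads))
  expect_lte(cs$vector_plus_flank, cs$vector_reads)
  expect_lte(cs$vector_reads, cs$total_reads)
  expect_lte(cs$cdna_plus_flank,
             min(cs$functional_cdna, cs$vector_plus_flank))
  flanked <- st$reads[st$reads$class == "vector_plus_flank", ]
  expect_equal(cs$mean_itrs_per_flanked_read, mean(flanked$n_itrs))
  # hand-built cohort: flanked reads with 2 and 3 ITRs average 2.5
  fake <- list(
    reads = data.frame(read_id = c("a", "b", "c"),
                       class = c("vector_plus_flank", "vector_plus_flank",
                                 "vector_only"),
                       n_itrs = c(2L, 3L, 1L), functional_cdna = FALSE),
    segments = data.frame(read_id = character(0), ref = character(0),
                          ops = character(0)),
    itrs = data.frame(read_id = character(0), intact = logical(0),
                      observed_length = integer(0))
  )
  expect_equal(summarize_cohort(fake)$mean_itrs_per_flanked_read, 2.5)
  # an episome-only cohort has no integration evidence
  epi_only <- fake
  epi_only$reads$class <- "vector_only"
  cs2 <- summarize_cohort(epi_only)
  expect_identical(cs2$vector_plus_flank, 0L)
  expect_identical(cs2$cdna_plus_flank, 0L)
})

test_that("segment decomposition recovers planted structures on constructed reads", {
  s <- small_sim()
  vm <- s$refs$vector
  host <- s$refs$host
  idx <- longread_index(vm, host)
  # two full head-to-tail copies
  read <- paste0(vm$sequence, vm$sequence)
  segs <- decompose_read(read, idx)
  expect_identical(nrow(segs), 2L)
  expect_true(all(segs$ref == "vector"))
  expect_true(all(segs$ref_start0 == 0L & segs$ref_end0 == vm$full_length))
  expect_identical(segs$orientation, c("+", "+"))
  # pure host fragment
  hseq <- substr(host$seqs[["chr1"]], 2001, 4000)
  hsegs <- decompose_read(hseq, idx)
  expect_identical(nrow(hsegs), 1L)
  expect_identical(hsegs$ref, "chr1")
  expect_identical(classify_read(hsegs)$classification, "host_only")
  # host flank + one copy + host flank in order
  read3 <- paste0(substr(host$seqs[["chr2"]], 5001, 5600), vm$sequence,
                  substr(host$seqs[["chr2"]], 9001, 9600))
  segs3 <- decompose_read(read3, idx)
  expect_identical(segs3$ref, c("chr2", "vector", "chr2"))
})

test_that("prep-read classification identifies sources and vector truncations", {
  s <- small_sim()
  prefs <- forge_prep_refs(seed = 42L)
  # single-source constructed reads
  lam <- substr(prefs[["lambda"]], 1001, 2500)
  full_vec <- s$refs$vector$sequence
  pc <- classify_prep_read(setNames(c(lam, full_vec), c("r1", "r2")),
                           s$refs$vector, prefs)
  expect_identical(pc$source, c("lambda_spike", "vector_genome"))
  expect_false(pc$truncated[2])
  trunc_vec <- substr(full_vec, 501, nchar(full_vec))
  pc2 <- classify_prep_read(c(rt = trunc_vec), s$refs$vector, prefs)
  expect_true(pc2$truncated)
})
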