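test_that("read-pair parsing enforces the UMI pattern and the ITR anchor", {
  vm <- vector_model(seed = 1L)
  host_tail <- strrep("A", 110)
  good_r1 <- paste0(vm$anchor, substr(vm$sequence, 21, 45), host_tail)
  good_r2 <- paste0("ACGTACGT", "ACTGGTAA", strrep("C", 120))
  p <- parse_read_pair(good_r1, good_r2, vm)
  expect_identical(p$status, "ok")
  expect_identical(p$umi, "ACTGGTAA")

  bad_umi_r2 <- paste0("ACGTACGT", "ACGGGCAA", strrep("C", 120))
  p2 <- parse_read_pair(good_r1, bad_umi_r2, vm)
  expect_identical(p2$status, "umi_invalid")

  no_anchor_r1 <- random_dna_fixture(150, seed = 99L)
  p3 <- parse_read_pair(no_anchor_r1, good_r2, vm)
  expect_identical(p3$status, "no_itr_anchor")
})

test_that("clone collapse follows the shared-adapter-or-shared-UMI closure", {
  # worked example: chained evidence collapses three reads into one clone
  obs <- data.frame(chrom = "chr1", coord0 = 100L, side = "right",
                    adapter_coord0 = c(1200L, 1200L, 1350L, 1500L),
                    umi = c("U1", "U2", "U1", "U3"))
  cs <- collapse_and_count(obs)
  expect_identical(cs$sites$n_clones, 2L)
  expect_identical(cs$sites$n_reads, 4L)
  expect_identical(cs$sites$n_clones,
                   brute_clone_count(obs$adapter_coord0, obs$umi))
  # five reads all sharing adapter and UMI are one clone
  obs2 <- data.frame(chrom = "chr1", coord0 = 100L, side = "right",
                     adapter_coord0 = rep(1200L, 5), umi = rep("U1", 5))
  expect_identical(collapse_and_count(obs2)$sites$n_clones, 1L)
  # randomized cases agree with the naive transitive-closure oracle
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    obs3 <- data.frame(chrom = "chr1", coord0 = 50L, side = "left",
                       adapter_coord0 = sample(1:5, n, replace = TRUE),
                       umi = sample(paste0("U", 1:4), n, replace = TRUE))
    expect_identical(collapse_and_count(obs3)$sites$n_clones,
                     brute_clone_count(obs3$adapter_coord0, obs3$umi))
  }
  expect_identical(nrow(collapse_and_count(obs[0, ])$sites), 0L)
})

test_that("clone counts are invariant to read order and added PCR duplicates", {
  res <- small_callset()
  obs <- res$observations[res$observations$status == "ok", ]
  base <- collapse_and_count(obs)
  set.seed(5)
  perm <- collapse_and_count(obs[sample(nrow(obs)), ])
  expect_identical(base$sites, perm$sites)
  dup_rows <- obs[sample(nrow(obs), 15, replace = TRUE), ]
  aug <- collapse_and_count(rbind(obs, dup_rows))
  expect_identical(base$sites$n_clones, aug$sites$n_clones)
  expect_identical(nrow(base$sites), nrow(aug$sites))
})

test_that("junction location is exact on truth, tolerant to a substitution, and flags ambiguity", {
  s <- small_sim()
  res <- small_callset()
  obs <- res$observations
  tr <- s$sr$truth
  m <- merge(obs[obs$status == "ok", ], tr, by = "read_id")
  expect_true(all(m$coord0 == m$junction_coord0))
  expect_true(all(m$adapter_coord0.x == m$adapter_coord0.y))
  expect_true(all(m$umi.x == m$umi.y))

  # one substitution in the host flank, 90% identity threshold: same call
  r1 <- s$sr$r1[1]
  mid <- nchar(r1) - 30L
  base <- substr(r1, mid, mid)
  substr(r1, mid, mid) <- setdiff(c("A", "C", "G", "T"), base)[1]
  p <- parse_read_pair(r1, s$sr$r2[1], s$refs$vector)
  o <- locate_junctions(p, s$refs$host)
  expect_identical(o$status, "ok")
  expect_identical(o$coord0, obs$coord0[obs$read_id == names(r1)])

  # a host part matching two planted duplicated segments is ambiguous
  seg <- random_dna_fixture(300)
  dup_host <- structure(list(
    seqs = c(chrA = paste0(seg, random_dna_fixture(2000), seg)),
    lengths = c(chrA = 2600L), total_length = 2600L
  ), class = "aav_host_genome")
  vm <- s$refs$vector
  amb_r1 <- paste0(vm$anchor, substr(vm$sequence, 21, 45),
                   substr(seg, 1, 105))
  amb_r2 <- paste0("ACGTACGT", "ACTGGTAA", substr(seg, 106, 239))
  p2 <- parse_read_pair(amb_r1, amb_r2, vm)
  o2 <- locate_junctions(p2, dup_host)
  expect_identical(o2$status, "ambiguous")
})

test_that("per-100-genomes normalization matches closed-form arithmetic", {
  mk <- function(n) {
    collapse_and_count(data.frame(chrom = character(n), coord0 = seq_len(n) * 10L,
                                  side = character(n),
                                  adapter_coord0 = seq_len(n) * 10L + 500L,
                                  umi = character(n)))
  }
  cs <- normalize_per_100_genomes(mk(30L), 100, 6.6)
  expect_equal(cs$genome_equivalents, 100 * 1000 / 6.6)
  expect_equal(cs$per_100_genomes, 30 * 100 / (100 * 1000 / 6.6))
  expect_equal(cs$per_100_genomes, 0.198, tolerance = 1e-3)
  # zero sites give zero frequency
  cs0 <- normalize_per_100_genomes(mk(0L), 100, 6.6)
  expect_identical(cs0$per_100_genomes, 0)
  # doubling the input mass halves the frequency
  expect_equal(normalize_per_100_genomes(mk(30L), 200, 6.6)$per_100_genomes,
               cs$per_100_genomes / 2)
  expect_error(normalize_per_100_genomes(mk(1L), 0, 6.6), "positive")
})

test_that("expansion summary counts expanded sites and clone sizes", {
  fake <- function(nc) {
    structure(list(sites = data.frame(n_clones = nc)), class = "aav_callset")
  }
  s <- expansion_summary(fake(c(1L, 1L, 2L, 3L)))
  expect_equal(s$percent_expanded, 50)
  expect_equal(s$mean_clone_size_of_expanded, 2.5)
  expect_identical(s$largest_clone, 3L)
  s2 <- expansion_summary(fake(c(1L, 1L, 1L)))
  expect_equal(s2$percent_expanded, 0)
  expect_true(is.na(s2$mean_clone_size_of_expanded))
  expect_identical(s2$largest_clone, 1L)
  s3 <- expansion_summary(fake(integer(0)))
  expect_true(is.na(s3$percent_expanded))
})
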