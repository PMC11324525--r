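test_that("expression categories partition the nx axis at 1, 10 and 100", {
  nx <- c(0, 0.999, 1, 9.99, 10, 99.9, 100, 5000)
  expect_identical(as.character(expression_category(nx)),
                   c("not_expressed", "not_expressed", "low", "low",
                     "medium", "medium", "high", "high"))
})

test_that("site annotation uses half-open gene bodies, smallest-interval ties and gene lists", {
  genes <- data.frame(
    gene_id = c("BIGGY", "TP53", "SMALL"),
    chrom = c("chr1", "chr1", "chr1"),
    start0 = c(1000L, 5000L, 1200L),
    end0 = c(3000L, 6000L, 1600L),
    strand = "+"
  )
  expr <- data.frame(gene_id = c("BIGGY", "TP53", "SMALL"),
                     nx = c(150, 0.5, 20))
  sites <- data.frame(
    chrom = "chr1",
    coord0 = c(999L,   # 1 bp left of a gene start: intergenic
               1000L,  # first gene base: genic
               1400L,  # inside both BIGGY and SMALL: smallest wins
               3000L,  # half-open end: intergenic
               5500L)  # inside the TP53 homolog
  )
  a <- annotate_sites(sites, genes, expr, hcc_genes = "TP53")
  expect_identical(a$genic, c(FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_identical(a$gene_id, c(NA, "BIGGY", "SMALL", NA, "TP53"))
  expect_identical(a$category, c(NA, "high", "medium", NA, "not_expressed"))
  expect_identical(a$hcc_hit, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # annotation is invariant to gene-list input order
  a2 <- annotate_sites(sites, genes[c(3, 1, 2), ], expr, hcc_genes = "TP53")
  expect_identical(a, a2)
})

test_that("random loci are deterministic, avoid N runs and follow chromosome lengths", {
  s <- small_sim()
  host <- s$refs$host
  l1 <- random_loci(host, n = 1L, seed = 3L)
  l2 <- random_loci(host, n = 1L, seed = 3L)
  expect_identical(l1, l2)
  loci <- random_loci(host, n = 4000L, seed = 3L)
  base <- mapply(function(ch, p) substr(host$seqs[[ch]], p + 1L, p + 1L),
                 loci$chrom, loci$coord0)
  expect_false(any(base == "N"))
  # per-chromosome counts within 4 SD of the length-proportional expectation
  non_n <- vapply(names(host$seqs), function(ch) {
    sum(charToRaw(host$seqs[[ch]]) != charToRaw("N"))
  }, numeric(1))
  p <- non_n / sum(non_n)
  cnt <- table(factor(loci$chrom, levels = names(host$seqs)))
  z <- (as.numeric(cnt) - 4000 * p) / sqrt(4000 * p * (1 - p))
  expect_true(all(abs(z) <= 4))
})

test_that("fold-change enrichment behaves at the identity and degenerate limits", {
  s <- small_sim()
  gm <- forge_gene_models(s$refs$host, n_genes = 15L, seed = 5L)
  loci <- random_loci(s$refs$host, n = 500L, seed = 8L)
  ann <- annotate_sites(loci, gm$genes, gm$expression)
  # identical site and background sets: every defined fold change is 1
  e <- enrichment(ann, ann)
  defined <- !is.na(e$fold_change)
  expect_true(all(e$fold_change[defined] == 1))
  # category fractions partition the sites
  expect_equal(sum(e$observed_fraction), 1)
  expect_equal(sum(e$background_fraction), 1)
  # categories missing from the background are undefined, not infinite
  exp_zero <- e$background_fraction == 0
  expect_true(all(is.na(e$fold_change[exp_zero])))
  expect_error(enrichment(ann, ann[0, ]), "non-empty")
})

test_that("gene models round-trip through GFF3", {
  s <- small_sim()
  gm <- forge_gene_models(s$refs$host, n_genes = 10L, seed = 2L)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models(gm$genes, path)
  back <- read_gene_models(path)
  ord <- order(back$gene_id)
  ord0 <- order(gm$genes$gene_id)
  expect_identical(back$gene_id[ord], gm$genes$gene_id[ord0])
  expect_identical(back$start0[ord], gm$genes$start0[ord0])
  expect_identical(back$end0[ord], gm$genes$end0[ord0])
})
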