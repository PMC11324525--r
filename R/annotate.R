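# Annotation of integration sites against gene models, liver-expression
# categories and cancer-gene lists, with fold-change enrichment over a
# random-locus background.

EXPRESSION_CATEGORIES <- c("not_expressed", "low", "medium", "high")

#' Liver-expression category from normalized expression (nx)
#'
#' Categories partition the nx axis: not expressed (nx < 1), low
#' (1 <= nx < 10), medium (10 <= nx < 100), high (nx >= 100).
#'
#' @param nx numeric vector of normalized expression values
#' @return factor with levels not_expressed / low / medium / high
#' @examples
#' expression_category(c(0.5, 1, 50, 150))
#' @export
expression_category <- function(nx) {
  cut(nx, breaks = c(-Inf, 1, 10, 100, Inf), right = FALSE,
      labels = EXPRESSION_CATEGORIES)
}

#' Forge toy gene models with liver-expression values
#'
#' Non-overlapping gene intervals are placed on the host genome and assigned
#' nx values so that the four expression categories are represented; a few
#' genes are named after cancer-associated genes so list screens can be
#' exercised.
#'
#' @param host [forge_host_genome()]
#' @param n_genes number of genes
#' @param length_range gene length range (bases)
#' @param seed integer seed
#' @return list with `genes` (data.frame gene_id, chrom, start0, end0,
#'   strand), `expression` (data.frame gene_id, nx, category) and `hcc_genes`
#'   / `mouse_hcc_genes` (character vectors of gene ids present in the toy
#'   annotation)
#' @export
forge_gene_models <- function(host, n_genes = 40L,
                              length_range = c(2000L, 6000L), seed = 1L) {
  hcc_names <- c("TP53", "TERT", "CTNNB1", "AXIN1", "ARID1A")
  mouse_names <- c("DLK1", "TAX1BP1", "HRAS", "SOS1", "MEG8")
  with_seed(seed + 5L, {
    placed <- list()
    tries <- 0L
    while (length(placed) < n_genes && tries < 50L * n_genes) {
      tries <- tries + 1L
      chrom <- sample(names(host$seqs), 1L, prob = host$lengths)
      len <- sample(length_range[1]:length_range[2], 1L)
      s <- sample.int(host$lengths[[chrom]] - len, 1L) - 1L
      ok <- TRUE
      for (g in placed) {
        if (g$chrom == chrom && s < g$end0 && g$start0 < s + len) {
          ok <- FALSE
          break
        }
      }
      if (ok) placed[[length(placed) + 1L]] <- list(chrom = chrom,
                                                    start0 = s, end0 = s + len)
    }
    if (length(placed) < n_genes) stop("cannot place non-overlapping genes")
    n <- length(placed)
    ids <- sprintf("GENE%03d", seq_len(n))
    # name a few genes after the screened cancer genes (as many as fit)
    special <- head(c(hcc_names, mouse_names), n)
    ids[seq_along(special)] <- special
    genes <- data.frame(
      gene_id = ids,
      chrom = vapply(placed, `[[`, "", "chrom"),
      start0 = vapply(placed, `[[`, 0L, "start0"),
      end0 = vapply(placed, `[[`, 0L, "end0"),
      strand = sample(c("+", "-"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    # nx values spread across the four categories
    cat_draw <- sample(EXPRESSION_CATEGORIES, n, replace = TRUE)
    nx <- vapply(cat_draw, function(cc) {
      switch(cc,
        not_expressed = runif(1, 0, 1),
        low = runif(1, 1, 10),
        medium = runif(1, 10, 100),
        high = runif(1, 100, 1000))
    }, numeric(1))
    expr <- data.frame(gene_id = ids, nx = nx,
                       category = as.character(expression_category(nx)),
                       stringsAsFactors = FALSE)
    list(genes = genes, expression = expr,
         hcc_genes = hcc_names, mouse_hcc_genes = mouse_names)
  })
}

genes_to_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start0 + 1L, end = genes$end0),
    gene_id = genes$gene_id
  )
}

#' Annotate integration sites against gene models and gene lists
#'
#' A site is genic when its coordinate falls inside a gene body (0-based
#' half-open intervals); among overlapping genes the smallest containing
#' interval wins, ties broken by gene id. Genic sites are assigned the
#' liver-expression category of their gene and screened against the
#' HCC-associated and mouse-HCC gene lists.
#'
#' @param sites data.frame with columns chrom and coord0 (e.g. the `sites`
#'   of a call set, or [random_loci()] output)
#' @param genes gene data.frame (gene_id, chrom, start0, end0, strand)
#' @param expression data.frame (gene_id, nx) or (gene_id, nx, category)
#' @param hcc_genes,mouse_hcc_genes character vectors of gene ids
#' @param flank_bp optional extension of gene bodies on both sides
#' @return the input data.frame with columns genic, gene_id, category,
#'   hcc_hit, mouse_hcc_hit appended
#' @export
annotate_sites <- function(sites, genes, expression,
                           hcc_genes = character(0),
                           mouse_hcc_genes = character(0),
                           flank_bp = 0L) {
  out <- sites
  out$genic <- FALSE
  out$gene_id <- NA_character_
  out$category <- NA_character_
  out$hcc_hit <- FALSE
  out$mouse_hcc_hit <- FALSE
  if (!nrow(sites)) return(out)
  # deterministic order regardless of gene-list input order
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  gr <- genes_to_granges(genes)
  if (flank_bp > 0L) {
    gr <- GenomicRanges::resize(gr, GenomicRanges::width(gr) + 2L * flank_bp,
                                fix = "center")
  }
  sg <- GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$coord0 + 1L, width = 1L)
  )
  hits <- suppressWarnings(GenomicRanges::findOverlaps(sg, gr))
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    w <- GenomicRanges::width(gr)[sh]
    # smallest containing interval wins, then lexicographic gene id
    ord <- order(qh, w, genes$gene_id[sh])
    first <- !duplicated(qh[ord])
    qsel <- qh[ord][first]
    gsel <- sh[ord][first]
    out$genic[qsel] <- TRUE
    out$gene_id[qsel] <- genes$gene_id[gsel]
  }
  expr_cat <- if ("category" %in% names(expression)) {
    setNames(as.character(expression$category), expression$gene_id)
  } else {
    setNames(as.character(expression_category(expression$nx)),
             expression$gene_id)
  }
  has_expr <- out$genic & out$gene_id %in% names(expr_cat)
  out$category[has_expr] <- expr_cat[out$gene_id[has_expr]]
  out$hcc_hit <- out$genic & out$gene_id %in% hcc_genes
  out$mouse_hcc_hit <- out$genic & out$gene_id %in% mouse_hcc_genes
  out
}

#' Random genomic loci as an annotation background
#'
#' Draws loci uniformly over non-N host positions (chromosome chosen
#' proportional to its non-N length, position uniform within it), with
#' replacement, deterministic under the seed.
#'
#' @param host [forge_host_genome()]
#' @param n number of loci (the reference analysis uses 10,000)
#' @param seed integer seed
#' @return data.frame (chrom, coord0)
#' @export
random_loci <- function(host, n = 10000L, seed = 1L) {
  stopifnot(n >= 1L)
  ok_pos <- lapply(names(host$seqs), function(ch) which(non_n_mask(host, ch)) - 1L)
  names(ok_pos) <- names(host$seqs)
  if (!sum(lengths(ok_pos))) stop("host genome contains no non-N positions")
  with_seed(seed + 6L, {
    ch <- sample(names(ok_pos), n, replace = TRUE, prob = lengths(ok_pos))
    pos <- vapply(ch, function(cc) {
      ok_pos[[cc]][sample.int(length(ok_pos[[cc]]), 1L)]
    }, integer(1))
    data.frame(chrom = ch, coord0 = pos, row.names = NULL,
               stringsAsFactors = FALSE)
  })
}

#' Fold-change enrichment of site annotation categories over background
#'
#' For every category (intergenic plus the four genic expression
#' categories, and genic sites without an expression entry) the fold change
#' is the fraction of sites in the category divided by the fraction of
#' background loci in it. Categories absent from the background are
#' reported as `NA` (undefined), not infinity.
#'
#' @param sites_annotated,background_annotated outputs of [annotate_sites()]
#' @return list of class `aav_enrichment`: per-category observed and
#'   background fractions and fold changes, plus `n_sites` and `n_background`
#' @export
enrichment <- function(sites_annotated, background_annotated) {
  if (!nrow(background_annotated)) stop("background must be non-empty")
  cat_of <- function(a) {
    ifelse(!a$genic, "intergenic",
           ifelse(is.na(a$category), "genic_unscored", a$category))
  }
  levels_all <- c("intergenic", EXPRESSION_CATEGORIES, "genic_unscored")
  sc <- factor(cat_of(sites_annotated), levels = levels_all)
  bc <- factor(cat_of(background_annotated), levels = levels_all)
  n_s <- nrow(sites_annotated)
  obs <- if (n_s) as.numeric(table(sc)) / n_s else rep(NA_real_, length(levels_all))
  bg <- as.numeric(table(bc)) / nrow(background_annotated)
  fc <- ifelse(bg > 0, obs / bg, NA_real_)
  structure(list(
    categories = levels_all,
    observed_fraction = setNames(obs, levels_all),
    background_fraction = setNames(bg, levels_all),
    fold_change = setNames(fc, levels_all),
    n_sites = n_s,
    n_background = nrow(background_annotated)
  ), class = "aav_enrichment")
}

#' @export
print.aav_enrichment <- function(x, ...) {
  cat(sprintf("Enrichment over %d background loci (%d sites)\n",
              x$n_background, x$n_sites))
  df <- data.frame(category = x$categories,
                   observed = round(x$observed_fraction, 4),
                   background = round(x$background_fraction, 4),
                   fold_change = round(x$fold_change, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

# ---- gene model IO -------------------------------------------------------

#' Write toy gene models as GFF3
#'
#' @param genes gene data.frame (gene_id, chrom, start0, end0, strand)
#' @param path output path
#' @return invisible path
#' @export
write_gene_models <- function(genes, path) {
  gr <- genes_to_granges(genes)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  GenomicRanges::strand(gr) <- genes$strand
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3 or BED
#'
#' @param path GFF3 (type `gene` features) or BED file
#' @return gene data.frame (gene_id, chrom, start0, end0, strand)
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  if ("type" %in% names(md)) gr <- gr[md$type == "gene"]
  md <- S4Vectors::mcols(gr)
  ids <- if ("gene_id" %in% names(md)) md$gene_id
         else if ("ID" %in% names(md)) md$ID
         else if ("name" %in% names(md)) md$name
         else sprintf("GENE%03d", seq_along(gr))
  data.frame(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start0 = GenomicRanges::start(gr) - 1L,
    end0 = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}
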