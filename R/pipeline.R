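# Pipeline orchestration: validated run configuration, stage execution with
# persisted artifacts, and a combined per-sample report.

#' Default run configuration
#'
#' @param sample_id sample label
#' @param seed integer seed propagated to every stochastic stage
#' @param out_dir output directory
#' @return nested configuration list
#' @export
run_config <- function(sample_id = "sample", seed = 1L, out_dir = "aavint_run") {
  list(
    sample_id = sample_id,
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = list(simulate = TRUE, itrseq = TRUE, annotation = TRUE,
                  longread = TRUE),
    inputs = list(host_fasta = NULL, r1_fastq = NULL, r2_fastq = NULL,
                  long_reads_fasta = NULL, genes_gff3 = NULL,
                  expression_tsv = NULL),
    sim = list(),
    itrseq = list(input_dna_ng = 100, genome_mass_pg = 6.6, window = 0L,
                  dup_pos_tolerance = 0L),
    annotation = list(n_genes = 40L, n_random = 10000L, flank_bp = 0L),
    longread = list()
  )
}

#' Validate a run configuration
#'
#' Accepts a configuration list or the path of a YAML file; fills defaults,
#' rejects unknown keys, and type/range-checks every parameter. All
#' violations are reported together.
#'
#' @param config configuration list or YAML path
#' @return the validated configuration with defaults filled in
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- run_config()
  errs <- character(0)
  bad_top <- setdiff(names(config), names(defaults))
  if (length(bad_top)) {
    errs <- c(errs, sprintf("unknown key '%s'", bad_top))
  }
  for (blk in c("stages", "inputs", "sim", "itrseq", "annotation", "longread")) {
    if (!is.null(config[[blk]])) {
      known <- if (blk == "sim") names(formals(sim_config))
               else if (blk == "longread") names(formals(longread_params))
               else names(defaults[[blk]])
      bad <- setdiff(names(config[[blk]]), known)
      if (length(bad)) {
        errs <- c(errs, sprintf("%s: unknown key '%s'", blk, bad))
      }
    }
  }
  cfg <- modifyList(defaults, config, keep.null = TRUE)
  chk <- function(cond, path, msg) {
    if (!cond) errs <<- c(errs, sprintf("%s: %s", path, msg))
  }
  chk(is.numeric(cfg$seed) && cfg$seed == floor(cfg$seed), "seed",
      "must be an integer")
  chk(is.character(cfg$sample_id) && nzchar(cfg$sample_id), "sample_id",
      "must be a non-empty string")
  for (st in names(cfg$stages)) {
    chk(is.logical(cfg$stages[[st]]), paste0("stages.", st),
        "must be TRUE or FALSE")
  }
  if (!is.null(cfg$sim$n_events)) {
    chk(cfg$sim$n_events >= 0, "sim.n_events", "must be non-negative")
  }
  if (!is.null(cfg$sim$n_long_reads)) {
    chk(cfg$sim$n_long_reads >= 0, "sim.n_long_reads", "must be non-negative")
  }
  if (!is.null(cfg$sim$substitution_error_rate)) {
    chk(cfg$sim$substitution_error_rate >= 0 &&
          cfg$sim$substitution_error_rate <= 1,
        "sim.substitution_error_rate", "must lie in [0, 1]")
  }
  chk(cfg$itrseq$input_dna_ng > 0, "itrseq.input_dna_ng", "must be positive")
  chk(cfg$itrseq$genome_mass_pg > 0, "itrseq.genome_mass_pg",
      "must be positive")
  chk(cfg$annotation$n_random >= 1, "annotation.n_random", "must be >= 1")
  chk(cfg$annotation$n_genes >= 1, "annotation.n_genes", "must be >= 1")
  if (isFALSE(cfg$stages$simulate)) {
    if (isTRUE(cfg$stages$itrseq)) {
      chk(!is.null(cfg$inputs$host_fasta), "inputs.host_fasta",
          "required when the simulate stage is disabled")
      chk(!is.null(cfg$inputs$r1_fastq) && !is.null(cfg$inputs$r2_fastq),
          "inputs.r1_fastq", "required when the simulate stage is disabled")
    }
    if (isTRUE(cfg$stages$longread)) {
      chk(!is.null(cfg$inputs$host_fasta), "inputs.host_fasta",
          "required when the simulate stage is disabled")
      chk(!is.null(cfg$inputs$long_reads_fasta), "inputs.long_reads_fasta",
          "required when the simulate stage is disabled")
    }
  }
  if (length(errs)) {
    stop("invalid run configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }
  cfg
}

# canonical hash of a configuration (used for idempotent stage skipping)
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE, na = "null")
  unname(tools::md5sum(tmp))
}

stage_done <- function(dir, hash) {
  marker <- file.path(dir, ".done.json")
  if (!file.exists(marker)) return(FALSE)
  ok <- tryCatch(identical(jsonlite::read_json(marker)$hash, hash),
                 error = function(e) FALSE)
  isTRUE(ok)
}

mark_done <- function(dir, hash) {
  jsonlite::write_json(list(hash = hash), file.path(dir, ".done.json"),
                       auto_unbox = TRUE)
}

#' Write all synthetic-data artifacts for one sample
#'
#' Forges references, plants events, emits ITR-seq read pairs and long
#' reads, forges gene models and expression, and writes everything under
#' `out_dir`: FASTA references, gzipped FASTQ pairs, a long-read FASTA,
#' truth TSVs (`events.tsv`, `copies.tsv`, `reads_truth.tsv`,
#' `longreads_truth.tsv` plus segment and ITR tables), GFF3 gene models,
#' the expression table, gene lists and a JSON manifest.
#'
#' @param config [sim_config()]
#' @param out_dir output directory
#' @param n_genes number of toy genes
#' @return invisible list of the in-memory objects and file paths
#' @export
simulate_sample <- function(config, out_dir, n_genes = 40L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  refs <- forge_references(config, out_dir = out_dir)
  ev <- plant_events(refs$host, refs$vector, config)
  sr <- make_itrseq_reads(ev, refs$host, refs$vector, config)
  lr <- make_long_reads(ev, refs$host, refs$vector, config)
  gm <- forge_gene_models(refs$host, n_genes = n_genes, seed = config$seed)
  p <- function(f) file.path(out_dir, f)
  wt <- function(df, f) {
    write.table(df, p(f), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(ev$events, "events.tsv")
  wt(ev$copies, "copies.tsv")
  wt(sr$truth, "reads_truth.tsv")
  wt(lr$reads_truth, "longreads_truth.tsv")
  wt(lr$segments_truth, "longreads_segments_truth.tsv")
  wt(lr$itrs_truth, "longreads_itrs_truth.tsv")
  wt(gm$expression, "expression.tsv")
  write_fastq(unname(sr$r1), names(sr$r1), p("reads_R1.fastq.gz"))
  write_fastq(unname(sr$r2), names(sr$r2), p("reads_R2.fastq.gz"))
  write_fasta(as.list(lr$reads), p("long_reads.fasta"))
  write_gene_models(gm$genes, p("genes.gff3"))
  writeLines(gm$hcc_genes, p("hcc_genes.txt"))
  writeLines(gm$mouse_hcc_genes, p("mouse_hcc_genes.txt"))
  manifest <- list(
    seed = config$seed, n_events = config$n_events,
    n_read_pairs = length(sr$r1), n_long_reads = length(lr$reads),
    n_genes = n_genes,
    files = c("host.fasta", "vector.fasta", "events.tsv", "copies.tsv",
              "reads_R1.fastq.gz", "reads_R2.fastq.gz", "reads_truth.tsv",
              "long_reads.fasta", "longreads_truth.tsv",
              "longreads_segments_truth.tsv", "longreads_itrs_truth.tsv",
              "genes.gff3", "expression.tsv", "hcc_genes.txt",
              "mouse_hcc_genes.txt")
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(refs = refs, events = ev, short_reads = sr, long_reads = lr,
                 gene_models = gm))
}

#' Run the full simulate / call / annotate / long-read pipeline
#'
#' Stages run in dependency order; each stage persists its artifacts under
#' `out_dir/<stage>/` and is skipped on re-runs when its outputs are present
#' and the configuration is unchanged (unless `force`). The combined report
#' (`report.json`, `report.tsv`) is assembled from the persisted stage
#' summaries only, and contains no timestamps, so identical configurations
#' and seeds give byte-identical reports.
#'
#' @param config run configuration (validated with [validate_config()])
#' @param force re-run stages even when outputs are up to date
#' @param quiet suppress progress messages
#' @return invisible report list
#' @export
run_pipeline <- function(config, force = FALSE, quiet = FALSE) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  scfg <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))
  vec <- vector_model(seed = cfg$seed + 1L)
  lparams <- do.call(longread_params, cfg$longread)
  sim_dir <- file.path(cfg$out_dir, "sim")
  itr_dir <- file.path(cfg$out_dir, "itrseq")
  ann_dir <- file.path(cfg$out_dir, "annotation")
  lr_dir <- file.path(cfg$out_dir, "longread")

  if (isTRUE(cfg$stages$simulate)) {
    h <- config_hash(list(seed = cfg$seed, sim = cfg$sim,
                          n_genes = cfg$annotation$n_genes))
    if (force || !stage_done(sim_dir, h)) {
      t0 <- Sys.time()
      simulate_sample(scfg, sim_dir, n_genes = cfg$annotation$n_genes)
      mark_done(sim_dir, h)
      say("simulate: done in %.1fs", as.numeric(Sys.time() - t0, "secs"))
    } else {
      say("simulate: up to date, skipped")
    }
  }

  host_fasta <- if (isTRUE(cfg$stages$simulate)) file.path(sim_dir, "host.fasta")
                else cfg$inputs$host_fasta
  host <- NULL
  get_host <- function() {
    if (is.null(host)) {
      seqs <- read_fasta(host_fasta)
      host <<- structure(list(seqs = seqs, lengths = nchar(seqs),
                              total_length = sum(nchar(seqs))),
                         class = "aav_host_genome")
    }
    host
  }

  if (isTRUE(cfg$stages$itrseq)) {
    h <- config_hash(list(seed = cfg$seed, sim = cfg$sim, itr = cfg$itrseq))
    if (force || !stage_done(itr_dir, h)) {
      t0 <- Sys.time()
      r1 <- if (isTRUE(cfg$stages$simulate)) file.path(sim_dir, "reads_R1.fastq.gz")
            else cfg$inputs$r1_fastq
      r2 <- if (isTRUE(cfg$stages$simulate)) file.path(sim_dir, "reads_R2.fastq.gz")
            else cfg$inputs$r2_fastq
      ip <- itrseq_params(window = cfg$itrseq$window,
                          dup_pos_tolerance = cfg$itrseq$dup_pos_tolerance)
      res <- call_itrseq(r1, r2, get_host(), vec, ip,
                         sample_id = cfg$sample_id,
                         input_dna_ng = cfg$itrseq$input_dna_ng,
                         genome_mass_pg = cfg$itrseq$genome_mass_pg)
      write_callset(res$callset, itr_dir)
      mark_done(itr_dir, h)
      say("itrseq: %d sites in %.1fs", nrow(res$callset$sites),
          as.numeric(Sys.time() - t0, "secs"))
    } else {
      say("itrseq: up to date, skipped")
    }
  }

  if (isTRUE(cfg$stages$annotation)) {
    h <- config_hash(list(seed = cfg$seed, sim = cfg$sim, itr = cfg$itrseq,
                          ann = cfg$annotation))
    if (force || !stage_done(ann_dir, h)) {
      t0 <- Sys.time()
      dir.create(ann_dir, recursive = TRUE, showWarnings = FALSE)
      sites <- read.delim(file.path(itr_dir, "sites.tsv"),
                          stringsAsFactors = FALSE)
      genes <- if (isTRUE(cfg$stages$simulate)) {
        read_gene_models(file.path(sim_dir, "genes.gff3"))
      } else {
        read_gene_models(cfg$inputs$genes_gff3)
      }
      expr <- if (isTRUE(cfg$stages$simulate)) {
        read.delim(file.path(sim_dir, "expression.tsv"),
                   stringsAsFactors = FALSE)
      } else {
        read.delim(cfg$inputs$expression_tsv, stringsAsFactors = FALSE)
      }
      hcc <- if (isTRUE(cfg$stages$simulate))
        readLines(file.path(sim_dir, "hcc_genes.txt")) else character(0)
      mouse <- if (isTRUE(cfg$stages$simulate))
        readLines(file.path(sim_dir, "mouse_hcc_genes.txt")) else character(0)
      ann <- annotate_sites(sites, genes, expr, hcc, mouse,
                            flank_bp = cfg$annotation$flank_bp)
      bg <- random_loci(get_host(), n = cfg$annotation$n_random,
                        seed = cfg$seed)
      bg_ann <- annotate_sites(bg, genes, expr, hcc, mouse,
                               flank_bp = cfg$annotation$flank_bp)
      enr <- enrichment(ann, bg_ann)
      write.table(ann, file.path(ann_dir, "annotated_sites.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(list(
        fold_change = as.list(enr$fold_change),
        observed_fraction = as.list(enr$observed_fraction),
        background_fraction = as.list(enr$background_fraction),
        n_sites = enr$n_sites, n_background = enr$n_background,
        n_hcc_hits = sum(ann$hcc_hit), n_mouse_hcc_hits = sum(ann$mouse_hcc_hit)
      ), file.path(ann_dir, "enrichment.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE, na = "null")
      mark_done(ann_dir, h)
      say("annotation: done in %.1fs", as.numeric(Sys.time() - t0, "secs"))
    } else {
      say("annotation: up to date, skipped")
    }
  }

  if (isTRUE(cfg$stages$longread)) {
    h <- config_hash(list(seed = cfg$seed, sim = cfg$sim, lr = cfg$longread))
    if (force || !stage_done(lr_dir, h)) {
      t0 <- Sys.time()
      dir.create(lr_dir, recursive = TRUE, showWarnings = FALSE)
      lr_path <- if (isTRUE(cfg$stages$simulate))
        file.path(sim_dir, "long_reads.fasta") else cfg$inputs$long_reads_fasta
      reads <- read_fasta(lr_path)
      structures <- annotate_long_reads(reads, vec, get_host(), lparams)
      cohort <- summarize_cohort(structures)
      write.table(structures$reads, file.path(lr_dir, "read_structures.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(structures$segments, file.path(lr_dir, "segments.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(structures$itrs, file.path(lr_dir, "itrs.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(unclass(cohort), file.path(lr_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           na = "null")
      mark_done(lr_dir, h)
      say("longread: %d reads in %.1fs", length(reads),
          as.numeric(Sys.time() - t0, "secs"))
    } else {
      say("longread: up to date, skipped")
    }
  }

  report <- assemble_report(cfg)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  write_report_tsv(report, file.path(cfg$out_dir, "report.tsv"))
  invisible(report)
}

# the report is assembled from persisted stage summaries only
assemble_report <- function(cfg) {
  rep <- list(sample_id = cfg$sample_id,
              provenance = list(
                package_version = as.character(utils::packageVersion("aavint")),
                seed = cfg$seed,
                # hash of the analysis parameters only: output locations and
                # input paths do not affect the result
                config_hash = config_hash(cfg[setdiff(names(cfg),
                                                      c("out_dir", "inputs"))])
              ))
  itr_json <- file.path(cfg$out_dir, "itrseq", "summary.json")
  if (file.exists(itr_json)) {
    rep$itrseq <- jsonlite::read_json(itr_json)
  }
  ann_json <- file.path(cfg$out_dir, "annotation", "enrichment.json")
  if (file.exists(ann_json)) {
    rep$annotation <- jsonlite::read_json(ann_json)
  }
  lr_json <- file.path(cfg$out_dir, "longread", "summary.json")
  if (file.exists(lr_json)) {
    rep$longread <- jsonlite::read_json(lr_json)
  }
  rep
}

write_report_tsv <- function(report, path) {
  rows <- list()
  add <- function(name, value) {
    rows[[length(rows) + 1L]] <<- data.frame(metric = name,
                                             value = as.character(value))
  }
  if (!is.null(report$longread)) {
    lr <- report$longread
    add("Total", lr$total_reads)
    add("Vector", lr$vector_reads)
    add("Vector + flank (confirmed integrated)", lr$vector_plus_flank)
    add("Average no. ITRs per read", lr$mean_itrs_per_flanked_read)
    add("Functional cDNA", lr$functional_cdna)
    add("cDNA + flank (confirmed integrated)", lr$cdna_plus_flank)
  }
  if (!is.null(report$itrseq)) {
    add("Short-read sequencing, number of unique integration sites per 100 cells",
        report$itrseq$per_100_genomes)
    add("aavint.itrseq.n_sites", report$itrseq$n_sites)
    add("aavint.itrseq.percent_expanded", report$itrseq$percent_expanded)
  }
  if (!is.null(report$annotation)) {
    add("aavint.annotation.n_hcc_hits", report$annotation$n_hcc_hits)
  }
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
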