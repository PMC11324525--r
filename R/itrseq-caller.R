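# ITR-seq junction calling: anchored read-pair parsing, host mapping,
# unique-junction collapse with clone/PCR-duplicate separation, and
# per-100-genomes normalization.

#' Parameters for ITR-seq calling
#'
#' @param k seed k-mer length for host mapping
#' @param anchor_max_mismatch mismatches tolerated in the ITR primer anchor
#' @param min_identity minimum host alignment identity
#' @param min_host minimum mappable host bases per read part
#' @param max_fragment maximum ITR-to-adapter distance (bases)
#' @param window junction grouping window (0 = exact coordinate)
#' @param dup_pos_tolerance adapter-position tolerance when calling PCR
#'   duplicates (0 = exact)
#' @param barcode_length,umi_length adapter layout on read 2
#' @return list of class `aav_itrseq_params`
#' @export
itrseq_params <- function(k = 21L, anchor_max_mismatch = 2L,
                          min_identity = 0.9, min_host = 25L,
                          max_fragment = 2000L, window = 0L,
                          dup_pos_tolerance = 0L, barcode_length = 8L,
                          umi_length = 8L) {
  structure(list(k = as.integer(k),
                 anchor_max_mismatch = as.integer(anchor_max_mismatch),
                 min_identity = min_identity, min_host = as.integer(min_host),
                 max_fragment = as.integer(max_fragment),
                 window = as.integer(window),
                 dup_pos_tolerance = as.integer(dup_pos_tolerance),
                 barcode_length = as.integer(barcode_length),
                 umi_length = as.integer(umi_length)),
            class = "aav_itrseq_params")
}

#' Parse anchored-PCR read pairs
#'
#' Read 2 must start with the sample barcode followed by an 8-base UMI of
#' the form NNWNNWNN; read 1 must start with the ITR primer anchor (within
#' the configured mismatch tolerance), followed by residual ITR sequence and
#' the host flank. The residual ITR is split off by tolerant extension along
#' the vector's ITR sequence.
#'
#' @param r1,r2 character vectors of read sequences (pair order aligned)
#' @param vector [vector_model()] supplying the anchor and ITR sequence
#' @param params [itrseq_params()]
#' @return data.frame (read_id, status, umi, barcode, itr_residual_length,
#'   host_part_r1, host_part_r2); status is `ok` or a rejection reason
#'   (`umi_invalid`, `no_itr_anchor`, `too_short`)
#' @examples
#' vm <- vector_model(seed = 1)
#' r1 <- paste0(vm$anchor, substr(vm$sequence, 21, 45),
#'              paste(rep("A", 60), collapse = ""))
#' r2 <- paste0("ACGTACGT", "ACTGGTAA", paste(rep("C", 60), collapse = ""))
#' parse_read_pair(r1, r2, vm)$status
#' @export
parse_read_pair <- function(r1, r2, vector, params = itrseq_params()) {
  n <- length(r1)
  stopifnot(length(r2) == n)
  ids <- names(r1)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_len(n))
  bl <- params$barcode_length; ul <- params$umi_length
  anchor <- vector$anchor
  al <- nchar(anchor)
  itr_ref_raw <- charToRaw(vector$sequence)
  status <- rep("ok", n)
  umi <- substr(r2, bl + 1L, bl + ul)
  barcode <- substr(r2, 1L, bl)
  itr_res <- rep(NA_integer_, n)
  h1 <- rep(NA_character_, n); h2 <- rep(NA_character_, n)
  min_len <- al + params$min_host
  too_short <- nchar(r1) < min_len | nchar(r2) < bl + ul + params$min_host
  status[too_short] <- "too_short"
  bad_umi <- status == "ok" & !valid_umi(umi)
  status[bad_umi] <- "umi_invalid"
  check <- which(status == "ok")
  anchor_obs <- substr(r1, 1L, al)
  for (i in check) {
    if (mismatch_count(anchor_obs[i], anchor) > params$anchor_max_mismatch) {
      status[i] <- "no_itr_anchor"
      next
    }
    rr <- charToRaw(r1[i])
    # walk the residual ITR along the vector sequence after the anchor; a
    # mismatch is crossed only on near-perfect continuation (a sequencing
    # error inside the ITR), never at the host junction
    nres <- extend_match(rr, itr_ref_raw, al + 1L, al + 1L, 1L, 1L,
                         min_look_match = 9L)
    itr_res[i] <- nres
    host1 <- substr(r1[i], al + nres + 1L, nchar(r1[i]))
    if (nchar(host1) < params$min_host) {
      status[i] <- "too_short"
      next
    }
    h1[i] <- host1
    h2[i] <- substr(r2[i], bl + ul + 1L, nchar(r2[i]))
  }
  data.frame(read_id = ids, status = status, umi = umi, barcode = barcode,
             itr_residual_length = itr_res, host_part_r1 = h1,
             host_part_r2 = h2, stringsAsFactors = FALSE, row.names = NULL)
}

# ---- host mapping --------------------------------------------------------

# seed index for short-read mapping
shortread_index <- function(host, k) {
  list(index = kmer_index(host$seqs, k),
       raws = lapply(host$seqs, charToRaw),
       k = k)
}

# Map one query to the host: unique best placement with mismatch counting.
# Returns list(status, chrom, strand, start0, mm) where status is one of
# ok / ambiguous / unmappable.
map_query <- function(query, sri, params) {
  k <- sri$k
  L <- nchar(query)
  if (L < k) return(list(status = "unmappable"))
  cands <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else revcomp(query)
    seeds <- seq_kmers(q, k, stride = k)
    hit <- sri$index[seeds, on = "kmer", nomatch = NULL,
                     allow.cartesian = TRUE]
    if (nrow(hit)) {
      hit <- unique(data.table::data.table(ref = hit$ref,
                                           start0 = hit$rpos0 - hit$pos0))
      hit <- hit[hit$start0 >= 0, ]
      if (nrow(hit)) {
        hit$strand <- strand
        cands[[strand]] <- hit
      }
    }
  }
  if (!length(cands)) return(list(status = "unmappable"))
  cands <- data.table::rbindlist(cands)
  cands <- unique(cands)
  best_mm <- Inf; best <- NULL; n_best <- 0L
  max_mm <- floor((1 - params$min_identity) * L)
  for (i in seq_len(nrow(cands))) {
    ref <- cands$ref[i]; s0 <- cands$start0[i]
    rw <- sri$raws[[ref]]
    if (s0 + L > length(rw)) next
    qs <- if (cands$strand[i] == "+") query else revcomp(query)
    mm <- sum(charToRaw(qs) != rw[(s0 + 1L):(s0 + L)])
    if (mm > max_mm) next
    if (mm < best_mm) {
      best_mm <- mm; best <- cands[i, ]; n_best <- 1L
    } else if (mm == best_mm) {
      n_best <- n_best + 1L
    }
  }
  if (is.null(best)) return(list(status = "unmappable"))
  if (n_best > 1L) return(list(status = "ambiguous"))
  list(status = "ok", chrom = best$ref, strand = best$strand,
       start0 = best$start0, mm = best_mm, len = L)
}

#' Locate ITR-genome and adapter-genome junctions for parsed read pairs
#'
#' The read-1 host part is aligned to the host genome; its junction-adjacent
#' end gives the ITR-genome junction coordinate and the side of the host
#' flank relative to the vector. The read-2 host part gives the
#' adapter-genome (shear) coordinate. Reads whose host parts map to multiple
#' equally scoring placements are flagged ambiguous; sub-threshold
#' alignments are unmappable; discordant pairs (different chromosome,
#' inconsistent strands, or implausible fragment span) are rejected.
#'
#' @param parsed output of [parse_read_pair()]
#' @param host [forge_host_genome()]
#' @param params [itrseq_params()]
#' @return data.frame of junction observations (read_id, status, chrom,
#'   coord0, side, adapter_coord0, umi, itr_residual_length)
#' @export
locate_junctions <- function(parsed, host, params = itrseq_params()) {
  sri <- shortread_index(host, params$k)
  n <- nrow(parsed)
  out <- data.frame(read_id = parsed$read_id,
                    status = parsed$status,
                    chrom = NA_character_, coord0 = NA_integer_,
                    side = NA_character_, adapter_coord0 = NA_integer_,
                    umi = parsed$umi,
                    itr_residual_length = parsed$itr_residual_length,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (parsed$status[i] != "ok") next
    m1 <- map_query(parsed$host_part_r1[i], sri, params)
    if (m1$status != "ok") {
      out$status[i] <- if (m1$status == "ambiguous") "ambiguous" else "unmappable"
      next
    }
    m2 <- map_query(parsed$host_part_r2[i], sri, params)
    if (m2$status != "ok") {
      out$status[i] <- if (m2$status == "ambiguous") "ambiguous" else "unmappable"
      next
    }
    if (m1$chrom != m2$chrom || m1$strand == m2$strand) {
      out$status[i] <- "discordant"
      next
    }
    if (m1$strand == "+") {
      coord <- m1$start0; side <- "right"
    } else {
      coord <- m1$start0 + m1$len; side <- "left"
    }
    adapter <- if (m2$strand == "+") m2$start0 else m2$start0 + m2$len
    if (abs(coord - adapter) > params$max_fragment) {
      out$status[i] <- "discordant"
      next
    }
    out$chrom[i] <- m1$chrom
    out$coord0[i] <- coord
    out$side[i] <- side
    out$adapter_coord0[i] <- adapter
  }
  out
}

# ---- collapse and count --------------------------------------------------

# union-find
uf_new <- function(n) seq_len(n)
uf_find <- function(uf, i) {
  while (uf[i] != i) {
    uf[i] <- uf[uf[i]]
    i <- uf[i]
  }
  i
}

#' Collapse junction observations into unique sites with clone counts
#'
#' Observations are grouped by ITR junction (chromosome, coordinate within
#' `window`, side). Within a group, two reads are PCR duplicates of one
#' another when they share the adapter position (within `dup_pos_tolerance`)
#' or share the UMI; cell clones are the connected components of that
#' relation, the unique order-free closure of the pairwise duplicate rule.
#'
#' @param observations data.frame from [locate_junctions()] (rows with
#'   status `ok` are used) or any data.frame with columns chrom, coord0,
#'   side, adapter_coord0, umi
#' @param params [itrseq_params()]
#' @param sample_id sample label stored on the call set
#' @return object of class `aav_callset`: list with `sites` (data.frame
#'   chrom, coord0, side, n_reads, n_clones, per_100_genomes), `sample_id`,
#'   `genome_equivalents` (NA until normalized), `per_100_genomes` and
#'   `params`
#' @examples
#' obs <- data.frame(chrom = "chr1", coord0 = 100, side = "right",
#'                   adapter_coord0 = c(1200, 1200, 1350, 1500),
#'                   umi = c("U1", "U2", "U1", "U3"))
#' collapse_and_count(obs)$sites$n_clones  # 2
#' @export
collapse_and_count <- function(observations, params = itrseq_params(),
                               sample_id = "sample") {
  obs <- observations
  if ("status" %in% names(obs)) obs <- obs[obs$status == "ok", , drop = FALSE]
  sites <- list()
  if (nrow(obs)) {
    obs <- obs[order(obs$chrom, obs$side, obs$coord0), , drop = FALSE]
    grp_key <- paste(obs$chrom, obs$side)
    for (gk in unique(grp_key)) {
      g <- obs[grp_key == gk, , drop = FALSE]
      # single-linkage clustering of junction coordinates within the window
      brk <- c(TRUE, diff(g$coord0) > params$window)
      g$cluster <- cumsum(brk)
      for (cl in unique(g$cluster)) {
        gg <- g[g$cluster == cl, , drop = FALSE]
        m <- nrow(gg)
        uf <- uf_new(m)
        for (i in seq_len(m)) {
          for (j in seq_len(i - 1L)) {
            dup <- abs(gg$adapter_coord0[i] - gg$adapter_coord0[j]) <=
              params$dup_pos_tolerance || gg$umi[i] == gg$umi[j]
            if (dup) {
              ri <- uf_find(uf, i); rj <- uf_find(uf, j)
              if (ri != rj) uf[ri] <- rj
            }
          }
        }
        roots <- vapply(seq_len(m), function(i) uf_find(uf, i), integer(1))
        sites[[length(sites) + 1L]] <- data.frame(
          chrom = gg$chrom[1], coord0 = min(gg$coord0), side = gg$side[1],
          n_reads = m, n_clones = length(unique(roots)),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(chrom = character(0), coord0 = integer(0),
               side = character(0), n_reads = integer(0),
               n_clones = integer(0))
  sites <- sites[order(sites$chrom, sites$coord0, sites$side), , drop = FALSE]
  sites$per_100_genomes <- rep(NA_real_, nrow(sites))
  rownames(sites) <- NULL
  structure(list(sample_id = sample_id, sites = sites,
                 genome_equivalents = NA_real_, per_100_genomes = NA_real_,
                 params = params),
            class = "aav_callset")
}

#' @export
print.aav_callset <- function(x, ...) {
  cat(sprintf("ITR-seq call set '%s': %d unique sites\n", x$sample_id,
              nrow(x$sites)))
  if (!is.na(x$per_100_genomes)) {
    cat(sprintf("  %.4g unique sites per 100 genomes (%.0f genome equivalents)\n",
                x$per_100_genomes, x$genome_equivalents))
  }
  invisible(x)
}

#' Normalize unique-site counts to 100 genomes of input DNA
#'
#' Genome equivalents are `input_dna_ng * 1000 / genome_mass_pg`; the sample
#' frequency is `n_sites * 100 / genome_equivalents`. Each site is echoed
#' the per-site contribution `100 / genome_equivalents`.
#'
#' @param callset [collapse_and_count()] result
#' @param input_dna_ng input DNA mass in nanograms (> 0)
#' @param genome_mass_pg mass of one diploid genome in picograms (> 0;
#'   default 6.6)
#' @return the call set with `genome_equivalents`, `per_100_genomes` and the
#'   per-site column filled in
#' @examples
#' cs <- collapse_and_count(data.frame(chrom = "chr1", coord0 = 1:30,
#'                                     side = "right", adapter_coord0 = 1:30,
#'                                     umi = sprintf("U%d", 1:30)))
#' normalize_per_100_genomes(cs, 100, 6.6)$per_100_genomes  # ~0.198
#' @export
normalize_per_100_genomes <- function(callset, input_dna_ng,
                                      genome_mass_pg = 6.6) {
  if (input_dna_ng <= 0 || genome_mass_pg <= 0) {
    stop("input_dna_ng and genome_mass_pg must be positive")
  }
  ge <- input_dna_ng * 1000 / genome_mass_pg
  callset$genome_equivalents <- ge
  callset$per_100_genomes <- nrow(callset$sites) * 100 / ge
  callset$sites$per_100_genomes <- rep(100 / ge, nrow(callset$sites))
  callset
}

#' Clonal-expansion summary of a call set
#'
#' A site is clonally expanded when two or more clones (independent
#' UMI/adapter evidence) share its junction.
#'
#' @param callset [collapse_and_count()] result
#' @return list(percent_expanded, mean_clone_size_of_expanded, largest_clone);
#'   fields are `NA` when undefined (empty call set; no expanded site)
#' @examples
#' # sites with clone counts 1, 1, 2, 3
#' @export
expansion_summary <- function(callset) {
  nc <- callset$sites$n_clones
  if (!length(nc)) {
    return(list(percent_expanded = NA_real_,
                mean_clone_size_of_expanded = NA_real_,
                largest_clone = NA_integer_))
  }
  exp_sites <- nc[nc >= 2L]
  list(
    percent_expanded = 100 * length(exp_sites) / length(nc),
    mean_clone_size_of_expanded = if (length(exp_sites)) mean(exp_sites)
                                  else NA_real_,
    largest_clone = max(nc)
  )
}

#' Call AAV integration sites from ITR-seq read pairs
#'
#' Driver running [parse_read_pair()], [locate_junctions()],
#' [collapse_and_count()] and (when `input_dna_ng` is given)
#' [normalize_per_100_genomes()].
#'
#' @param r1,r2 named character vectors of read sequences, or paths to
#'   (optionally gzipped) FASTQ files
#' @param host [forge_host_genome()] object or path to a host FASTA
#' @param vector [vector_model()] supplying the ITR anchor
#' @param params [itrseq_params()]
#' @param sample_id sample label
#' @param input_dna_ng optional input DNA mass (ng) for normalization
#' @param genome_mass_pg diploid genome mass (pg)
#' @return list with `callset`, `observations` (per-read outcomes) and
#'   `rejects` (table of rejection reasons)
#' @export
call_itrseq <- function(r1, r2, host, vector, params = itrseq_params(),
                        sample_id = "sample", input_dna_ng = NULL,
                        genome_mass_pg = 6.6) {
  if (is.character(r1) && length(r1) == 1L && file.exists(r1)) {
    r1 <- read_fastq(r1)
  }
  if (is.character(r2) && length(r2) == 1L && file.exists(r2)) {
    r2 <- read_fastq(r2)
  }
  if (is.character(host) && length(host) == 1L && file.exists(host)) {
    seqs <- read_fasta(host)
    host <- structure(list(seqs = seqs, lengths = nchar(seqs),
                           total_length = sum(nchar(seqs))),
                      class = "aav_host_genome")
  }
  parsed <- parse_read_pair(r1, r2, vector, params)
  obs <- locate_junctions(parsed, host, params)
  cs <- collapse_and_count(obs, params, sample_id)
  if (!is.null(input_dna_ng)) {
    cs <- normalize_per_100_genomes(cs, input_dna_ng, genome_mass_pg)
  }
  list(callset = cs, observations = obs,
       rejects = table(obs$status[obs$status != "ok"]))
}

#' Write a call set as BED6+ and TSV
#'
#' @param callset [collapse_and_count()] result
#' @param dir output directory
#' @return invisible paths
#' @export
write_callset <- function(callset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- callset$sites
  bed <- data.frame(chrom = s$chrom, start = s$coord0, end = s$coord0 + 1L,
                    name = sprintf("site%04d", seq_len(nrow(s))),
                    score = s$n_clones,
                    strand = ifelse(s$side == "left", "-", "+"),
                    n_reads = s$n_reads,
                    per_100_genomes = s$per_100_genomes)
  bed_path <- file.path(dir, "sites.bed")
  write.table(bed, bed_path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  tsv_path <- file.path(dir, "sites.tsv")
  write.table(s, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- c(list(sample_id = callset$sample_id,
                 n_sites = nrow(s),
                 genome_equivalents = callset$genome_equivalents,
                 per_100_genomes = callset$per_100_genomes),
            expansion_summary(callset))
  json_path <- file.path(dir, "summary.json")
  jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(c(bed_path, tsv_path, json_path))
}
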