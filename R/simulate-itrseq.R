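# Planting integration events and forging anchored-PCR (ITR-seq) read pairs
# with complete ground truth.

#' Validate UMI sequences against the NNWNNWNN pattern
#'
#' Y-adapter UMIs are 8-mers whose third and sixth bases (1-based) are
#' restricted to A or T (W); all other positions may be any base.
#'
#' @param x character vector of candidate UMI sequences
#' @return logical vector
#' @examples
#' valid_umi(c("ACTGGTAA", "ACGGGCAA"))  # TRUE, FALSE
#' @export
valid_umi <- function(x) {
  grepl("^[ACGT]{2}[AT][ACGT]{2}[AT][ACGT]{2}$", x)
}

# draw n distinct UMIs under the current RNG state
make_umis <- function(n) {
  draw1 <- function() {
    b <- sample(DNA_BASES, 8L, replace = TRUE)
    b[c(3L, 6L)] <- sample(c("A", "T"), 2L, replace = TRUE)
    paste(b, collapse = "")
  }
  out <- character(0)
  while (length(out) < n) {
    out <- unique(c(out, vapply(seq_len(n - length(out) + 2L),
                                function(i) draw1(), character(1))))
  }
  out[seq_len(n)]
}

# --- event planting -------------------------------------------------------

# per-chromosome positions usable for event placement: non-N, and at least
# `margin` away from chromosome ends and N runs (so flanks and fragments
# never leave defined sequence)
usable_positions <- function(host, margin) {
  lapply(names(host$seqs), function(chrom) {
    ok <- non_n_mask(host, chrom)
    L <- length(ok)
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    bad <- logical(L)
    for (i in which(!r$values)) {
      lo <- max(1L, starts[i] - margin)
      hi <- min(L, ends[i] + margin)
      bad[lo:hi] <- TRUE
    }
    if (margin > 0L) {
      bad[seq_len(min(margin, L))] <- TRUE
      bad[seq.int(max(1L, L - margin + 1L), L)] <- TRUE
    }
    which(ok & !bad) - 1L  # 0-based
  }) |> setNames(names(host$seqs))
}

# one concatemer: per-copy vector intervals, orientations and ITR truncations
draw_copies <- function(vector, config, n_copies = NULL) {
  n <- if (is.null(n_copies)) draw_dist(config$concatemer_copy_distribution, 1L) else n_copies
  itr <- vector$itr_canonical_length
  full <- vector$full_length
  bb <- vector$bb_loop_interval
  ori <- character(n)
  ori[1] <- sample(c("+", "-"), 1L)
  for (i in seq_len(n)[-1]) {
    flip <- runif(1) < config$inversion_prob
    ori[i] <- if (flip) setdiff(c("+", "-"), ori[i - 1L]) else ori[i - 1L]
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    internal <- runif(1) < config$internal_trunc_prob
    vstart <- 0L; vend <- full
    itr5_ret <- itr; itr3_ret <- itr
    if (runif(1) >= config$itr_intact_prob) {
      brk <- sample(bb[1]:(bb[2] - 1L), 1L)
      vstart <- brk
      itr5_ret <- itr - brk
    }
    if (runif(1) >= config$itr_intact_prob) {
      brk <- sample(bb[1]:(bb[2] - 1L), 1L)
      vend <- full - brk
      itr3_ret <- itr - brk
    }
    if (internal) {
      if (sample(c(TRUE, FALSE), 1L)) {
        vstart <- sample(itr:(full - itr - 300L), 1L)
        itr5_ret <- 0L
      } else {
        vend <- sample((itr + 300L):(full - itr), 1L)
        itr3_ret <- 0L
      }
    }
    out[[i]] <- data.frame(copy_index = i, vstart0 = vstart, vend0 = vend,
                           orientation = ori[i], itr5_retained = itr5_ret,
                           itr3_retained = itr3_ret)
  }
  do.call(rbind, out)
}

#' Plant integration events with clonal-expansion ground truth
#'
#' Event positions are sampled uniformly over usable non-N host positions
#' with a minimum pairwise spacing; each event carries an orientation, a
#' clone count drawn from the configured distribution, and a planted
#' concatemer structure (per-copy vector intervals, orientations and ITR
#' truncations) used by the long-read simulator.
#'
#' @param host [forge_host_genome()] object
#' @param vector [vector_model()] object
#' @param config [sim_config()] object
#' @return object of class `aav_events`: list with data.frames `events`
#'   (event_id, chrom, pos0, orientation, clone_count, n_copies) and `copies`
#'   (event_id, copy_index, vstart0, vend0, orientation, itr5_retained,
#'   itr3_retained)
#' @examples
#' cfg <- sim_config(seed = 7, n_events = 5, chromosome_length = 20000)
#' refs <- forge_references(cfg)
#' ev <- plant_events(refs$host, refs$vector, cfg)
#' ev$events
#' @export
plant_events <- function(host, vector, config) {
  margin <- max(config$flank_length_range[2] + config$flank_indel_max,
                as.integer(config$fragment_size_mean + 6 * config$fragment_size_sd),
                config$read_length) + 50L
  usable <- usable_positions(host, margin)
  n_usable <- sum(lengths(usable))
  if (config$n_events > n_usable) {
    stop("more events requested than usable host positions")
  }
  with_seed(config$seed + 1L, {
    chrom_names <- names(usable)
    placed <- data.frame(chrom = character(0), pos0 = integer(0))
    tries <- 0L
    max_tries <- 200L * max(config$n_events, 1L)
    while (nrow(placed) < config$n_events) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("cannot place events with the required spacing; ",
             "reduce n_events or min_event_spacing")
      }
      ch <- sample(chrom_names, 1L, prob = lengths(usable))
      p <- usable[[ch]][sample.int(length(usable[[ch]]), 1L)]
      same <- placed$pos0[placed$chrom == ch]
      if (length(same) == 0L || min(abs(same - p)) >= config$min_event_spacing) {
        placed <- rbind(placed, data.frame(chrom = ch, pos0 = p))
      }
    }
    ord <- order(placed$chrom, placed$pos0)
    placed <- placed[ord, , drop = FALSE]
    n <- nrow(placed)
    events <- data.frame(
      event_id = sprintf("ev%04d", seq_len(n)),
      chrom = placed$chrom,
      pos0 = placed$pos0,
      orientation = sample(c("+", "-"), n, replace = TRUE),
      clone_count = as.integer(draw_dist(config$clone_count_distribution, n)),
      stringsAsFactors = FALSE
    )
    copies <- do.call(rbind, lapply(seq_len(n), function(i) {
      cp <- draw_copies(vector, config)
      # re-anchor the first copy on the event orientation, preserving the
      # drawn flip pattern between successive copies
      if (cp$orientation[1] != events$orientation[i]) {
        cp$orientation <- ifelse(cp$orientation == "+", "-", "+")
      }
      cp$event_id <- events$event_id[i]
      cp
    }))
    copies <- copies[, c("event_id", "copy_index", "vstart0", "vend0",
                         "orientation", "itr5_retained", "itr3_retained")]
    events$n_copies <- as.integer(table(factor(copies$event_id,
                                               levels = events$event_id)))
    structure(list(events = events, copies = copies), class = "aav_events")
  })
}

#' @export
print.aav_events <- function(x, ...) {
  cat(sprintf("Planted integration events: %d events, %d concatemer copies\n",
              nrow(x$events), nrow(x$copies)))
  invisible(x)
}

# --- ITR-seq read forging -------------------------------------------------

#' Forge anchored-PCR (ITR-seq) read pairs with ground truth
#'
#' For each event and each cell clone one template is emitted with a
#' distinct (adapter shear position, UMI) pair, followed by the configured
#' number of PCR duplicates that share the ITR position, the adapter position
#' and the UMI. Read 1 starts with the 20-base ITR primer anchor, continues
#' through residual ITR sequence and crosses into the host flank; read 2
#' carries the sample barcode and the UMI, then host sequence from the shear
#' point inward. Substitution errors are applied at the configured rate.
#'
#' @param events [plant_events()] result
#' @param host,vector,config as in [plant_events()]
#' @return list with `r1`, `r2` (named character vectors of read sequences)
#'   and `truth` (data.frame: read_id, event_id, clone_id, dup_id, chrom,
#'   pos0, side, adapter_coord0, umi, fragment)
#' @examples
#' cfg <- sim_config(seed = 7, n_events = 3, chromosome_length = 20000)
#' refs <- forge_references(cfg)
#' ev <- plant_events(refs$host, refs$vector, cfg)
#' rd <- make_itrseq_reads(ev, refs$host, refs$vector, cfg)
#' head(rd$truth)
#' @export
make_itrseq_reads <- function(events, host, vector, config) {
  ev <- events$events
  itr_part <- substr(vector$sequence, 1L,
                     20L + config$itr_residual_length)  # anchor + residual
  len1 <- config$read_length - nchar(itr_part)
  len2 <- config$read_length - nchar(config$barcode) - 8L
  stopifnot(len1 >= 30L, len2 >= 30L)
  with_seed(config$seed + 2L, {
    rows <- vector("list", nrow(ev))
    for (i in seq_len(nrow(ev))) {
      nc <- ev$clone_count[i]
      # distinct shear offsets (fragment sizes) per clone
      frags <- integer(0)
      while (length(frags) < nc) {
        f <- max(config$min_fragment_size,
                 as.integer(round(rnorm(1, config$fragment_size_mean,
                                        config$fragment_size_sd))))
        if (!(f %in% frags)) frags <- c(frags, f)
      }
      umis <- make_umis(nc)
      dups <- as.integer(draw_dist(config$n_pcr_duplicates_per_read, nc))
      rows[[i]] <- data.frame(
        event_id = ev$event_id[i], chrom = ev$chrom[i], pos0 = ev$pos0[i],
        orientation = ev$orientation[i], clone_id = seq_len(nc),
        fragment = frags, umi = umis, n_dup = dups,
        stringsAsFactors = FALSE
      )
    }
    tmpl <- do.call(rbind, rows)
    # expand PCR duplicates (dup 0 is the original molecule)
    idx <- rep(seq_len(nrow(tmpl)), tmpl$n_dup + 1L)
    truth <- tmpl[idx, ]
    truth$dup_id <- unlist(lapply(tmpl$n_dup, function(d) 0:d))
    truth$side <- ifelse(truth$orientation == "+", "left", "right")
    truth$adapter_coord0 <- ifelse(truth$side == "left",
                                   truth$pos0 - truth$fragment,
                                   truth$pos0 + truth$fragment)
    # canonical junction coordinate: host bases that continue the vector
    # sequence beyond the residual ITR are attributed to the ITR side
    # (left-maximal along the vector), matching the caller's convention
    vec_raw <- charToRaw(vector$sequence)
    v0 <- nchar(itr_part)  # 0-based vector offset of the first host base
    canon <- integer(nrow(truth))
    for (j in seq_len(nrow(truth))) {
      ch_raw <- charToRaw(host$seqs[[truth$chrom[j]]])
      p <- truth$pos0[j]
      h <- 0L
      if (truth$side[j] == "right") {
        while (v0 + h < length(vec_raw) &&
               ch_raw[p + h + 1L] == vec_raw[v0 + h + 1L]) h <- h + 1L
        canon[j] <- p + h
      } else {
        while (v0 + h < length(vec_raw) && p - h - 1L >= 0L &&
               .COMP[as.integer(ch_raw[p - h]) + 1L] ==
                 vec_raw[v0 + h + 1L]) h <- h + 1L
        canon[j] <- p - h
      }
    }
    truth$junction_coord0 <- canon
    truth$read_id <- sprintf("%s_cl%02d_dup%02d", truth$event_id,
                             truth$clone_id, truth$dup_id)
    rownames(truth) <- NULL

    host_window <- function(chrom, start0, end0) {
      subseq0(host$seqs[[chrom]], start0, end0)
    }
    r1 <- character(nrow(truth)); r2 <- character(nrow(truth))
    for (j in seq_len(nrow(truth))) {
      ch <- truth$chrom[j]; p <- truth$pos0[j]; f <- truth$fragment[j]
      if (truth$side[j] == "left") {
        h1 <- revcomp(host_window(ch, p - len1, p))
        h2 <- host_window(ch, p - f, p - f + len2)
      } else {
        h1 <- host_window(ch, p, p + len1)
        h2 <- revcomp(host_window(ch, p + f - len2, p + f))
      }
      r1[j] <- paste0(itr_part, h1)
      r2[j] <- paste0(config$barcode, truth$umi[j], h2)
    }
    r1 <- apply_substitutions(r1, config$substitution_error_rate)
    r2 <- apply_substitutions(r2, config$substitution_error_rate)
    names(r1) <- truth$read_id
    names(r2) <- truth$read_id
    truth <- truth[, c("read_id", "event_id", "clone_id", "dup_id", "chrom",
                       "pos0", "junction_coord0", "side", "adapter_coord0",
                       "umi", "fragment")]
    list(r1 = r1, r2 = r2, truth = truth)
  })
}
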