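# Annotation of the DJ architecture: tandem satellite arrays (48-bp CER-like
# monomer period), long inverted repeats, and foreign insertions embedded in
# satellite blocks. Periodicity is detected from nearest-downstream identical
# k-mer distances, which tolerates a few percent monomer divergence and
# yields an integer period directly.

# 0/next-occurrence distance per k-mer start position of s (1-based starts)
.kmer_recurrence <- function(s, k, max_period) {
  kv <- .kmers(s, k)
  if (length(kv) == 0) return(integer(0))
  cpp_next_kmer_distance(kv, as.integer(max_period))
}

#' Estimate the period of a tandem satellite segment
#'
#' For every position whose k-mer recurs downstream within `max_period`, the
#' distance to the nearest identical occurrence is recorded; the period is
#' the mode of that distance distribution if the mode covers at least
#' `min_frac` of the recorded distances, else `NA`.
#'
#' @param segment DNA string.
#' @param k k-mer length.
#' @param max_period largest period considered.
#' @param min_frac minimum fraction of recorded distances the mode must
#'   cover.
#' @param min_hits minimum number of recorded distances the mode must have
#'   (guards against the handful of chance k-mer recurrences in random
#'   sequence).
#' @param allow_short permit segments shorter than `3 * max_period`.
#' @return integer period in bp, or `NA` for aperiodic input.
#' @export
estimate_period <- function(segment, k = 12, max_period = 2000,
                            min_frac = 0.3, min_hits = 10,
                            allow_short = FALSE) {
  segment <- .as_seq(segment, "segment")$seq
  if (!allow_short && nchar(segment) < 3 * max_period) {
    abort("segment shorter than 3 * max_period; set allow_short = TRUE")
  }
  d <- .kmer_recurrence(segment, k, max_period)
  d <- d[d > 0]
  if (!length(d)) return(NA_integer_)
  tab <- tabulate(d, nbins = max_period)
  mode <- which.max(tab)
  if (tab[mode] < min_hits || tab[mode] / length(d) < min_frac) {
    return(NA_integer_)
  }
  as.integer(mode)
}

#' Find tandem satellite blocks in a contig
#'
#' Positions whose k-mer recurs within `max_period` are marked periodic;
#' maximal marked runs are merged across gaps of at most `merge_gap` bp into
#' components. Components of the same period separated by at most
#' `max_insert_gap` bp (the signature of a foreign insert embedded in the
#' array) are merged into one block whose outer span covers them; the
#' intervening gaps are what [find_foreign_inserts()] reports. Blocks whose
#' outer span is at least `min_block` bp are returned with an estimated
#' period, the majority-vote monomer consensus of the longest component and
#' the mean identity of its monomer copies to that consensus.
#'
#' @param contig a one-row contig tibble or (named) character scalar.
#' @param k,max_period see [estimate_period()].
#' @param min_block minimum block outer span in bp.
#' @param merge_gap maximal unmarked gap bridged inside a component.
#' @param min_component minimum component span considered.
#' @param max_insert_gap maximal gap between same-period components merged
#'   into one block.
#' @return a tibble: `contig_id`, `start`, `end` (0-based half-open outer
#'   span), `period`, `monomer_consensus`, `mean_monomer_identity`, and a
#'   `components` list column of (start, end) sub-spans of contiguous
#'   periodicity.
#' @export
find_satellite_blocks <- function(contig, k = 12, max_period = 2000,
                                  min_block = 1000, merge_gap = 500,
                                  min_component = 300,
                                  max_insert_gap = 20000) {
  sq <- .as_seq(contig, "contig")
  d <- .kmer_recurrence(sq$seq, k, max_period)
  marked <- which(d > 0)
  empty <- tibble(
    contig_id = character(0), start = integer(0), end = integer(0),
    period = integer(0), monomer_consensus = character(0),
    mean_monomer_identity = double(0), components = list()
  )
  if (!length(marked)) return(empty)
  runs <- .pos_runs(marked, merge_gap)
  # run of marked k-mer starts [s, e] covers bases [s, e + k - 1] (1-based)
  runs$end_bp <- runs$end + k - 1L
  runs <- filter(runs, .data$end_bp - .data$start + 1L >= min_component)
  if (nrow(runs) == 0) return(empty)
  runs$start0 <- runs$start - 1L
  runs$period <- vapply(seq_len(nrow(runs)), function(i) {
    p <- estimate_period(
      .sub0(sq$seq, runs$start0[i], runs$end_bp[i]), k, max_period,
      allow_short = TRUE
    )
    if (is.na(p)) NA_integer_ else p
  }, 0L)
  runs <- filter(runs, !is.na(.data$period))
  if (nrow(runs) == 0) return(empty)
  # merge same-period components across insert-sized gaps
  grp <- integer(nrow(runs))
  g <- 1L
  grp[1] <- g
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      gap <- runs$start0[i] - runs$end_bp[i - 1]
      if (runs$period[i] == runs$period[i - 1] && gap <= max_insert_gap) {
        grp[i] <- g
      } else {
        g <- g + 1L
        grp[i] <- g
      }
    }
  }
  out <- purrr::map_dfr(unique(grp), function(gg) {
    seg <- runs[grp == gg, ]
    per <- seg$period[which.max(seg$end_bp - seg$start0)]
    # refine component boundaries by periodic extension: the k-mer scan
    # loses ~(period + k) bp at every array terminus because terminal
    # k-mers have no downstream recurrence
    comp <- purrr::map_dfr(seq_len(nrow(seg)), function(i) {
      tibble(
        start = .periodic_extend(sq$seq, seg$start0[i], -1L, per),
        end = .periodic_extend(sq$seq, seg$end_bp[i], +1L, per)
      )
    })
    s0 <- min(comp$start)
    e0 <- max(comp$end)
    if (e0 - s0 < min_block) return(NULL)
    main <- comp[which.max(comp$end - comp$start), ]
    cm <- .monomer_consensus(.sub0(sq$seq, main$start, main$end), per)
    tibble(
      contig_id = sq$id, start = s0, end = e0, period = per,
      monomer_consensus = cm$consensus,
      mean_monomer_identity = cm$mean_identity,
      components = list(comp)
    )
  })
  if (nrow(out) == 0) empty else out
}

# Extend a component boundary while the sequence stays in phase with the
# array: a position agrees when it matches the copy one or two periods
# behind it (dir = +1; ahead of it for dir = -1), which tolerates a
# diverged array where either copy may carry substitutions. The walk keeps a
# rolling window of agreements and stops when the window falls below half;
# the boundary is placed at the end of the last run of `run_len` consecutive
# agreements, so it overshoots aperiodic flanks by at most a few bases.
# Returns the refined 0-based boundary (end-exclusive for dir = +1).
.periodic_extend <- function(s, bound, dir, p, window = 24L, run_len = 6L) {
  n <- nchar(s)
  agrees <- function(i) {
    if (i < 0 || i >= n) return(NA)
    c0 <- .char_at(s, i)
    if (dir > 0) {
      (i - p >= 0 && c0 == .char_at(s, i - p)) ||
        (i - 2 * p >= 0 && c0 == .char_at(s, i - 2 * p))
    } else {
      (i + p < n && c0 == .char_at(s, i + p)) ||
        (i + 2 * p < n && c0 == .char_at(s, i + 2 * p))
    }
  }
  buf <- rep(TRUE, window)
  run <- 0L
  best <- 0L  # extension length ending the last full agreement run
  t <- 0L
  repeat {
    i <- if (dir > 0) bound + t else bound - 1L - t
    ok <- agrees(i)
    if (is.na(ok)) break
    buf[t %% window + 1L] <- ok
    if (ok) {
      run <- run + 1L
      if (run >= run_len) best <- t + 1L
    } else {
      run <- 0L
    }
    t <- t + 1L
    if (t >= window && sum(buf) < window / 2) break
  }
  if (dir > 0) bound + best else bound - best
}

# maximal runs of sorted positions, merging gaps <= merge_gap
.pos_runs <- function(pos, merge_gap) {
  brk <- c(TRUE, diff(pos) > merge_gap + 1L)
  grp <- cumsum(brk)
  tibble(
    start = as.integer(tapply(pos, grp, min)),
    end = as.integer(tapply(pos, grp, max))
  )
}

# majority-vote consensus over period-length windows and mean per-copy
# identity to it
.monomer_consensus <- function(block, period) {
  n <- nchar(block)
  ncopy <- n %/% period
  if (ncopy < 1) return(list(consensus = NA_character_, mean_identity = NA_real_))
  chars <- strsplit(.sub0(block, 0, ncopy * period), "", fixed = TRUE)[[1]]
  m <- matrix(chars, nrow = period)
  cons <- apply(m, 1, function(col) names(which.max(table(col))))
  idents <- colMeans(m == cons)
  list(
    consensus = paste(cons, collapse = ""),
    mean_identity = 100 * mean(idents)
  )
}

#' Find long inverted repeats
#'
#' Satellite blocks are masked, shared unique k-mers between the contig and
#' its reverse complement define anti-diagonal anchors, anchors are grouped
#' by their (arm1 + arm2) coordinate sum, and consistent groups — including
#' groups offset by internal arm indels up to `max_arm_indel` bp — are
#' chained into arms. Arms of at least `min_arm` bp are reported with
#' boundaries refined by mismatch-tolerant extension on the unmasked
#' sequence and with the identity of arm 1 against the reverse complement of
#' arm 2.
#'
#' @param contig contig tibble row or character scalar.
#' @param min_arm minimum arm length in bp.
#' @param k anchor k-mer length.
#' @param sum_tol tolerance on the anti-diagonal coordinate sum within one
#'   anchor group.
#' @param max_arm_indel largest internal indel bridged when chaining anchor
#'   groups of one repeat.
#' @param max_gap largest anchor-free stretch bridged when chaining.
#' @param mask_satellite mask satellite blocks before anchoring (prevents
#'   spurious anti-diagonal anchors from near-palindromic monomers).
#' @return tibble: `contig_id`, `arm1_start`, `arm1_end`, `arm2_start`,
#'   `arm2_end` (0-based half-open), `spacer_len`, `arm_identity`.
#' @export
find_inverted_repeats <- function(contig, min_arm = 5000, k = 21,
                                  sum_tol = 200, max_arm_indel = 10000,
                                  max_gap = 5000, mask_satellite = TRUE) {
  sq <- .as_seq(contig, "contig")
  n <- nchar(sq$seq)
  empty <- tibble(
    contig_id = character(0), arm1_start = integer(0), arm1_end = integer(0),
    arm2_start = integer(0), arm2_end = integer(0), spacer_len = integer(0),
    arm_identity = double(0)
  )
  if (n < 2 * min_arm) return(empty)
  masked <- sq$seq
  if (mask_satellite) {
    blocks <- find_satellite_blocks(sq$seq)
    for (i in seq_len(nrow(blocks))) {
      masked <- paste0(
        .sub0(masked, 0, blocks$start[i]),
        strrep("N", blocks$end[i] - blocks$start[i]),
        .sub0(masked, blocks$end[i], n)
      )
    }
  }
  rc <- .revcomp(masked)
  anch <- .anchors(masked, rc, k)
  if (nrow(anch) == 0) return(empty)
  # k-mer at j (1-based) of revcomp(S) mirrors S positions [n-j-k+2, n-j+1]
  i1 <- anch$qpos
  i2 <- n - anch$tpos - k + 2L
  keep <- i1 < i2
  i1 <- i1[keep]; i2 <- i2[keep]
  if (!length(i1)) return(empty)
  s <- i1 + i2
  ord <- order(s, i1)
  i1 <- i1[ord]; i2 <- i2[ord]; s <- s[ord]
  grp <- cumsum(c(TRUE, diff(s) > sum_tol))
  segs <- purrr::map_dfr(unique(grp), function(g) {
    sel <- grp == g
    tibble(
      a1s = min(i1[sel]) - 1L, a1e = max(i1[sel]) + k - 1L,
      a2s = min(i2[sel]) - 1L, a2e = max(i2[sel]) + k - 1L,
      smid = stats::median(s[sel]), n_anchor = sum(sel)
    )
  }) |> arrange(.data$a1s)
  # chain segments of one repeat across internal indels: arm1 advances while
  # arm2 recedes (anti-diagonal) with bounded gaps and bounded sum offset
  used <- rep(FALSE, nrow(segs))
  out <- list()
  for (i in seq_len(nrow(segs))) {
    if (used[i]) next
    cur <- segs[i, ]
    used[i] <- TRUE
    repeat {
      cand <- which(!used &
        segs$a1s >= cur$a1e - 50 & segs$a1s - cur$a1e <= max_gap &
        segs$a2e <= cur$a2s + 50 & cur$a2s - segs$a2e <= max_gap &
        abs(segs$smid - cur$smid) <= max_arm_indel)
      if (!length(cand)) break
      j <- cand[which.min(segs$a1s[cand])]
      cur$a1e <- max(cur$a1e, segs$a1e[j])
      cur$a2s <- min(cur$a2s, segs$a2s[j])
      cur$a1s <- min(cur$a1s, segs$a1s[j])
      cur$a2e <- max(cur$a2e, segs$a2e[j])
      used[j] <- TRUE
    }
    out[[length(out) + 1]] <- cur
  }
  segs <- bind_rows(out)
  res <- purrr::map_dfr(seq_len(nrow(segs)), function(i) {
    a1s <- segs$a1s[i]; a1e <- segs$a1e[i]
    a2s <- segs$a2s[i]; a2e <- segs$a2e[i]
    if (a1e - a1s < min_arm || a2e - a2s < min_arm) return(NULL)
    if (a1e > a2s) return(NULL)
    # refine boundaries on the unmasked sequence: outward at arm1 start /
    # arm2 end, inward at arm1 end / arm2 start
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    ext_out <- .extend_match(
      function(t) .char_at(sq$seq, a1s - 1L - t),
      function(t) comp[.char_at(sq$seq, a2e + t)],
      max_steps = min(a1s, n - a2e)
    )
    a1s <- a1s - ext_out; a2e <- a2e + ext_out
    ext_in <- .extend_match(
      function(t) .char_at(sq$seq, a1e + t),
      function(t) comp[.char_at(sq$seq, a2s - 1L - t)],
      max_steps = max(0L, a2s - a1e)  # stop before the arms touch
    )
    a1e <- a1e + ext_in; a2s <- a2s - ext_in
    arm1 <- .sub0(sq$seq, a1s, a1e)
    arm2 <- .sub0(sq$seq, a2s, a2e)
    aln <- dj_align(arm1, .revcomp(arm2))
    tibble(
      contig_id = sq$id, arm1_start = a1s, arm1_end = a1e,
      arm2_start = a2s, arm2_end = a2e, spacer_len = a2s - a1e,
      arm_identity = identity_pct(aln)
    )
  })
  if (nrow(res) == 0) empty else arrange(res, .data$arm1_start)
}

#' Find foreign inserts embedded in satellite blocks
#'
#' Reports the aperiodic intervals inside each satellite block's outer span:
#' the gaps between the block's periodic components (see
#' [find_satellite_blocks()]) of at least `min_insert` bp.
#'
#' @param contig contig tibble row or (named) character scalar (unused
#'   except for its id; kept for interface symmetry).
#' @param blocks satellite blocks from [find_satellite_blocks()] computed on
#'   this contig.
#' @param min_insert minimum insert length in bp.
#' @return tibble: `contig_id`, `start`, `end` (0-based half-open),
#'   `host_start`, `host_end` (outer span of the hosting block).
#' @export
find_foreign_inserts <- function(contig, blocks, min_insert = 500) {
  sq <- .as_seq(contig, "contig")
  empty <- tibble(
    contig_id = character(0), start = integer(0), end = integer(0),
    host_start = integer(0), host_end = integer(0)
  )
  if (nrow(blocks) == 0) return(empty)
  out <- purrr::map_dfr(seq_len(nrow(blocks)), function(i) {
    comp <- blocks$components[[i]]
    if (is.null(comp) || nrow(comp) < 2) return(NULL)
    comp <- arrange(comp, .data$start)
    gs <- comp$end[-nrow(comp)]
    ge <- comp$start[-1]
    keep <- ge - gs >= min_insert
    if (!any(keep)) return(NULL)
    tibble(
      contig_id = sq$id, start = as.integer(gs[keep]), end = as.integer(ge[keep]),
      host_start = blocks$start[i], host_end = blocks$end[i]
    )
  })
  if (nrow(out) == 0) empty else out
}
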