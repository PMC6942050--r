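# rDNA/DJ junction location and far-distal homology-block mapping.
#
# The junction is defined operationally as the end of the maximal near-exact
# terminal match between a contig end and the rDNA reference: anchors locate
# the rDNA copy, and a mismatch-tolerant extension (isolated mismatches are
# crossed when the following bases confirm the match) finds its end. Both
# contig ends are tried, so reverse-complemented input yields the mirrored
# junction.

#' Locate the rDNA/DJ junction on a contig
#'
#' @param contig contig tibble row or (named) character scalar.
#' @param rdna_ref rDNA reference segment (any IGS-containing segment), same
#'   forms accepted.
#' @param min_seed minimum terminal rDNA match length; below it the result
#'   is "no junction" (`found = FALSE`), as expected for contigs without an
#'   rDNA stub.
#' @param k anchor k-mer length.
#' @param flank_half half-width j of the junction flank (2j bp centred on
#'   the junction, truncated at contig ends).
#' @param min_identity minimum identity of the matched rDNA prefix.
#' @return one-row tibble: `contig_id`, `found`, `end` (`"start"` or
#'   `"end"` of the contig), `junction_pos` (0-based position on the input
#'   contig just beyond the rDNA match), `rdna_prefix_len`, `rdna_offset`
#'   (junction position on the rDNA reference), `match_identity`, `flank`.
#' @export
find_junction <- function(contig, rdna_ref, min_seed = 200, k = 31,
                          flank_half = 100, min_identity = 99) {
  sq <- .as_seq(contig, "contig")
  rd <- .as_seq(rdna_ref, "rdna")
  fwd <- .terminal_rdna_match(sq$seq, rd$seq, min_seed, k, min_identity)
  rev <- .terminal_rdna_match(.revcomp(sq$seq), rd$seq, min_seed, k, min_identity)
  no_hit <- tibble(
    contig_id = sq$id, found = FALSE, end = NA_character_,
    junction_pos = NA_integer_, rdna_prefix_len = NA_integer_,
    rdna_offset = NA_integer_, match_identity = NA_real_,
    flank = NA_character_
  )
  use_rev <- !is.null(rev) && (is.null(fwd) || rev$len > fwd$len)
  hit <- if (use_rev) rev else fwd
  if (is.null(hit)) return(no_hit)
  n <- nchar(sq$seq)
  jp <- if (use_rev) n - hit$junction else hit$junction
  fl_lo <- max(0L, jp - flank_half)
  fl_hi <- min(n, jp + flank_half)
  flank <- .sub0(sq$seq, fl_lo, fl_hi)
  if (use_rev) flank <- .revcomp(flank)
  tibble(
    contig_id = sq$id, found = TRUE,
    end = if (use_rev) "end" else "start",
    junction_pos = as.integer(jp),
    rdna_prefix_len = as.integer(hit$len),
    rdna_offset = as.integer(hit$rdna_offset),
    match_identity = hit$identity,
    flank = flank
  )
}

# Maximal near-exact match between the START of `s` and any position of the
# rDNA reference. Returns NULL or list(junction = 0-based end position on s,
# len, rdna_offset, identity).
.terminal_rdna_match <- function(s, rdna, min_seed, k, min_identity) {
  head_len <- min(nchar(s), nchar(rdna) + 2000L)
  head_seq <- .sub0(s, 0, head_len)
  anch <- .anchors(head_seq, rdna, k)
  if (nrow(anch) == 0) return(NULL)
  # terminal cluster: anchors consistent with the offset of the anchor
  # closest to the contig start
  first <- anch[which.min(anch$qpos), ]
  off <- first$tpos - first$qpos
  sel <- anch[abs(anch$tpos - anch$qpos - off) <= 50 & anch$qpos >= first$qpos, ]
  last <- sel[which.max(sel$qpos), ]
  # extend beyond the last anchor, crossing isolated mismatches only when
  # the following bases confirm
  base_end <- last$qpos - 1L + k  # 0-based end of the anchored match on s
  rd_end <- last$tpos - 1L + k
  ext <- .extend_match(
    function(t) .char_at(s, base_end + t),
    function(t) .char_at(rdna, rd_end + t),
    max_steps = min(nchar(s) - base_end, nchar(rdna) - rd_end)
  )
  junction <- base_end + ext
  start_gap <- first$qpos - 1L
  len <- junction
  if (len < min_seed || start_gap > 0.05 * len + 100) return(NULL)
  # identity of the matched prefix against the rDNA reference
  a <- .sub0(s, 0, junction)
  b <- .sub0(rdna, max(0L, off), max(0L, off) + junction)
  w <- min(nchar(a), nchar(b))
  matches <- sum(strsplit(substr(a, 1, w), "", fixed = TRUE)[[1]] ==
    strsplit(substr(b, 1, w), "", fixed = TRUE)[[1]])
  identity <- 100 * matches / w
  if (identity < min_identity) return(NULL)
  list(
    junction = junction, len = len,
    rdna_offset = rd_end + ext, identity = identity
  )
}

#' Compare junction flanks across contigs
#'
#' @param calls row-bound [find_junction()] results with `found = TRUE`.
#' @return list: `identical` (TRUE iff all flank strings are identical;
#'   vacuously TRUE for a single call) and `report`, a tibble of differing
#'   flank positions (0-based within the flank) with the variant bases.
#' @export
compare_junction_flanks <- function(calls) {
  calls <- filter(calls, .data$found)
  if (nrow(calls) < 2) {
    return(list(identical = TRUE, report = tibble(
      position = integer(0), variants = character(0)
    )))
  }
  flanks <- calls$flank
  lens <- nchar(flanks)
  width <- min(lens)
  m <- do.call(rbind, strsplit(substr(flanks, 1, width), "", fixed = TRUE))
  diffpos <- which(apply(m, 2, function(col) length(unique(col)) > 1))
  report <- tibble(
    position = as.integer(diffpos - 1L),
    variants = vapply(
      diffpos, function(p) paste(unique(m[, p]), collapse = "/"), ""
    )
  )
  list(identical = length(diffpos) == 0 && length(unique(lens)) == 1, report = report)
}

#' Map homology blocks between a query and a target
#'
#' Anchor-chained local homology on both strands. Chains are split where the
#' anchor diagonal jumps by more than `max_diag_jump` bp (candidate internal
#' insertions/deletions); surviving blocks of at least `min_block` bp with
#' identity at least `min_identity` are reported. Target-side gaps between
#' consecutive collinear forward blocks imply candidate internal deletions
#' and are reported in the `gaps` attribute.
#'
#' @param query,target contig tibble rows or (named) character scalars.
#' @param min_block minimum block span in bp.
#' @param min_identity minimum substitution-only identity in percent (the
#'   default 85 captures diverged paralogous copies at 86-87% identity while
#'   excluding noise).
#' @param k anchor k-mer length.
#' @param max_diag_jump diagonal jump splitting chains into blocks.
#' @return tibble: `query_id`, `target_id`, `q_start`, `q_end`, `t_start`,
#'   `t_end` (0-based half-open; target spans always in forward
#'   coordinates), `identity`, `strand`; attribute `gaps` with
#'   `query_gap`, `target_gap`, `implied_deletion` between consecutive
#'   forward blocks.
#' @export
homology_blocks <- function(query, target, min_block = 2000,
                            min_identity = 85, k = 21,
                            max_diag_jump = 1000) {
  qs <- .as_seq(query, "query")
  ts <- .as_seq(target, "target")
  fwd <- .strand_blocks(qs, ts$seq, ts$id, k, max_diag_jump, min_block, min_identity)
  if (nrow(fwd)) fwd$strand <- "forward"
  n <- nchar(ts$seq)
  rev <- .strand_blocks(
    qs, .revcomp(ts$seq), ts$id, k, max_diag_jump, min_block, min_identity
  )
  if (nrow(rev)) {
    rev <- mutate(rev,
      t_start2 = n - .data$t_end, t_end = n - .data$t_start,
      t_start = .data$t_start2, strand = "reverse"
    ) |> select(-"t_start2")
  }
  out <- bind_rows(fwd, rev)
  gaps <- tibble(
    query_gap = integer(0), target_gap = integer(0), implied_deletion = integer(0)
  )
  if (nrow(fwd) > 1) {
    f <- arrange(fwd, .data$q_start)
    qg <- f$q_start[-1] - f$q_end[-nrow(f)]
    tg <- f$t_start[-1] - f$t_end[-nrow(f)]
    gaps <- tibble(
      query_gap = as.integer(qg), target_gap = as.integer(tg),
      implied_deletion = as.integer(tg - qg)
    )
  }
  out <- if (nrow(out)) arrange(out, .data$q_start) else tibble(
    query_id = character(0), target_id = character(0),
    q_start = integer(0), q_end = integer(0), t_start = integer(0),
    t_end = integer(0), identity = double(0), strand = character(0)
  )
  attr(out, "gaps") <- gaps
  out
}

.strand_blocks <- function(qs, tseq, tid, k, max_diag_jump, min_block,
                           min_identity) {
  empty <- tibble(
    query_id = character(0), target_id = character(0),
    q_start = integer(0), q_end = integer(0), t_start = integer(0),
    t_end = integer(0), identity = double(0)
  )
  chain <- .chain_runs(.anchor_runs(.anchors(qs$seq, tseq, k), k))
  if (nrow(chain) == 0) return(empty)
  diag <- chain$tstart - chain$qstart
  brk <- c(TRUE, abs(diff(diag)) > max_diag_jump)
  grp <- cumsum(brk)
  out <- purrr::map_dfr(unique(grp), function(g) {
    seg <- chain[grp == g, ]
    q0 <- seg$qstart[1] - 1L
    q1 <- seg$qstart[nrow(seg)] - 1L + seg$len[nrow(seg)]
    t0 <- seg$tstart[1] - 1L
    t1 <- seg$tstart[nrow(seg)] - 1L + seg$len[nrow(seg)]
    if (q1 - q0 < min_block || t1 - t0 < min_block) return(NULL)
    aln <- dj_align(.sub0(qs$seq, q0, q1), .sub0(tseq, t0, t1))
    idn <- identity_pct(aln)
    if (idn < min_identity) return(NULL)
    tibble(
      query_id = qs$id, target_id = tid,
      q_start = q0, q_end = q1, t_start = t0, t_end = t1, identity = idn
    )
  })
  if (nrow(out) == 0) empty else out
}
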