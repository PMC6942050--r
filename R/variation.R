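# Indel calling between contigs, breakpoint matching across chromosomes, and
# inference of exchanges between heterologous chromosomes. Exchange is
# formalised as the classic four-gamete condition under an
# infinite-sites-style assumption: each indel marker arose exactly once, so a
# marker pair exhibiting all four joint presence/absence patterns requires at
# least one exchange between the marker positions.

#' Call indels from an alignment
#'
#' Every insertion/deletion operation of at least `min_len` bp becomes a
#' call. Calls are left-normalised (shifted leftward on the reference while
#' the alignment is preserved) and breakpoint flanks of `flank` bp are
#' extracted from the reference after normalisation. The alignment's target
#' is the reference.
#'
#' @param aln a `dj_alignment` (target = reference).
#' @param min_len minimum indel length in bp (default 50; below this,
#'   alignment ambiguity in repeat-rich sequence makes breakpoint identity
#'   unreliable).
#' @param flank flank length in bp.
#' @return tibble: `reference_id`, `query_id`, `ref_pos` (0-based,
#'   left-normalised), `length`, `type`, `left_flank`, `right_flank`.
#' @export
call_indels <- function(aln, min_len = 50, flank = 30) {
  stopifnot(inherits(aln, "dj_alignment"))
  ops <- tidy(aln)
  tgt_off <- aln$target_span[1]
  qry_off <- aln$query_span[1]
  tcons <- ops$kind %in% c("match", "mismatch", "ambiguous", "deletion_in_query")
  qcons <- ops$kind %in% c("match", "mismatch", "ambiguous", "insertion_in_query")
  tpos <- tgt_off + cumsum(ifelse(tcons, ops$length, 0L)) - ifelse(tcons, ops$length, 0L)
  qpos <- qry_off + cumsum(ifelse(qcons, ops$length, 0L)) - ifelse(qcons, ops$length, 0L)
  hit <- which(ops$kind %in% c("deletion_in_query", "insertion_in_query") &
    ops$length >= min_len)
  ref <- aln$target
  # target coordinates here are local to the aligned segment; shift to the
  # full reference coordinate system
  rows <- purrr::map(hit, function(i) {
    type <- ops$kind[i]
    L <- ops$length[i]
    p <- tpos[i] - tgt_off  # local 0-based on the aligned target segment
    seg <- if (type == "deletion_in_query") {
      .sub0(ref, p, p + L)
    } else {
      .sub0(aln$query, qpos[i] - qry_off, qpos[i] - qry_off + L)
    }
    norm <- .left_normalise(ref, p, seg, type)
    p <- norm$pos
    gpos <- p + tgt_off
    right0 <- if (type == "deletion_in_query") p + L else p
    tibble(
      reference_id = aln$target_id, query_id = aln$query_id,
      ref_pos = as.integer(gpos), length = as.integer(L), type = type,
      left_flank = .sub0(ref, max(0L, p - flank), p),
      right_flank = .sub0(ref, right0, min(nchar(ref), right0 + flank))
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(
      reference_id = character(0), query_id = character(0),
      ref_pos = integer(0), length = integer(0), type = character(0),
      left_flank = character(0), right_flank = character(0)
    ))
  }
  arrange(out, .data$ref_pos)
}

#' Match indel breakpoints across queries into markers
#'
#' Calls from multiple queries against one reference cluster into a single
#' marker if and only if their type, exact length, normalised position and
#' both flank strings agree. Near-matches (same type and length, different
#' position or flanks) are reported separately in the `candidates` attribute
#' and never merged silently.
#'
#' @param calls row-bound output of [call_indels()] over multiple queries
#'   sharing one reference.
#' @return tibble of markers: `marker_id`, `ref_pos`, `length`, `type`,
#'   `left_flank`, `right_flank`, `carriers` (list column of query ids),
#'   sorted by `ref_pos`; attribute `candidates` lists marker-id pairs with
#'   matching type/length but differing breakpoints.
#' @export
match_breakpoints <- function(calls) {
  if (nrow(calls) == 0) {
    out <- tibble(
      marker_id = character(0), ref_pos = integer(0), length = integer(0),
      type = character(0), left_flank = character(0),
      right_flank = character(0), carriers = list()
    )
    attr(out, "candidates") <- tibble(
      marker_a = character(0), marker_b = character(0)
    )
    return(out)
  }
  if (length(unique(calls$reference_id)) != 1) {
    abort("all calls must share one reference")
  }
  out <- calls |>
    group_by(
      .data$type, .data$length, .data$ref_pos, .data$left_flank,
      .data$right_flank
    ) |>
    summarise(carriers = list(.data$query_id), .groups = "drop") |>
    arrange(.data$ref_pos)
  dup <- vapply(out$carriers, anyDuplicated, 0L)
  if (any(dup > 0)) abort("duplicate carrier: one query contributes two calls to a marker")
  out$marker_id <- sprintf("M%02d", seq_len(nrow(out)))
  out <- select(
    out, "marker_id", "ref_pos", "length", "type", "left_flank",
    "right_flank", "carriers"
  )
  cand <- tibble(marker_a = character(0), marker_b = character(0))
  if (nrow(out) > 1) {
    for (i in seq_len(nrow(out) - 1)) {
      for (j in (i + 1):nrow(out)) {
        if (out$type[i] == out$type[j] && out$length[i] == out$length[j]) {
          cand <- bind_rows(cand, tibble(
            marker_a = out$marker_id[i], marker_b = out$marker_id[j]
          ))
        }
      }
    }
  }
  attr(out, "candidates") <- cand
  out
}

#' Construct a marker presence matrix
#'
#' @param markers tibble with at least `marker_id`, `ref_pos`, `length`,
#'   `type`, sorted by `ref_pos`.
#' @param chromosomes ordered labels of cohort members (matrix columns).
#' @param presence integer matrix markers x chromosomes with entries 0, 1 or
#'   NA (missing: locus unalignable).
#' @return object of class `dj_marker_matrix`.
#' @export
marker_matrix <- function(markers, chromosomes, presence) {
  stopifnot(
    is.matrix(presence), nrow(presence) == nrow(markers),
    ncol(presence) == length(chromosomes)
  )
  if (is.unsorted(markers$ref_pos)) abort("markers must be sorted by ref_pos")
  if (!all(presence %in% c(0L, 1L, NA_integer_))) {
    abort("presence entries must be 0, 1 or NA")
  }
  dimnames(presence) <- list(markers$marker_id, chromosomes)
  structure(
    list(
      markers = as_tibble(markers[, c("marker_id", "ref_pos", "length", "type")]),
      chromosomes = chromosomes, presence = presence
    ),
    class = "dj_marker_matrix"
  )
}

#' @export
print.dj_marker_matrix <- function(x, ...) {
  cat(sprintf(
    "<dj_marker_matrix> %d markers x %d chromosomes\n",
    nrow(x$presence), ncol(x$presence)
  ))
  print(x$presence)
  invisible(x)
}

#' Long-format marker matrix
#'
#' @param x a `dj_marker_matrix`.
#' @param ... unused.
#' @return tibble: `marker_id`, `ref_pos`, `chromosome`, `present`.
#' @method tidy dj_marker_matrix
#' @export
tidy.dj_marker_matrix <- function(x, ...) {
  long <- as_tibble(as.data.frame.table(x$presence, stringsAsFactors = FALSE))
  names(long) <- c("marker_id", "chromosome", "present")
  left_join(long, x$markers[, c("marker_id", "ref_pos")], by = "marker_id") |>
    select("marker_id", "ref_pos", "chromosome", "present")
}

#' Build the marker matrix from alignments
#'
#' Presence is 1 when the query carries the marker's call. Absence (0) is
#' verified, not assumed: the query must align contiguously across the
#' marker locus with no indel operation of `min_len` bp or more overlapping
#' it; otherwise the entry is NA (missing) and is excluded from downstream
#' four-gamete tests.
#'
#' @param markers output of [match_breakpoints()].
#' @param alignments named list of `dj_alignment`s (one per query, all
#'   against the marker reference); names are the chromosome labels.
#' @param min_len as in [call_indels()].
#' @param pad bp of required contiguous alignment on each side of the locus.
#' @return a `dj_marker_matrix`.
#' @export
build_marker_matrix <- function(markers, alignments, min_len = 50, pad = 25) {
  chrom <- names(alignments)
  presence <- matrix(
    NA_integer_, nrow(markers), length(chrom),
    dimnames = list(markers$marker_id, chrom)
  )
  for (j in seq_along(chrom)) {
    aln <- alignments[[j]]
    ops <- tidy(aln)
    tcons <- ops$kind %in% c("match", "mismatch", "ambiguous", "deletion_in_query")
    tlen <- ifelse(tcons, ops$length, 0L)
    tstart <- aln$target_span[1] + cumsum(tlen) - tlen
    tend <- tstart + tlen
    for (i in seq_len(nrow(markers))) {
      if (chrom[j] %in% markers$carriers[[i]]) {
        presence[i, j] <- 1L
        next
      }
      span_on_ref <- if (markers$type[i] == "deletion_in_query") markers$length[i] else 0L
      lo <- markers$ref_pos[i] - pad
      hi <- markers$ref_pos[i] + span_on_ref + pad
      if (lo < aln$target_span[1] || hi > aln$target_span[2]) next  # NA
      big_indel <- ops$kind %in% c("deletion_in_query", "insertion_in_query") &
        ops$length >= min_len
      overlaps <- big_indel & tend > lo & tstart < hi
      # insertions consume no reference; attach them to their left position
      ins <- ops$kind == "insertion_in_query" & ops$length >= min_len
      overlaps <- overlaps | (ins & tstart >= lo & tstart <= hi)
      presence[i, j] <- if (any(overlaps)) NA_integer_ else 0L
    }
  }
  marker_matrix(markers, chrom, presence)
}

#' Four-gamete test for a marker pair
#'
#' TRUE iff all four joint presence/absence patterns (0,0), (0,1), (1,0),
#' (1,1) occur among chromosomes non-missing at both markers — which, under
#' the single-origin assumption, requires at least one exchange between the
#' two marker positions.
#'
#' @param mi,mj marker ids.
#' @param matrix a `dj_marker_matrix`.
#' @return logical.
#' @export
four_gamete <- function(mi, mj, matrix) {
  stopifnot(inherits(matrix, "dj_marker_matrix"))
  a <- matrix$presence[mi, ]
  b <- matrix$presence[mj, ]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) abort("untestable pair: no chromosome non-missing at both markers")
  a <- a[ok]; b <- b[ok]
  all(c("00", "01", "10", "11") %in% paste0(a, b))
}

#' Classify an exchange mechanism from the adjoining shared block length
#'
#' Noncrossover (gene-conversion) tracts are limited to about 1 kb, so a
#' homogeneous shared block longer than that implies a crossover.
#'
#' @param shared_block_len length in bp (vectorised).
#' @return `"CO"` where length > 1000, else `"NCO_possible"`.
#' @export
classify_mechanism <- function(shared_block_len) {
  stopifnot(all(shared_block_len >= 0))
  ifelse(shared_block_len > 1000, "CO", "NCO_possible")
}

#' Classify inter-marker intervals as exchange-required or linked
#'
#' Every adjacent marker pair (by reference position) is tested with
#' [four_gamete()]: intervals where the test passes require at least one
#' exchange; the rest are linked. A greedy left-to-right scan reduces the
#' exchange-required intervals to a minimal disjoint set whose size is the
#' minimum number of exchanges (`min_exchanges` attribute). Each
#' exchange-required interval is classified `CO` when the widest run of
#' linked intervals immediately adjoining it exceeds 1 kb, else
#' `NCO_possible`.
#'
#' @param matrix a `dj_marker_matrix` with at least two markers.
#' @return tibble: `left_marker`, `right_marker`, `start`, `end`, `width`
#'   (bp), `status` (`exchange_required`/`linked`), `mechanism_class` (NA for
#'   linked intervals); attribute `min_exchanges`.
#' @export
exchange_intervals <- function(matrix) {
  stopifnot(inherits(matrix, "dj_marker_matrix"))
  mk <- matrix$markers
  if (nrow(mk) < 2) abort("need at least two markers")
  n <- nrow(mk) - 1
  out <- tibble(
    left_marker = mk$marker_id[seq_len(n)],
    right_marker = mk$marker_id[seq_len(n) + 1],
    start = mk$ref_pos[seq_len(n)],
    end = mk$ref_pos[seq_len(n) + 1],
    width = mk$ref_pos[seq_len(n) + 1] - mk$ref_pos[seq_len(n)],
    status = vapply(seq_len(n), function(i) {
      if (four_gamete(mk$marker_id[i], mk$marker_id[i + 1], matrix)) {
        "exchange_required"
      } else {
        "linked"
      }
    }, "")
  )
  # widest adjoining run of linked intervals, per exchange interval
  out$mechanism_class <- NA_character_
  linked_run_width <- function(from, dir) {
    w <- 0L
    i <- from
    while (i >= 1 && i <= n && out$status[i] == "linked") {
      w <- w + out$width[i]
      i <- i + dir
    }
    w
  }
  for (i in which(out$status == "exchange_required")) {
    shared <- max(linked_run_width(i - 1, -1L), linked_run_width(i + 1, 1L))
    out$mechanism_class[i] <- classify_mechanism(shared)
  }
  # greedy left-to-right minimal disjoint set
  req <- filter(out, .data$status == "exchange_required")
  count <- 0L
  last_end <- -Inf
  if (nrow(req)) {
    for (i in seq_len(nrow(req))) {
      if (req$start[i] >= last_end) {
        count <- count + 1L
        last_end <- req$end[i]
      }
    }
  }
  attr(out, "min_exchanges") <- count
  out
}

#' The three reported DJ deletion markers on the WAV17 contig
#'
#' The published presence/absence pattern of the three large deletions on
#' the WAV17 DJ contig coordinate system — 1.5 kb at 110 kb (carried by
#' A9-13, A9-15 and GM10063) and 0.3 kb / 5.0 kb at 161 kb / 172 kb
#' (carried by A9-22, WAV17 and GM10063) — across the seven sequenced
#' acrocentric chromosomes.
#'
#' @return a `dj_marker_matrix` (3 markers x 7 chromosomes).
#' @export
dj_reference_markers <- function() {
  chroms <- c("A9-13", "A9-14", "A9-15", "A9-21", "A9-22", "WAV17", "GM10063")
  markers <- tibble(
    marker_id = c("D1.5", "D0.3", "D5.0"),
    ref_pos = c(110000L, 161000L, 172000L),
    length = c(1500L, 300L, 5000L),
    type = "deletion_in_query"
  )
  carriers <- list(
    `D1.5` = c("A9-13", "A9-15", "GM10063"),
    `D0.3` = c("A9-22", "WAV17", "GM10063"),
    `D5.0` = c("A9-22", "WAV17", "GM10063")
  )
  presence <- matrix(
    0L, 3, 7,
    dimnames = list(markers$marker_id, chroms)
  )
  for (m in names(carriers)) presence[m, carriers[[m]]] <- 1L
  marker_matrix(markers, chroms, presence)
}
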