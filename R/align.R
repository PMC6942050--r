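# Pairwise alignment of long contigs under unit edit costs.
#
# Small problems are solved by exact dynamic programming (Levenshtein with
# traceback, in C++). Large problems are anchored: maximal runs of k-mers
# unique in both sequences are collinearly chained and the gaps between
# consecutive anchors are closed by exact (possibly banded) DP. Alignment
# columns opposite an N are classified "ambiguous" and excluded from
# identity numerators and denominators.

OP_KINDS <- c(
  "=" = "match", "X" = "mismatch", "n" = "ambiguous",
  "I" = "insertion_in_query", "D" = "deletion_in_query"
)

.new_alignment <- function(query_id, target_id, query, target, opstr,
                           query_span, target_span) {
  matches <- stringr::str_count(opstr, stringr::fixed("="))
  mism <- stringr::str_count(opstr, stringr::fixed("X"))
  amb <- stringr::str_count(opstr, stringr::fixed("n"))
  ins <- stringr::str_count(opstr, stringr::fixed("I"))
  del <- stringr::str_count(opstr, stringr::fixed("D"))
  structure(
    list(
      query_id = query_id, target_id = target_id,
      query = query, target = target,
      opstr = opstr,
      query_span = as.integer(query_span), target_span = as.integer(target_span),
      matches = matches, substitutions = mism, ambiguous_columns = amb,
      aligned_columns = matches + mism,
      indel_bases = ins + del,
      insertion_bases = ins, deletion_bases = del,
      indel_events = NA_integer_
    ),
    class = "dj_alignment"
  )
}

#' Ordered alignment operations
#'
#' @param x a `dj_alignment`.
#' @param ... unused.
#' @return a tibble with columns `kind` (match, mismatch, ambiguous,
#'   insertion_in_query, deletion_in_query) and `length`, in alignment order.
#'   Adjacent operations of the same kind are merged.
#' @method tidy dj_alignment
#' @export
tidy.dj_alignment <- function(x, ...) {
  r <- rle(strsplit(x$opstr, "", fixed = TRUE)[[1]])
  tibble(kind = unname(OP_KINDS[r$values]), length = r$lengths)
}

#' One-row alignment summary
#'
#' @param x a `dj_alignment`.
#' @param ... unused.
#' @return a one-row tibble of derived counts and both identity modes.
#' @method glance dj_alignment
#' @export
glance.dj_alignment <- function(x, ...) {
  tibble(
    query_id = x$query_id, target_id = x$target_id,
    aligned_columns = x$aligned_columns, matches = x$matches,
    substitutions = x$substitutions, ambiguous_columns = x$ambiguous_columns,
    indel_events = x$indel_events, indel_bases = x$indel_bases,
    identity_substitution_only = identity_pct(x, "substitution_only"),
    identity_blast_like = identity_pct(x, "blast_like")
  )
}

#' @export
print.dj_alignment <- function(x, ...) {
  cat(sprintf(
    "<dj_alignment> %s vs %s\n  query span [%d, %d), target span [%d, %d)\n  %d matches, %d substitutions, %d indel events (%d bp), %d ambiguous\n  identity %.4f%% (substitution-only), %.4f%% (blast-like)\n",
    x$query_id, x$target_id, x$query_span[1], x$query_span[2],
    x$target_span[1], x$target_span[2], x$matches, x$substitutions,
    x$indel_events, x$indel_bases, x$ambiguous_columns,
    identity_pct(x, "substitution_only"), identity_pct(x, "blast_like")
  ))
  invisible(x)
}

.finish_alignment <- function(query_id, target_id, query, target, opstr,
                              query_span, target_span) {
  aln <- .new_alignment(
    query_id, target_id, query, target, opstr, query_span, target_span
  )
  ops <- strsplit(opstr, "", fixed = TRUE)[[1]]
  r <- rle(ops)
  aln$indel_events <- sum(r$values %in% c("I", "D"))
  # invariants: column counts must reconstruct the spans
  stopifnot(
    sum(ops %in% c("=", "X", "n", "D")) == target_span[2] - target_span[1],
    sum(ops %in% c("=", "X", "n", "I")) == query_span[2] - query_span[1]
  )
  aln
}

# Raw DP alignment of two strings; extra = band slack (see cpp_edit_align).
.dp_ops <- function(a, b, extra = NULL) {
  if (nchar(a) == 0 && nchar(b) == 0) return(list(dist = 0, ops = ""))
  if (is.null(extra)) extra <- max(nchar(a), nchar(b))
  cpp_edit_align(a, b, extra)
}

# Band slack for an inter-anchor gap: full DP when the area is small,
# otherwise a band of width 2*|length difference| + band_pad.
.gap_extra <- function(la, lb, dp_max_area, band_pad) {
  if (as.numeric(la) * as.numeric(lb) <= dp_max_area) return(max(la, lb))
  abs(la - lb) + band_pad / 2
}

#' Global alignment of two sequences
#'
#' Computes a unit-cost (Levenshtein) global alignment. Inputs whose DP area
#' (product of lengths) is at most `dp_max_area` are aligned by exact dynamic
#' programming; larger inputs are aligned by chaining maximal shared unique
#' k-mer anchors and closing inter-anchor gaps with exact (banded) DP.
#'
#' @param a,b sequences: character scalars (optionally named) or one-row
#'   contig tibbles. `a` is the query, `b` the target/reference.
#' @param k anchor k-mer length (k-mers must be unique within each sequence).
#' @param dp_max_area maximum DP area for the exact path and for inter-anchor
#'   fills.
#' @param band_pad extra band width added to the length difference when a
#'   fill exceeds `dp_max_area`.
#' @return a `dj_alignment` object; see [tidy.dj_alignment()] and
#'   [glance.dj_alignment()].
#' @examples
#' aln <- dj_align("ACGTACGT", "ACGAACGT")
#' glance(aln)
#' @export
dj_align <- function(a, b, k = 21, dp_max_area = 64e6, band_pad = 512) {
  qa <- .as_seq(a, "query")
  tb <- .as_seq(b, "target")
  if (nchar(qa$seq) == 0 || nchar(tb$seq) == 0) abort("empty sequence")
  opstr <- .align_ops(qa$seq, tb$seq, k, dp_max_area, band_pad)
  .finish_alignment(
    qa$id, tb$id, qa$seq, tb$seq, opstr,
    c(0L, nchar(qa$seq)), c(0L, nchar(tb$seq))
  )
}

.align_ops <- function(a, b, k, dp_max_area, band_pad) {
  m <- nchar(a); n <- nchar(b)
  if (as.numeric(m) * as.numeric(n) <= dp_max_area) {
    return(.dp_ops(a, b)$ops)
  }
  chain <- .chain_runs(.anchor_runs(.anchors(a, b, k), k))
  if (nrow(chain) == 0) {
    abort("unalignable: no shared unique k-mer anchors", class = "dj_unalignable")
  }
  pieces <- character(2 * nrow(chain) + 1)
  qprev <- 0L; tprev <- 0L  # 0-based end of previous aligned piece
  for (i in seq_len(nrow(chain))) {
    qs <- chain$qstart[i] - 1L; ts <- chain$tstart[i] - 1L
    ga <- .sub0(a, qprev, qs); gb <- .sub0(b, tprev, ts)
    extra <- .gap_extra(nchar(ga), nchar(gb), dp_max_area, band_pad)
    pieces[2 * i - 1] <- .dp_ops(ga, gb, extra)$ops
    pieces[2 * i] <- strrep("=", chain$len[i])
    qprev <- qs + chain$len[i]; tprev <- ts + chain$len[i]
  }
  ga <- .sub0(a, qprev, m); gb <- .sub0(b, tprev, n)
  extra <- .gap_extra(nchar(ga), nchar(gb), dp_max_area, band_pad)
  pieces[2 * nrow(chain) + 1] <- .dp_ops(ga, gb, extra)$ops
  paste(pieces, collapse = "")
}

#' Percent identity of an alignment
#'
#' `substitution_only` is `100 * matches / (matches + mismatches)` — the
#' convention under which a terminal block differing by substitutions alone
#' yields e.g. 99.95% for 53 differences over ~112 kb. `blast_like` divides
#' by `matches + mismatches + indel bases` instead. Columns opposite N are
#' excluded from both numerator and denominator.
#'
#' @param aln a `dj_alignment`.
#' @param mode `"substitution_only"` (default) or `"blast_like"`.
#' @return identity in percent.
#' @export
identity_pct <- function(aln, mode = c("substitution_only", "blast_like")) {
  mode <- match.arg(mode)
  if (aln$aligned_columns == 0) abort("zero aligned columns")
  denom <- switch(mode,
    substitution_only = aln$aligned_columns,
    blast_like = aln$aligned_columns + aln$indel_bases
  )
  100 * aln$matches / denom
}

#' Align a reference interval against its partner region in another contig
#'
#' The query interval of `a` is extracted, its matching region in `b` is
#' located from shared unique k-mer anchors, and the two segments are
#' aligned. `query_span`/`target_span` of the result record the coordinates
#' on the full input sequences.
#'
#' @inheritParams dj_align
#' @param a_interval 0-based half-open `c(start, end)` on `a`.
#' @return a `dj_alignment`.
#' @export
dj_align_range <- function(a, b, a_interval, k = 21, dp_max_area = 64e6,
                           band_pad = 512) {
  qa <- .as_seq(a, "query")
  tb <- .as_seq(b, "target")
  start <- a_interval[1]; end <- a_interval[2]
  if (start < 0 || end > nchar(qa$seq) || end <= start) {
    abort("a_interval outside query")
  }
  sub_a <- .sub0(qa$seq, start, end)
  n <- nchar(tb$seq)
  chain <- .chain_runs(.anchor_runs(.anchors(sub_a, tb$seq, k), k))
  if (nrow(chain) == 0) {
    abort("unalignable: partner region not locatable", class = "dj_unalignable")
  }
  first <- chain[1, ]; last <- chain[nrow(chain), ]
  t0 <- max(0L, first$tstart - 1L - (first$qstart - 1L))
  t1 <- min(n, last$tstart - 1L + last$len + (nchar(sub_a) - (last$qstart - 1L + last$len)))
  sub_b <- .sub0(tb$seq, t0, t1)
  opstr <- .align_ops(sub_a, sub_b, k, dp_max_area, band_pad)
  .finish_alignment(
    qa$id, tb$id, sub_a, sub_b, opstr,
    c(start, end), c(t0, t1)
  )
}

#' Windowed identity profile along a reference
#'
#' Each query is globally aligned to the reference once; alignment columns
#' are then assigned to reference windows and per-window identity computed.
#' Windows tile the reference (non-overlapping at the default step); a final
#' partial window is kept when it is at least half the window size. A window
#' with no aligned columns for a query is reported as `NA` (missing), never
#' zero.
#'
#' @param reference the reference contig (coordinate system of the profile).
#' @param queries a cohort tibble or named character vector of query
#'   sequences.
#' @param window_bp,step_bp window size and step in bp (default 100 kb,
#'   non-overlapping).
#' @param mode identity mode, see [identity_pct()].
#' @inheritParams dj_align
#' @return a tibble of class `dj_identity_profile` with columns
#'   `window_start`, `window_end`, `query_id`, `matches`, `mismatches`,
#'   `indel_bases`, `identity`.
#' @seealso [profile_mean()], [autoplot.dj_identity_profile()]
#' @export
window_identity <- function(reference, queries, window_bp = 100000,
                            step_bp = window_bp,
                            mode = c("substitution_only", "blast_like"),
                            k = 21, dp_max_area = 64e6, band_pad = 512) {
  mode <- match.arg(mode)
  ref <- .as_seq(reference, "reference")
  len <- nchar(ref$seq)
  if (len < window_bp) abort("reference shorter than one window")
  cohort <- .as_cohort(queries)
  starts <- seq(0L, len - 1L, by = step_bp)
  ends <- pmin(starts + window_bp, len)
  keep <- (ends - starts) >= window_bp / 2
  starts <- starts[keep]; ends <- ends[keep]

  per_query <- purrr::map(seq_len(nrow(cohort)), function(i) {
    aln <- dj_align(
      setNames(cohort$sequence[i], cohort$id[i]), ref$seq,
      k = k, dp_max_area = dp_max_area, band_pad = band_pad
    )
    ops <- strsplit(aln$opstr, "", fixed = TRUE)[[1]]
    tcons <- ops %in% c("=", "X", "n", "D")
    refpos <- cumsum(tcons) - 1L  # 0-based ref position of each column
    ok <- refpos >= 0
    # per-reference-position counts, then window sums via cumulative sums so
    # overlapping windows (step < window) are handled too
    cs <- function(sel) {
      c(0, cumsum(tabulate(refpos[ok & sel] + 1L, nbins = len)))
    }
    cm <- cs(ops == "=")
    cx <- cs(ops == "X")
    ci <- cs(ops %in% c("I", "D"))
    tibble(
      window_start = starts, window_end = ends,
      query_id = cohort$id[i],
      matches = as.integer(cm[ends + 1L] - cm[starts + 1L]),
      mismatches = as.integer(cx[ends + 1L] - cx[starts + 1L]),
      indel_bases = as.integer(ci[ends + 1L] - ci[starts + 1L])
    )
  })
  out <- bind_rows(per_query)
  denom <- out$matches + out$mismatches +
    if (mode == "blast_like") out$indel_bases else 0L
  out$identity <- ifelse(
    out$matches + out$mismatches == 0, NA_real_,
    100 * out$matches / denom
  )
  structure(
    out,
    reference_id = ref$id, mode = mode, window_bp = window_bp,
    class = c("dj_identity_profile", class(out))
  )
}

#' Per-window mean identity across queries
#'
#' @param profile a `dj_identity_profile` from [window_identity()].
#' @return a tibble with one row per window: `window_start`, `window_end`,
#'   `mean_identity` (across queries with non-missing identity),
#'   `n_queries`.
#' @export
profile_mean <- function(profile) {
  as_tibble(profile) |>
    group_by(.data$window_start, .data$window_end) |>
    summarise(
      mean_identity = mean(.data$identity, na.rm = TRUE),
      n_queries = sum(!is.na(.data$identity)),
      .groups = "drop"
    )
}
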