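# Internal helpers shared across modules. All coordinates inside the package
# are 0-based half-open; conversion to 1-based happens only at substr() calls.

DNA_BASES <- c("A", "C", "G", "T")

.rand_seq <- function(n) {
  if (n <= 0) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# substr with 0-based half-open interval
.sub0 <- function(s, start, end) {
  if (end <= start) return("")
  substr(s, start + 1, end)
}

.char_at <- function(s, pos0) substr(s, pos0 + 1, pos0 + 1)

# Accept a sequence as: character scalar (optionally named), or a one-row
# tibble/data.frame with columns id and sequence. Returns list(id, seq).
.as_seq <- function(x, default_id = "seq") {
  if (is.character(x) && length(x) == 1) {
    id <- names(x) %||% default_id
    return(list(id = id, seq = unname(x)))
  }
  if (is.data.frame(x)) {
    if (nrow(x) != 1) abort("expected a single sequence (one row)")
    return(list(id = as.character(x$id), seq = as.character(x$sequence)))
  }
  abort("cannot interpret input as a sequence")
}

# Accept a cohort as: tibble with id/sequence columns, or named character
# vector. Returns tibble(id, sequence).
.as_cohort <- function(x) {
  if (is.character(x)) {
    ids <- names(x) %||% paste0("seq", seq_along(x))
    return(tibble(id = ids, sequence = unname(x)))
  }
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "sequence") %in% names(x)))
    return(as_tibble(x[, c("id", "sequence")]))
  }
  abort("cannot interpret input as a cohort")
}

# Left-normalise an indel on the reference. pos0 is the 0-based reference
# position where the event starts; for a deletion-in-query the segment is the
# run of reference bases absent from the query, for an insertion-in-query it
# is the run of query bases absent from the reference. Shifts left while the
# alignment is preserved; returns list(pos, seg).
.left_normalise <- function(ref, pos0, seg, type) {
  len <- nchar(seg)
  if (type == "deletion_in_query") {
    while (pos0 > 0 && .char_at(ref, pos0 - 1) == .char_at(ref, pos0 + len - 1)) {
      pos0 <- pos0 - 1
    }
    seg <- .sub0(ref, pos0, pos0 + len)
  } else {
    while (pos0 > 0 && .char_at(ref, pos0 - 1) == substr(seg, len, len)) {
      seg <- paste0(.char_at(ref, pos0 - 1), substr(seg, 1, len - 1))
      pos0 <- pos0 - 1
    }
  }
  list(pos = pos0, seg = seg)
}

# All k-mer start strings of s (1-based starts). Returns character vector of
# length nchar(s) - k + 1 (empty if shorter than k).
.kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1), k:n)
}

# 1-based start positions of k-mers that occur exactly once in s and contain
# no N. Returns list(pos = integer, kmer = character).
.unique_kmers <- function(s, k) {
  kv <- .kmers(s, k)
  if (length(kv) == 0) return(list(pos = integer(0), kmer = character(0)))
  keep <- !(duplicated(kv) | duplicated(kv, fromLast = TRUE))
  keep <- keep & !grepl("N", kv, fixed = TRUE)
  list(pos = which(keep), kmer = kv[keep])
}

# Exact-match anchors between a and b from k-mers unique in both. Returns a
# tibble(qpos, tpos) of 1-based starts sorted by qpos.
.anchors <- function(a, b, k) {
  ua <- .unique_kmers(a, k)
  ub <- .unique_kmers(b, k)
  m <- match(ua$kmer, ub$kmer)
  hit <- !is.na(m)
  tibble(qpos = ua$pos[hit], tpos = ub$pos[m[hit]]) |> arrange(.data$qpos)
}

# Collapse anchors on the same diagonal with consecutive starts into maximal
# exact runs. Returns tibble(qstart, tstart, len) of 1-based starts.
.anchor_runs <- function(anch, k) {
  if (nrow(anch) == 0) {
    return(tibble(qstart = integer(0), tstart = integer(0), len = integer(0)))
  }
  d <- anch$tpos - anch$qpos
  new_run <- c(TRUE, diff(anch$qpos) != 1L | diff(d) != 0L)
  grp <- cumsum(new_run)
  qs <- tapply(anch$qpos, grp, min)
  qe <- tapply(anch$qpos, grp, max)
  ts <- tapply(anch$tpos, grp, min)
  tibble(
    qstart = as.integer(qs), tstart = as.integer(ts),
    len = as.integer(qe - qs + k)
  )
}

# Weighted longest-increasing-subsequence chain over anchor runs: selects a
# subset collinear in both coordinates maximising total run length. Ties are
# broken toward the leftmost chain. O(r^2); runs are thinned to the longest
# max_runs beforehand.
.chain_runs <- function(runs, max_runs = 4000) {
  r <- nrow(runs)
  if (r == 0) return(runs)
  if (r > max_runs) {
    keep <- order(runs$len, decreasing = TRUE)[seq_len(max_runs)]
    runs <- runs[sort(keep), ]
    r <- nrow(runs)
  }
  runs <- arrange(runs, .data$qstart, .data$tstart)
  score <- as.numeric(runs$len)
  prev <- rep(NA_integer_, r)
  qs <- runs$qstart; ts <- runs$tstart; ln <- runs$len
  for (i in seq_len(r)) {
    if (i == 1) next
    j <- which(qs[1:(i - 1)] < qs[i] & ts[1:(i - 1)] < ts[i])
    if (length(j)) {
      cand <- score[j] + ln[i]
      best <- which.max(cand)
      if (cand[best] > ln[i]) {
        score[i] <- cand[best]
        prev[i] <- j[best]
      }
    }
  }
  end <- which.max(score)
  path <- integer(0)
  while (!is.na(end)) {
    path <- c(end, path)
    end <- prev[end]
  }
  chain <- runs[path, ]
  # trim overlaps between consecutive runs (runs are exact matches so
  # trimming preserves exactness)
  if (nrow(chain) > 1) {
    for (i in 2:nrow(chain)) {
      ovl <- max(
        chain$qstart[i - 1] + chain$len[i - 1] - chain$qstart[i],
        chain$tstart[i - 1] + chain$len[i - 1] - chain$tstart[i],
        0
      )
      if (ovl > 0) {
        chain$qstart[i] <- chain$qstart[i] + ovl
        chain$tstart[i] <- chain$tstart[i] + ovl
        chain$len[i] <- chain$len[i] - ovl
      }
    }
    chain <- filter(chain, .data$len > 0)
  }
  chain
}

# Mismatch-tolerant extension walk used for boundary refinement: advance
# while a position predicate holds; an isolated failure is crossed only when
# the following `confirm` positions all hold. Returns the number of leading
# positions (0-based offsets) confirmed to hold.
.extend_predicate <- function(pred, max_steps, confirm = 12L) {
  i <- 0L
  matched <- 0L
  while (i < max_steps) {
    ok <- pred(i)
    if (is.na(ok)) break
    if (ok) {
      i <- i + 1L
      matched <- i
      next
    }
    cross <- i + confirm < max_steps
    if (cross) {
      for (t in seq_len(confirm)) {
        xt <- pred(i + t)
        if (is.na(xt) || !xt) {
          cross <- FALSE
          break
        }
      }
    }
    if (!cross) break
    i <- i + 1L  # cross the failing position; `matched` advances only once
    # the confirm window is consumed by the main loop
  }
  matched
}

# Character-pair form of the walk: matched leading positions where two
# accessor functions agree.
.extend_match <- function(char_a, char_b, max_steps, confirm = 12L) {
  .extend_predicate(function(i) {
    ca <- char_a(i)
    cb <- char_b(i)
    if (is.na(ca) || is.na(cb) || ca == "" || cb == "") return(NA)
    ca == cb
  }, max_steps = max_steps, confirm = confirm)
}

# Adjusted Rand index between two labelings of the same items.
#' Adjusted Rand index
#'
#' Agreement between two partitions of the same items, corrected for chance;
#' 1 means identical partitions, 0 is the expectation for random labelings.
#'
#' @param x,y label vectors of equal length (any atomic type).
#' @return a single numeric value.
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) > 0)
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  nch <- choose(sum(tab), 2)
  expected <- b * cc / nch
  maxi <- (b + cc) / 2
  if (maxi == expected) return(1)
  (a - expected) / (maxi - expected)
}
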