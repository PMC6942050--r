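# Shared fixtures, built in code. The threegroup simulation and its alignments
# against the m3 reference are cached so the files that need them share one
# computation.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# plant exactly n substitutions at distinct positions; returns list(seq, pos)
plant_subs <- function(s, n_subs, lo = 1, hi = nchar(s)) {
  idx <- lo:hi
  n_subs <- min(n_subs, length(idx))
  pos <- sort(idx[sample.int(length(idx), n_subs)])
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  list(seq = paste(chars, collapse = ""), pos = pos)
}

edit_dist_oracle <- function(a, b) {
  as.integer(utils::adist(a, b))
}

threegroup_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cohort("threegroup", seed = 42)
    cache
  }
})

# alignments of every member against the m3 reference (m3 carries no shared
# indel, so observed marker polarity equals the ancestral one)
threegroup_alignments <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    sim <- threegroup_sim()
    co <- sim$cohort
    ref <- setNames(co$sequence[co$id == "m3"], "m3")
    qids <- setdiff(co$id, "m3")
    alns <- lapply(qids, function(q) {
      dj_align(setNames(co$sequence[co$id == q], q), ref)
    })
    names(alns) <- qids
    cache <<- alns
    cache
  }
})

threegroup_marker_matrix <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    sim <- threegroup_sim()
    alns <- threegroup_alignments()
    calls <- dplyr::bind_rows(lapply(alns, call_indels))
    calls <- dplyr::filter(calls, ref_pos < sim$manifest$prox_end)
    mk <- match_breakpoints(calls)
    cache <<- build_marker_matrix(mk, alns)
    cache
  }
})

# brute-force four-gamete oracle: scan chromosomes and tick off each of the
# four joint patterns explicitly
four_gamete_oracle <- function(a, b) {
  seen <- c(`00` = FALSE, `01` = FALSE, `10` = FALSE, `11` = FALSE)
  for (i in seq_along(a)) {
    if (is.na(a[i]) || is.na(b[i])) next
    seen[paste0(a[i], b[i])] <- TRUE
  }
  all(seen)
}

# build a 2-marker matrix from presence vectors
two_marker_matrix <- function(a, b) {
  mk <- tibble::tibble(
    marker_id = c("Ma", "Mb"), ref_pos = c(100L, 200L),
    length = c(60L, 60L), type = "deletion_in_query"
  )
  marker_matrix(mk, paste0("c", seq_along(a)), rbind(Ma = a, Mb = b))
}
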