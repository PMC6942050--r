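# Synthetic DJ cohorts with full ground truth.
#
# An ancestor contig is laid out as: rDNA stub | unique1 | IR arm |
# spacer | revcomp(IR arm) | unique2 | satellite array | tail. A cohort
# evolves from it in two levels: each group first acquires shared structural
# events (indels with identical breakpoints by construction, foreign inserts
# into the satellite array) and group-level substitutions at a low proximal /
# high distal rate; each member then acquires independent substitutions at a
# small uniform rate. Optional exchange events transfer the suffix of a donor
# member onto a recipient at an ancestor-coordinate breakpoint
# (single-crossover model; two events compose to an interval transfer).
# Everything realized is recorded in a manifest that fully determines the
# cohort given the ancestor.

#' Bundled synthetic rDNA reference segment
#'
#' A deterministic pseudo-random 6-kb stand-in for an intergenic-spacer rDNA
#' segment, bundled so junction analysis and the simulator run without
#' external data. It is synthetic: it shares no homology with real rDNA.
#' Junction analysis accepts any user-supplied rDNA reference instead.
#'
#' @return a one-row contig tibble.
#' @export
rdna_reference <- function() {
  path <- system.file("extdata", "rdna_reference_synthetic.fa",
    package = "acrodj"
  )
  read_contigs(path)
}

#' Architecture of a synthetic DJ-like contig
#'
#' Lengths of the layout parts, in bp, in contig order. The default
#' desk-scale architecture totals 60 kb so the full pipeline runs in
#' seconds; `dj_preset("full_scale")` supplies a 400-kb architecture with
#' 100-kb-class inverted-repeat arms and a 40-kb satellite block.
#'
#' @param rdna_stub_len rDNA stub copied from [rdna_reference()].
#' @param unique1_len unique spacer before the inverted repeat.
#' @param ir_arm_len inverted-repeat arm length (arm 2 is the reverse
#'   complement of arm 1).
#' @param ir_spacer_len spacer between the arms.
#' @param unique2_len unique region between arm 2 and the satellite array.
#' @param satellite_period satellite monomer length (default 48, the CER
#'   monomer size).
#' @param satellite_len satellite array length.
#' @param tail_len distal unique tail.
#' @return an object of class `dj_architecture` with a `layout` tibble.
#' @export
dj_architecture <- function(rdna_stub_len = 2000, unique1_len = 10000,
                            ir_arm_len = 5000, ir_spacer_len = 1000,
                            unique2_len = 25000, satellite_period = 48,
                            satellite_len = 5000, tail_len = 7000) {
  lens <- c(
    rdna_stub = rdna_stub_len, unique1 = unique1_len, ir_arm1 = ir_arm_len,
    ir_spacer = ir_spacer_len, ir_arm2 = ir_arm_len, unique2 = unique2_len,
    satellite = satellite_len, tail = tail_len
  )
  if (any(lens < 0)) abort("architecture lengths must be >= 0")
  if (satellite_period < 2) abort("satellite_period must be >= 2")
  ends <- cumsum(lens)
  layout <- tibble(
    part = names(lens),
    start = as.integer(ends - lens),
    end = as.integer(ends)
  )
  structure(
    list(
      layout = layout, satellite_period = satellite_period,
      total_len = as.integer(ends[length(ends)]),
      proximal_len = as.integer(layout$start[layout$part == "satellite"]),
      rdna_stub_len = as.integer(rdna_stub_len)
    ),
    class = "dj_architecture"
  )
}

.layout_interval <- function(arch, part) {
  row <- arch$layout[arch$layout$part == part, ]
  c(row$start, row$end)
}

#' Build the ancestor contig of a synthetic cohort
#'
#' @param arch a [dj_architecture()].
#' @param seed integer seed; the same (arch, seed) always yields a
#'   byte-identical contig.
#' @param max_len guard against accidental huge layouts.
#' @return a list with `contig` (one-row tibble), `annotations` (tibble of
#'   rdna_stub / inverted_repeat_arm / satellite_block records) and `arch`.
#' @export
build_ancestor <- function(arch, seed = 1, max_len = 5e6) {
  stopifnot(inherits(arch, "dj_architecture"))
  if (arch$total_len > max_len) abort("architecture exceeds max_len")
  rdna <- rdna_reference()$sequence
  if (arch$rdna_stub_len > nchar(rdna)) {
    abort("rdna_stub_len longer than bundled rDNA reference")
  }
  seq <- withr::with_seed(seed, {
    stub <- .sub0(rdna, 0, arch$rdna_stub_len)
    u1 <- .rand_seq(.part_len(arch, "unique1"))
    arm <- .rand_seq(.part_len(arch, "ir_arm1"))
    sp <- .rand_seq(.part_len(arch, "ir_spacer"))
    u2 <- .rand_seq(.part_len(arch, "unique2"))
    monomer <- .rand_seq(arch$satellite_period)
    sat_len <- .part_len(arch, "satellite")
    sat <- .sub0(strrep(monomer, ceiling(sat_len / arch$satellite_period)), 0, sat_len)
    tl <- .rand_seq(.part_len(arch, "tail"))
    paste0(stub, u1, arm, sp, if (nchar(arm)) .revcomp(arm) else "", u2, sat, tl)
  })
  stopifnot(nchar(seq) == arch$total_len)
  ann_parts <- c(
    rdna_stub = "rdna_stub", ir_arm1 = "inverted_repeat_arm",
    ir_arm2 = "inverted_repeat_arm", satellite = "satellite_block"
  )
  keep <- names(ann_parts)[vapply(names(ann_parts), function(p) .part_len(arch, p) > 0, TRUE)]
  ann <- annotation_records(
    contig_id = "ancestor",
    start = vapply(keep, function(p) .layout_interval(arch, p)[1], 0),
    end = vapply(keep, function(p) .layout_interval(arch, p)[2], 0),
    feature_class = unname(ann_parts[keep]),
    attributes = ifelse(
      keep == "satellite", paste0("period=", arch$satellite_period), "."
    ),
    contig_length = arch$total_len
  )
  contig <- tibble(
    id = "ancestor", source = "simulated", chromosome = NA_character_,
    length = arch$total_len, sequence = seq
  )
  list(contig = contig, annotations = ann, arch = arch)
}

.part_len <- function(arch, part) {
  iv <- .layout_interval(arch, part)
  iv[2] - iv[1]
}

#' Specification of a synthetic cohort
#'
#' @param groups named list: group id -> character vector of member ids.
#'   Every member belongs to exactly one group.
#' @param proximal_sub_rate,distal_sub_rate group-lineage substitution rates
#'   (substitutions/bp from the ancestor) over the proximal region and the
#'   distal region (satellite array onward). Defaults reproduce the
#'   qualitative identity gradient of real DJ cohorts: ~99% proximal
#'   identity between groups and <90% distal.
#' @param member_sub_rate uniform member-level substitution rate (within a
#'   group); the default 2.5e-4 gives ~99.95% identity between members of a
#'   group.
#' @param shared_indels tibble with columns `groups` (list column of group
#'   ids), `pos` (0-based ancestor coordinate), `len`, `type`
#'   (`"deletion"` or `"insertion"`). Must lie inside the proximal region;
#'   breakpoints are identical within a group by construction.
#' @param foreign_inserts tibble with columns `groups` (list column),
#'   `satellite_offset` (0-based, within the satellite array), `len`. Each
#'   row is one integration event with its own random sequence.
#' @param exchange_events tibble with columns `recipient`, `donor` (member
#'   ids) and `breakpoint` (0-based ancestor coordinate); applied in row
#'   order, each replaces the recipient's suffix from the breakpoint onward
#'   with the donor's.
#' @param seed integer seed for [evolve_cohort()].
#' @return an object of class `dj_cohort_spec`.
#' @export
dj_cohort_spec <- function(groups,
                           proximal_sub_rate = 0.005,
                           distal_sub_rate = 0.06,
                           member_sub_rate = 2.5e-4,
                           shared_indels = NULL,
                           foreign_inserts = NULL,
                           exchange_events = NULL,
                           seed = 1) {
  rates <- c(proximal_sub_rate, distal_sub_rate, member_sub_rate)
  if (any(rates < 0) || any(rates > 0.5)) abort("rates must be in [0, 0.5]")
  members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(members)) abort("every member must appear in exactly one group")
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    abort("groups must be a named list")
  }
  empty_indels <- tibble(
    groups = list(), pos = integer(0), len = integer(0), type = character(0)
  )
  empty_ins <- tibble(groups = list(), satellite_offset = integer(0), len = integer(0))
  empty_ex <- tibble(recipient = character(0), donor = character(0), breakpoint = integer(0))
  shared_indels <- shared_indels %||% empty_indels
  foreign_inserts <- foreign_inserts %||% empty_ins
  exchange_events <- exchange_events %||% empty_ex
  if (nrow(shared_indels) && !all(shared_indels$type %in% c("deletion", "insertion"))) {
    abort("shared indel type must be 'deletion' or 'insertion'")
  }
  structure(
    list(
      groups = groups,
      proximal_sub_rate = proximal_sub_rate,
      distal_sub_rate = distal_sub_rate,
      member_sub_rate = member_sub_rate,
      shared_indels = shared_indels,
      foreign_inserts = foreign_inserts,
      exchange_events = exchange_events,
      seed = as.integer(seed)
    ),
    class = "dj_cohort_spec"
  )
}

# ---- coordinate machinery ---------------------------------------------------

# Segment map from ancestor to lineage coordinates given structural events on
# ancestor coordinates. events: tibble(pos, len, type in deletion/insertion).
# Returns tibble(anc_start, anc_end, offset): member_pos = anc_pos + offset.
.build_map <- function(n0, events) {
  if (nrow(events) == 0) {
    return(tibble(anc_start = 0L, anc_end = as.integer(n0), offset = 0L))
  }
  events <- arrange(events, .data$pos)
  segs <- list()
  prev <- 0L
  shift <- 0L
  for (i in seq_len(nrow(events))) {
    p <- events$pos[i]; L <- events$len[i]
    if (p > prev) segs[[length(segs) + 1]] <- c(prev, p, shift)
    if (events$type[i] == "deletion") {
      prev <- as.integer(p + L)
      shift <- shift - as.integer(L)
    } else {
      prev <- as.integer(p)
      shift <- shift + as.integer(L)
    }
  }
  if (prev < n0) segs[[length(segs) + 1]] <- c(prev, n0, shift)
  m <- do.call(rbind, segs)
  tibble(
    anc_start = as.integer(m[, 1]), anc_end = as.integer(m[, 2]),
    offset = as.integer(m[, 3])
  )
}

# Map a single ancestor position through a segment map. Positions inside a
# deleted span map to the left edge of the following segment.
.map_pos <- function(segs, p) {
  hit <- which(segs$anc_start <= p & p < segs$anc_end)
  if (length(hit)) return(p + segs$offset[hit[1]])
  nxt <- which(segs$anc_start >= p)
  if (length(nxt)) {
    i <- nxt[1]
    return(segs$anc_start[i] + segs$offset[i])
  }
  segs$anc_end[nrow(segs)] + segs$offset[nrow(segs)]
}

.clip_segs <- function(segs, from, to) {
  out <- filter(segs, .data$anc_end > from, .data$anc_start < to)
  mutate(out,
    anc_start = pmax(.data$anc_start, as.integer(from)),
    anc_end = pmin(.data$anc_end, as.integer(to))
  )
}

.owner_at <- function(owner_segs, p) {
  hit <- which(owner_segs$anc_start <= p & p < owner_segs$anc_end)
  if (!length(hit)) return(NA_character_)
  owner_segs$group[hit[1]]
}

# Apply structural events (with realized sequences for insertions) to a
# sequence; events on the current coordinate system of `seq`.
.apply_events <- function(seq, events) {
  if (nrow(events) == 0) return(seq)
  events <- arrange(events, dplyr::desc(.data$pos))
  for (i in seq_len(nrow(events))) {
    p <- events$pos[i]; L <- events$len[i]
    if (events$type[i] == "deletion") {
      seq <- paste0(.sub0(seq, 0, p), .sub0(seq, p + L, nchar(seq)))
    } else {
      seq <- paste0(.sub0(seq, 0, p), events$seq[i], .sub0(seq, p, nchar(seq)))
    }
  }
  seq
}

# Draw Bernoulli substitutions over chars[range] at `rate`; returns
# tibble(pos (1-based), from, to).
.draw_subs <- function(chars, from, to, rate) {
  if (to < from || rate <= 0) {
    return(tibble(pos = integer(0), from = character(0), to = character(0)))
  }
  idx <- from - 1L + which(runif(to - from + 1L) < rate)
  if (!length(idx)) {
    return(tibble(pos = integer(0), from = character(0), to = character(0)))
  }
  old <- chars[idx]
  new <- vapply(old, function(b) sample(setdiff(DNA_BASES, b), 1), "",
    USE.NAMES = FALSE
  )
  tibble(pos = as.integer(idx), from = old, to = new)
}

.apply_subs <- function(chars, subs) {
  if (nrow(subs)) chars[subs$pos] <- subs$to
  chars
}

# ---- evolution --------------------------------------------------------------

#' Evolve a synthetic cohort from an ancestor
#'
#' See [dj_cohort_spec()] for the model. Identical `(ancestor, spec)` always
#' produce identical cohorts and manifests.
#'
#' @param ancestor result of [build_ancestor()].
#' @param spec a [dj_cohort_spec()].
#' @return a list with `cohort` (contig tibble, one row per member, with the
#'   group id in the `chromosome` column) and `manifest` (ground truth: all
#'   realized events, coordinate maps, segment ownership, junction truth).
#' @export
evolve_cohort <- function(ancestor, spec) {
  stopifnot(inherits(spec, "dj_cohort_spec"))
  arch <- ancestor$arch
  S0 <- ancestor$contig$sequence
  n0 <- nchar(S0)
  prox_end <- arch$proximal_len
  sat_start <- .layout_interval(arch, "satellite")[1]

  si <- spec$shared_indels
  if (nrow(si)) {
    if (any(si$pos < 0) ||
      any(si$pos + ifelse(si$type == "deletion", si$len, 0L) > prox_end)) {
      abort("shared indels must lie inside the proximal region")
    }
    del <- filter(si, .data$type == "deletion")
    if (nrow(del) > 1) {
      d <- arrange(del, .data$pos)
      if (any(d$pos[-1] < (d$pos + d$len)[-nrow(d)])) {
        abort("overlapping shared indels")
      }
    }
  }
  fi <- spec$foreign_inserts
  if (nrow(fi)) {
    sat_len <- .part_len(arch, "satellite")
    if (any(fi$satellite_offset < 0) || any(fi$satellite_offset > sat_len)) {
      abort("foreign insert offset outside satellite array")
    }
  }
  ex <- spec$exchange_events
  if (nrow(ex)) {
    if (any(ex$breakpoint <= 0) || any(ex$breakpoint >= n0)) {
      abort("exchange breakpoint outside contig")
    }
    if (nrow(si)) {
      dels <- filter(si, .data$type == "deletion")
      for (bp in ex$breakpoint) {
        if (any(dels$pos < bp & bp < dels$pos + dels$len)) {
          abort("exchange breakpoint inside a shared indel")
        }
      }
    }
  }

  members <- unlist(spec$groups, use.names = FALSE)
  all_ids <- c(members, ex$recipient, ex$donor)
  if (!all(c(ex$recipient, ex$donor) %in% members)) {
    abort("exchange recipient/donor must be cohort members")
  }

  res <- withr::with_seed(spec$seed, {
    # realized sequences for insertion-type events, fixed before lineages
    si$seq <- if (nrow(si)) {
      ifelse(si$type == "insertion", vapply(si$len, .rand_seq, ""), NA_character_)
    } else {
      character(0)
    }
    fi$seq <- if (nrow(fi)) vapply(fi$len, .rand_seq, "") else character(0)

    group_events <- list()
    lineage_chars <- list()
    maps0 <- list()
    for (g in names(spec$groups)) {
      mine_i <- if (nrow(si)) vapply(si$groups, function(x) g %in% x, TRUE) else logical(0)
      mine_f <- if (nrow(fi)) vapply(fi$groups, function(x) g %in% x, TRUE) else logical(0)
      ind <- si[mine_i, , drop = FALSE]
      ins <- fi[mine_f, , drop = FALSE]
      ev <- bind_rows(
        tibble(
          pos = integer(0), len = integer(0), type = character(0),
          seq = character(0)
        ),
        if (nrow(ind)) tibble(
          pos = as.integer(ind$pos), len = as.integer(ind$len),
          type = ind$type, seq = ind$seq
        ),
        if (nrow(ins)) tibble(
          pos = as.integer(sat_start + ins$satellite_offset),
          len = as.integer(ins$len), type = "insertion", seq = ins$seq
        )
      )
      ev <- arrange(ev, .data$pos)
      segs <- .build_map(n0, ev)
      sg <- .apply_events(S0, ev)
      chars <- strsplit(sg, "", fixed = TRUE)[[1]]
      pe <- .map_pos(segs, prox_end)
      subs_p <- .draw_subs(chars, 1L, pe, spec$proximal_sub_rate)
      subs_d <- .draw_subs(chars, pe + 1L, length(chars), spec$distal_sub_rate)
      subs <- bind_rows(subs_p, subs_d)
      chars <- .apply_subs(chars, subs)
      group_events[[g]] <- list(events = ev, subs = subs)
      lineage_chars[[g]] <- chars
      maps0[[g]] <- segs
    }

    seqs <- list(); maps <- list(); owners <- list(); member_subs <- list()
    for (g in names(spec$groups)) {
      for (m in spec$groups[[g]]) {
        chars <- lineage_chars[[g]]
        subs <- .draw_subs(chars, 1L, length(chars), spec$member_sub_rate)
        chars <- .apply_subs(chars, subs)
        seqs[[m]] <- paste(chars, collapse = "")
        maps[[m]] <- maps0[[g]]
        owners[[m]] <- tibble(
          anc_start = 0L, anc_end = as.integer(n0), group = g
        )
        member_subs[[m]] <- subs
      }
    }

    ex_real <- ex
    ex_real$recipient_pos <- integer(nrow(ex))
    ex_real$donor_pos <- integer(nrow(ex))
    if (nrow(ex)) {
      for (i in seq_len(nrow(ex))) {
        r <- ex$recipient[i]; d <- ex$donor[i]; bp <- as.integer(ex$breakpoint[i])
        mr <- .map_pos(maps[[r]], bp)
        md <- .map_pos(maps[[d]], bp)
        seqs[[r]] <- paste0(
          .sub0(seqs[[r]], 0, mr), .sub0(seqs[[d]], md, nchar(seqs[[d]]))
        )
        donor_segs <- .clip_segs(maps[[d]], bp, n0)
        donor_segs$offset <- donor_segs$offset + (mr - md)
        maps[[r]] <- bind_rows(.clip_segs(maps[[r]], 0L, bp), donor_segs)
        owners[[r]] <- bind_rows(
          .clip_segs(owners[[r]], 0L, bp), .clip_segs(owners[[d]], bp, n0)
        )
        ex_real$recipient_pos[i] <- mr
        ex_real$donor_pos[i] <- md
      }
    }
    list(
      si = si, fi = fi, group_events = group_events, seqs = seqs,
      maps = maps, owners = owners, member_subs = member_subs, ex = ex_real
    )
  })

  rdna <- rdna_reference()$sequence
  junctions <- purrr::map_dfr(members, function(m) {
    e <- .map_pos(res$maps[[m]], arch$rdna_stub_len)
    seqm <- res$seqs[[m]]
    t <- 0L
    while (arch$rdna_stub_len + t < nchar(rdna) && e + t < nchar(seqm) &&
      .char_at(seqm, e + t) == .char_at(rdna, arch$rdna_stub_len + t)) {
      t <- t + 1L
    }
    tibble(id = m, stub_end = e, junction_obs = e + t)
  })

  grp_of <- setNames(
    rep(names(spec$groups), lengths(spec$groups)), members
  )
  cohort <- tibble(
    id = members,
    source = "simulated",
    chromosome = unname(grp_of[members]),
    length = vapply(members, function(m) nchar(res$seqs[[m]]), 0L, USE.NAMES = FALSE),
    sequence = vapply(members, function(m) res$seqs[[m]], "", USE.NAMES = FALSE)
  )

  # ancestor-normalised positions of the shared indels (ground truth)
  si <- res$si
  si$anc_seg <- if (nrow(si)) {
    vapply(seq_len(nrow(si)), function(i) {
      if (si$type[i] == "deletion") {
        .sub0(S0, si$pos[i], si$pos[i] + si$len[i])
      } else {
        si$seq[i]
      }
    }, "")
  } else {
    character(0)
  }
  si$norm_pos <- if (nrow(si)) {
    vapply(seq_len(nrow(si)), function(i) {
      seg <- if (si$type[i] == "deletion") {
        .sub0(S0, si$pos[i], si$pos[i] + si$len[i])
      } else {
        si$seq[i]
      }
      type <- if (si$type[i] == "deletion") "deletion_in_query" else "insertion_in_query"
      .left_normalise(S0, si$pos[i], seg, type)$pos
    }, 0L)
  } else {
    integer(0)
  }

  manifest <- structure(
    list(
      seed = spec$seed, n0 = n0, prox_end = prox_end, sat_start = sat_start,
      arch = arch, groups = spec$groups,
      rates = list(
        proximal = spec$proximal_sub_rate, distal = spec$distal_sub_rate,
        member = spec$member_sub_rate
      ),
      shared_indels = si, foreign_inserts = res$fi,
      group_events = res$group_events, member_subs = res$member_subs,
      exchanges = res$ex, maps = res$maps, owners = res$owners,
      junctions = junctions
    ),
    class = "dj_manifest"
  )
  list(cohort = cohort, manifest = manifest)
}

#' Replay a manifest without random number generation
#'
#' Reconstructs every member sequence from the recorded events alone; used to
#' verify that the manifest fully determines the cohort.
#'
#' @param ancestor result of [build_ancestor()].
#' @param manifest a `dj_manifest`.
#' @return named character vector of member sequences.
#' @export
replay_manifest <- function(ancestor, manifest) {
  S0 <- ancestor$contig$sequence
  lineage <- list()
  for (g in names(manifest$groups)) {
    ge <- manifest$group_events[[g]]
    sg <- .apply_events(S0, ge$events)
    chars <- .apply_subs(strsplit(sg, "", fixed = TRUE)[[1]], ge$subs)
    lineage[[g]] <- chars
  }
  seqs <- list()
  for (g in names(manifest$groups)) {
    for (m in manifest$groups[[g]]) {
      chars <- .apply_subs(lineage[[g]], manifest$member_subs[[m]])
      seqs[[m]] <- paste(chars, collapse = "")
    }
  }
  ex <- manifest$exchanges
  if (nrow(ex)) {
    for (i in seq_len(nrow(ex))) {
      r <- ex$recipient[i]; d <- ex$donor[i]
      seqs[[r]] <- paste0(
        .sub0(seqs[[r]], 0, ex$recipient_pos[i]),
        .sub0(seqs[[d]], ex$donor_pos[i], nchar(seqs[[d]]))
      )
    }
  }
  unlist(seqs)
}

#' Expected marker matrix implied by a manifest
#'
#' Derives, by coordinate arithmetic alone (no alignment), the indel markers
#' that calling every member against `reference_id` should produce: observed
#' type (inverted when the reference itself carries a variant), observed
#' carrier sets after exchange events, and left-normalised positions on the
#' reference sequence.
#'
#' @param manifest a `dj_manifest`.
#' @param reference_id member used as the call reference.
#' @param reference_seq the reference member's sequence.
#' @return a `dj_marker_matrix` (see [marker_matrix()]) whose columns are all
#'   members except the reference.
#' @export
manifest_expected_markers <- function(manifest, reference_id, reference_seq) {
  si <- manifest$shared_indels
  members <- unlist(manifest$groups, use.names = FALSE)
  queries <- setdiff(members, reference_id)
  if (nrow(si) == 0) {
    return(marker_matrix(
      tibble(
        marker_id = character(0), ref_pos = integer(0), length = integer(0),
        type = character(0)
      ),
      queries,
      matrix(integer(0), 0, length(queries), dimnames = list(NULL, queries))
    ))
  }
  rows <- purrr::map(seq_len(nrow(si)), function(i) {
    p <- si$pos[i]; L <- si$len[i]
    carriers_anc <- members[vapply(members, function(m) {
      .owner_at(manifest$owners[[m]], p) %in% si$groups[[i]]
    }, TRUE)]
    ref_carries <- reference_id %in% carriers_anc
    refmap <- manifest$maps[[reference_id]]
    if (!ref_carries) {
      obs_type <- if (si$type[i] == "deletion") "deletion_in_query" else "insertion_in_query"
      obs_carriers <- intersect(carriers_anc, queries)
    } else {
      obs_type <- if (si$type[i] == "deletion") "insertion_in_query" else "deletion_in_query"
      obs_carriers <- setdiff(queries, carriers_anc)
    }
    p_ref <- .map_pos(refmap, p)
    seg <- if (obs_type == "deletion_in_query") {
      .sub0(reference_seq, p_ref, p_ref + L)
    } else if (si$type[i] == "deletion") {
      # reference carries the deletion; queries insert the ancestral segment
      .sub0(manifest_ancestor_segment(manifest, i), 0, L)
    } else {
      si$seq[i]
    }
    norm <- .left_normalise(reference_seq, p_ref, seg, obs_type)
    tibble(
      ref_pos = as.integer(norm$pos), length = as.integer(L), type = obs_type,
      carriers = list(obs_carriers)
    )
  })
  tab <- bind_rows(rows) |> arrange(.data$ref_pos)
  tab$marker_id <- sprintf("M%02d", seq_len(nrow(tab)))
  presence <- matrix(
    0L, nrow(tab), length(queries),
    dimnames = list(tab$marker_id, queries)
  )
  for (i in seq_len(nrow(tab))) presence[i, tab$carriers[[i]]] <- 1L
  marker_matrix(
    select(tab, "marker_id", "ref_pos", "length", "type"), queries, presence
  )
}

# ancestral segment of shared indel i (used when the reference carries a
# deletion and other members keep the ancestral bases)
manifest_ancestor_segment <- function(manifest, i) {
  # the manifest does not store the ancestor; reconstructable only through
  # build_ancestor, so store the segment on the indel table at evolve time
  si <- manifest$shared_indels
  si$anc_seg[i] %||% abort("ancestral segment not recorded")
}

#' Cohort presets
#'
#' * `"minimal"`: one group of two members, no structural events; fastest.
#' * `"threegroup"`: the default desk-scale scenario: a ~60-kb ancestor, three
#'   groups `g1 = {m1, m2}`, `g2 = {m3, m4}`, `g3 = {m5, m6, m7}`, three
#'   shared deletions in the left inverted-repeat arm (A carried by g3; B and
#'   C carried by g1), one foreign insert per group in the satellite array,
#'   and member m7 made recombinant by two suffix exchanges (from the g1
#'   lineage between A and B, back to the g3 lineage after C) so that m7
#'   carries A together with B and C while still grouping with g3 at its
#'   distal end.
#' * `"full_scale"`: the same scenario on a 400-kb architecture with 105-kb
#'   inverted-repeat arms, a 40-kb satellite block, and the three deletions
#'   of 1.5 / 0.3 / 5 kb at 110 / 161 / 172 kb. Stress testing only.
#'
#' @param name preset name.
#' @param seed integer seed (ancestor uses `seed`, cohort evolution
#'   `seed + 1`).
#' @return list with `arch` and `spec`.
#' @seealso [simulate_cohort()]
#' @export
dj_preset <- function(name = c("threegroup", "minimal", "full_scale"), seed = 42) {
  name <- match.arg(name)
  if (name == "minimal") {
    arch <- dj_architecture(
      rdna_stub_len = 1000, unique1_len = 4000, ir_arm_len = 2000,
      ir_spacer_len = 500, unique2_len = 5000, satellite_len = 2400,
      tail_len = 3000
    )
    spec <- dj_cohort_spec(
      groups = list(g1 = c("m1", "m2")), seed = seed + 1L
    )
    return(list(arch = arch, spec = spec, seed = seed))
  }
  if (name == "threegroup") {
    arch <- dj_architecture()  # 60-kb default: arm1 spans [12000, 17000)
    indels <- tibble(
      groups = list("g3", "g1", "g1"),
      pos = c(13500L, 15200L, 16200L),
      len = c(1500L, 300L, 500L),
      type = "deletion"
    )
    inserts <- tibble(
      groups = list("g1", "g2", "g3"),
      satellite_offset = c(1000L, 2500L, 4000L),
      len = c(800L, 800L, 800L)
    )
    exchanges <- tibble(
      recipient = c("m7", "m7"),
      donor = c("m1", "m5"),
      breakpoint = c(15100L, 40000L)
    )
  } else {
    arch <- dj_architecture(
      rdna_stub_len = 4000, unique1_len = 96000, ir_arm_len = 105000,
      ir_spacer_len = 10000, unique2_len = 10000, satellite_len = 40000,
      tail_len = 30000
    )
    indels <- tibble(
      groups = list("g3", "g1", "g1"),
      pos = c(110000L, 161000L, 172000L),
      len = c(1500L, 300L, 5000L),
      type = "deletion"
    )
    inserts <- tibble(
      groups = list("g1", "g2", "g3"),
      satellite_offset = c(5000L, 18000L, 31000L),
      len = c(9000L, 6000L, 6000L)
    )
    exchanges <- tibble(
      recipient = c("m7", "m7"),
      donor = c("m1", "m5"),
      breakpoint = c(135000L, 325000L)
    )
  }
  spec <- dj_cohort_spec(
    groups = list(
      g1 = c("m1", "m2"), g2 = c("m3", "m4"), g3 = c("m5", "m6", "m7")
    ),
    shared_indels = indels,
    foreign_inserts = inserts,
    exchange_events = exchanges,
    seed = seed + 1L
  )
  list(arch = arch, spec = spec, seed = seed)
}

#' Simulate a cohort from a preset
#'
#' Convenience wrapper: builds the ancestor and evolves the cohort.
#'
#' @inheritParams dj_preset
#' @return list with `ancestor`, `cohort`, `manifest`.
#' @export
simulate_cohort <- function(name = c("threegroup", "minimal", "full_scale"),
                            seed = 42) {
  p <- dj_preset(name, seed)
  anc <- build_ancestor(p$arch, p$seed)
  ev <- evolve_cohort(anc, p$spec)
  list(ancestor = anc, cohort = ev$cohort, manifest = ev$manifest)
}
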