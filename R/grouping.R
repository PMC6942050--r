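# Classification of contigs from pairwise substitution distances over a
# region (whole contigs or distal tails), replacing a multiple-alignment tree
# with a fully specified distance + average-linkage procedure. Classification
# of DJ contigs is driven primarily by their distal ends, so the terminal
# region is the default for grouping.

#' Pairwise substitution distance matrix over a cohort
#'
#' Distances are substitutions per aligned site (columns opposite N
#' excluded) from a pairwise alignment of the chosen region.
#'
#' @param cohort contig tibble (or named character vector) with >= 2
#'   members.
#' @param region `"whole"` or `"terminal"` (the final `tail_bp` of each
#'   contig; contigs shorter than `tail_bp` are used whole, with a warning).
#' @param tail_bp terminal tail length in bp (default 100 kb, the region
#'   where between-group identity drops below 90%).
#' @inheritParams dj_align
#' @return a `dj_dist` object (symmetric matrix with labels).
#' @export
distance_matrix <- function(cohort, region = c("terminal", "whole"),
                            tail_bp = 100000, k = 21, dp_max_area = 64e6,
                            band_pad = 512) {
  region <- match.arg(region)
  cohort <- .as_cohort(cohort)
  if (nrow(cohort) < 2) abort("need at least two contigs")
  seqs <- cohort$sequence
  ids <- cohort$id
  if (region == "terminal") {
    short <- nchar(seqs) < tail_bp
    if (any(short)) {
      warn(paste0(
        "contigs shorter than tail_bp used whole: ",
        paste(ids[short], collapse = ", ")
      ))
    }
    seqs <- ifelse(
      short, seqs,
      substring(seqs, nchar(seqs) - tail_bp + 1L, nchar(seqs))
    )
  }
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      aln <- tryCatch(
        dj_align(
          setNames(seqs[i], ids[i]), setNames(seqs[j], ids[j]),
          k = k, dp_max_area = dp_max_area, band_pad = band_pad
        ),
        dj_unalignable = function(e) {
          abort(sprintf("unalignable pair: %s vs %s", ids[i], ids[j]))
        }
      )
      if (aln$aligned_columns == 0) {
        abort(sprintf("unalignable pair: %s vs %s", ids[i], ids[j]))
      }
      m[i, j] <- m[j, i] <- aln$substitutions / aln$aligned_columns
    }
  }
  structure(m, region = region, tail_bp = tail_bp, class = c("dj_dist", "matrix"))
}

#' Long-format distances
#'
#' @param x a `dj_dist`.
#' @param ... unused.
#' @return tibble: `a`, `b`, `distance` (each unordered pair once).
#' @method tidy dj_dist
#' @export
tidy.dj_dist <- function(x, ...) {
  ids <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble(
    a = ids[idx[, 1]], b = ids[idx[, 2]],
    distance = x[idx]
  )
}

#' Build a relationship tree from a distance matrix
#'
#' `average_linkage` (UPGMA-style hierarchical clustering) is the default
#' and supports group cutting; `neighbor_joining` is provided for display.
#' Labels are processed in sorted order so the result does not depend on
#' input order; remaining ties follow hclust's documented behaviour.
#'
#' @param D a `dj_dist`.
#' @param method `"average_linkage"` or `"neighbor_joining"`.
#' @return a `dj_tree`: list with `phylo` (ape tree with branch lengths),
#'   `hclust` (average linkage only), `method`, `labels`.
#' @export
build_tree <- function(D, method = c("average_linkage", "neighbor_joining")) {
  method <- match.arg(method)
  ids <- sort(rownames(D))
  m <- unclass(D)[ids, ids]
  if (method == "average_linkage") {
    hc <- hclust(as.dist(m), method = "average")
    phy <- ape::as.phylo(hc)
    # as.phylo halves heights into branch lengths so a 2-leaf tree at
    # distance d gets two branches of d/2
    structure(
      list(phylo = phy, hclust = hc, method = method, labels = ids),
      class = "dj_tree"
    )
  } else {
    phy <- ape::nj(as.dist(m))
    structure(
      list(phylo = phy, hclust = NULL, method = method, labels = ids),
      class = "dj_tree"
    )
  }
}

#' Serialize a tree to Newick
#'
#' @param tree a `dj_tree`.
#' @param path output path; when NULL the Newick string is returned.
#' @return the Newick string (invisibly when written to `path`).
#' @export
write_tree_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree$phylo)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Cut a tree into groups
#'
#' For `k`, the partition obtained by removing the k-1 highest merges of the
#' average-linkage tree. For `cut_height`, the tree cut is additionally
#' checked against the connected components of the graph joining pairs at
#' distance <= cut_height; a mismatch signals non-ultrametric structure and
#' is an error (choose `k` instead).
#'
#' @param tree a `dj_tree` built with `average_linkage`.
#' @param D the `dj_dist` the tree was built from (required for
#'   `cut_height`).
#' @param k requested number of groups.
#' @param cut_height distance threshold.
#' @return a `dj_grouping`: list with `groups` tibble (`id`, `group`),
#'   `tree`, `k`, `cut_height`. Group ids are integers numbered by first
#'   appearance in sorted label order.
#' @export
assign_groups <- function(tree, D = NULL, k = NULL, cut_height = NULL) {
  stopifnot(inherits(tree, "dj_tree"))
  if (is.null(tree$hclust)) {
    abort("group assignment requires an average_linkage tree")
  }
  if (is.null(k) == is.null(cut_height)) {
    abort("supply exactly one of k or cut_height")
  }
  if (!is.null(k)) {
    part <- cutree(tree$hclust, k = k)
  } else {
    if (is.null(D)) abort("cut_height requires the distance matrix D")
    part <- cutree(tree$hclust, h = cut_height)
    comp <- .threshold_components(unclass(D)[tree$labels, tree$labels], cut_height)
    if (adjusted_rand_index(part, comp) < 1) {
      abort(paste0(
        "threshold partition inconsistent with tree cut ",
        "(non-ultrametric structure); use k instead"
      ))
    }
  }
  ids <- names(part)
  grp <- as.integer(factor(part, levels = unique(part[order(ids)])))
  structure(
    list(
      groups = tibble(id = ids, group = grp[match(ids, ids)]),
      tree = tree, k = k, cut_height = cut_height
    ),
    class = "dj_grouping"
  )
}

# connected components under distance <= h (union-find)
.threshold_components <- function(m, h) {
  n <- nrow(m)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (m[i, j] <= h) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  vapply(seq_len(n), find, 0L)
}

#' @export
print.dj_grouping <- function(x, ...) {
  cat(sprintf(
    "<dj_grouping> %d contigs in %d groups (%s)\n",
    nrow(x$groups), length(unique(x$groups$group)),
    if (!is.null(x$k)) paste0("k = ", x$k) else paste0("cut = ", x$cut_height)
  ))
  print(x$groups, n = Inf)
  invisible(x)
}

#' Group assignments as a tibble
#'
#' @param x a `dj_grouping`.
#' @param ... unused.
#' @method tidy dj_grouping
#' @export
tidy.dj_grouping <- function(x, ...) x$groups

#' One-row grouping summary
#'
#' @param x a `dj_grouping`.
#' @param ... unused.
#' @method glance dj_grouping
#' @export
glance.dj_grouping <- function(x, ...) {
  tibble(
    n_contigs = nrow(x$groups),
    n_groups = length(unique(x$groups$group)),
    method = x$tree$method,
    k = x$k %||% NA_integer_,
    cut_height = x$cut_height %||% NA_real_
  )
}
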