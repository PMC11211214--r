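# Leakage-free genomic data splitting: gap-based single-linkage grouping
# along each chromosome, chromosome holdout, and nested stratified group
# k-folds assigned by deterministic greedy bin-packing.

#' Assign elements to genomic groups
#'
#' Single-linkage clustering along each chromosome: elements sorted by start
#' belong to the same group while the gap between consecutive elements
#' (start of the next minus end of the previous) stays below `gap_bp`; a gap
#' of at least `gap_bp` starts a new group. Elements on different
#' chromosomes never share a group.
#'
#' @param elements Element table.
#' @param gap_bp Minimum separating gap in bp (default 5 Mb).
#' @return `data.table` mapping `element_id` to integer `group_id`.
#' @export
assign_groups <- function(elements, gap_bp = 5e6) {
  if (gap_bp <= 0) stop("gap_bp must be positive")
  el <- data.table::as.data.table(elements)[order(chrom, start)]
  el[, gap := start - data.table::shift(end), by = chrom]
  el[, new_group := is.na(gap) | gap >= gap_bp]
  el[, group_id := cumsum(new_group)]
  el[, .(element_id, group_id)]
}

#' Group of each EP pair, with endpoint-group merging
#'
#' Each pair inherits the group of its endpoints; when the enhancer and TSS
#' fall in different groups the two groups are merged transitively
#' (union-find) before fold assignment, so a group can never span folds via
#' a bridging pair.
#'
#' @param ep Candidate table.
#' @param element_groups Output of [assign_groups()].
#' @return Integer vector of merged group ids aligned to `ep` rows.
#' @export
ep_groups <- function(ep, element_groups) {
  g <- stats::setNames(element_groups$group_id, element_groups$element_id)
  ge <- g[ep$enhancer_id]
  gt <- g[ep$tss_id]
  if (anyNA(ge) || anyNA(gt)) stop("EP endpoints missing from group table")
  n <- max(element_groups$group_id)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_len(nrow(ep))) {
    a <- find(ge[i]); b <- find(gt[i])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(roots[ge])
}

#' Chromosome holdout split
#'
#' Pairs whose TSS lies on a holdout chromosome form the test set (pairs are
#' intra-chromosomal, so either endpoint gives the same split).
#'
#' @param ep Candidate table with a `chrom` column.
#' @param holdout_chroms Character vector of held-out chromosome names.
#' @return Logical vector, `TRUE` for test rows.
#' @export
chromosome_holdout <- function(ep, holdout_chroms) {
  ep$chrom %in% holdout_chroms
}

#' Nested stratified group k-fold plan
#'
#' Whole groups are assigned to outer folds by a greedy bin-packing that
#' processes groups in decreasing order of (positive count, size), with a
#' seeded shuffle breaking ties, and places each group into the fold with
#' the fewest positives so far (then fewest rows). Within each outer
#' training split the same procedure yields the inner folds. No group ever
#' spans folds.
#'
#' @param groups Integer group id per pair.
#' @param labels Binary label per pair.
#' @param outer_k,inner_k Fold counts (default 4 and 4).
#' @param seed Integer seed for tie-breaking.
#' @return `data.table` with column `outer` (1..outer_k) and one column
#'   `inner<f>` per outer fold `f`, holding the pair's inner fold id
#'   (1..inner_k) within outer training split `f`, or `NA` for pairs that
#'   belong to outer fold `f` itself.
#' @export
nested_group_kfold <- function(groups, labels, outer_k = 4L, inner_k = 4L,
                               seed = 1L) {
  stopifnot(length(groups) == length(labels))
  if (length(unique(groups)) < outer_k)
    stop("fewer groups than outer folds")
  outer <- greedy_group_folds(groups, labels, outer_k, seed)
  plan <- data.table::data.table(outer = outer)
  for (f in seq_len(outer_k)) {
    tr <- which(outer != f)
    if (length(unique(groups[tr])) < inner_k)
      stop("fewer groups than inner folds in outer training split ", f)
    inner_f <- rep(NA_integer_, length(groups))
    inner_f[tr] <- greedy_group_folds(groups[tr], labels[tr], inner_k,
                                      seed + f)
    plan[, (paste0("inner", f)) := inner_f]
  }
  pos_per_fold <- tapply(labels, outer, sum)
  if (any(pos_per_fold == sum(labels)))
    warning("all positives fell into a single outer fold; ",
            "stratification is degenerate")
  plan[]
}

# greedy balanced bin-packing of whole groups into k folds
greedy_group_folds <- function(groups, labels, k, seed) {
  gstat <- data.table::data.table(group = groups, label = labels)
  gstat <- gstat[, .(pos = sum(label), n = .N), by = group]
  set.seed(seed)
  gstat <- gstat[sample.int(nrow(gstat))]          # seeded tie shuffle
  data.table::setorderv(gstat, c("pos", "n"), order = -1L)
  fold_pos <- numeric(k)
  fold_n <- numeric(k)
  fold_of <- integer(nrow(gstat))
  for (i in seq_len(nrow(gstat))) {
    if (gstat$pos[i] > 0) {
      cand <- which(fold_pos == min(fold_pos))
      if (length(cand) > 1L) cand <- cand[which.min(fold_n[cand])]
    } else {
      # a group without positives cannot help stratification: balance sizes
      cand <- which(fold_n == min(fold_n))
    }
    f <- cand[1]
    fold_of[i] <- f
    fold_pos[f] <- fold_pos[f] + gstat$pos[i]
    fold_n[f] <- fold_n[f] + gstat$n[i]
  }
  map <- stats::setNames(fold_of, gstat$group)
  unname(map[as.character(groups)])
}
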