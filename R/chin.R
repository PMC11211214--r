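# Promoter-centric Chromatin Interaction Networks (ChINs): nodes are
# elements, edges are significance-filtered Hi-C contacts, and every EP pair
# is labeled by its enhancer-mediated graph distance from the promoter
# (e0, e1, e2, e3, einf).

#' Select significant contact edges
#'
#' External mode (a loop-significance table is supplied) keeps bin pairs with
#' `q < q_threshold`. Builtin fallback mode bins pairs by genomic distance on
#' a log scale and keeps the top `keep_fraction` of contact values within
#' each distance bin — a crude distance-stratified stand-in that lets the
#' pipeline run self-contained when no external loop caller output is
#' available (flagged via the `mode` attribute).
#'
#' @param contacts A [contact_map()].
#' @param sig_table Optional `data.table` from [read_loops()] with columns
#'   `chrom`, `bin_i`, `bin_j`, `q`.
#' @param q_threshold Loop q-value threshold in (0, 1].
#' @param keep_fraction Builtin mode: fraction of pairs kept per distance
#'   bin.
#' @param n_distance_bins Builtin mode: number of log-spaced distance bins.
#' @return `data.table` of significant edges (`chrom`, `bin_i`, `bin_j`,
#'   `contact`) with attribute `mode` set to `"external"` or `"builtin"`.
#' @export
call_significant_edges <- function(contacts, sig_table = NULL,
                                   q_threshold = 0.05, keep_fraction = 0.1,
                                   n_distance_bins = 8L) {
  if (q_threshold <= 0 || q_threshold > 1)
    stop("q_threshold must be in (0, 1]")
  e <- contacts$entries
  if (nrow(e) == 0L) {
    out <- e[0]
    data.table::setattr(out, "mode",
                        if (is.null(sig_table)) "builtin" else "external")
    return(out)
  }
  if (!is.null(sig_table)) {
    sig <- sig_table[q < q_threshold, .(chrom, bin_i, bin_j)]
    out <- e[sig, on = c("chrom", "bin_i", "bin_j"), nomatch = NULL]
    data.table::setattr(out, "mode", "external")
    return(out[])
  }
  d <- (e$bin_j - e$bin_i) * contacts$bin_size
  d <- pmax(d, contacts$bin_size)
  breaks <- exp(seq(log(min(d)), log(max(d)), length.out = n_distance_bins + 1L))
  breaks[1] <- breaks[1] - 1; breaks[length(breaks)] <- breaks[length(breaks)] + 1
  bin_idx <- cut(d, breaks, labels = FALSE)
  keep <- logical(nrow(e))
  for (b in unique(bin_idx)) {
    rows <- which(bin_idx == b)
    k <- floor(keep_fraction * length(rows))
    if (k > 0L)
      keep[rows[order(-e$contact[rows])[seq_len(k)]]] <- TRUE
  }
  out <- e[keep]
  data.table::setattr(out, "mode", "builtin")
  out[]
}

#' Map bin-level edges to element-level edges
#'
#' An edge is created between every pair of elements whose midpoint bins
#' match a significant bin pair on the same chromosome; the edge weight is
#' the contact value.
#'
#' @param edges Significant bin-pair edges from [call_significant_edges()].
#' @param elements Element table.
#' @param bin_size Bin width in bp (must match the contact map).
#' @return `data.table` with columns `id1`, `id2`, `weight`.
#' @export
edges_to_element_pairs <- function(edges, elements, bin_size) {
  el <- data.table::data.table(chrom = elements$chrom,
                               element_id = elements$element_id,
                               bin = element_bin(elements, bin_size))
  a <- merge(edges, el, by.x = c("chrom", "bin_i"), by.y = c("chrom", "bin"),
             allow.cartesian = TRUE)
  b <- merge(a, el, by.x = c("chrom", "bin_j"), by.y = c("chrom", "bin"),
             allow.cartesian = TRUE, suffixes = c("_1", "_2"))
  out <- data.table::data.table(id1 = b$element_id_1, id2 = b$element_id_2,
                                weight = b$contact)
  out[id1 != id2]
}

#' Build the ChIN of one promoter
#'
#' Restricts the element-level edge set to the focal promoter and the tested
#' enhancers; edges touching any other element are dropped. Tested enhancers
#' with no surviving edge remain as isolated nodes.
#'
#' @param edges Element-level edges (`id1`, `id2`, `weight`), e.g. from
#'   [edges_to_element_pairs()].
#' @param elements Element table (supplies node kinds).
#' @param promoter_id Element id of the focal promoter.
#' @param tested_enhancer_ids Ids of enhancers tested in the screen.
#' @return An object of class `chin` with `promoter`, `nodes`
#'   (`element_id`, `kind`) and `edges` (`id1`, `id2`, `weight`).
#' @export
build_chin <- function(edges, elements, promoter_id, tested_enhancer_ids) {
  if (!promoter_id %in% elements$element_id)
    stop("unknown promoter_id: ", promoter_id)
  keep_ids <- unique(c(promoter_id, tested_enhancer_ids))
  nodes <- data.table::data.table(
    element_id = keep_ids,
    kind = elements$kind[match(keep_ids, elements$element_id)])
  if (anyNA(nodes$kind))
    stop("tested enhancer id(s) absent from element table")
  e <- edges[edges$id1 %in% keep_ids & edges$id2 %in% keep_ids, ]
  e <- unique(data.table::data.table(
    id1 = pmin(e$id1, e$id2), id2 = pmax(e$id1, e$id2), weight = e$weight))
  if (nrow(e)) {
    e <- e[, .(weight = max(weight)), by = .(id1, id2)]
    if (any(e$weight <= 0)) stop("edge weights must be positive")
  }
  structure(list(promoter = promoter_id, nodes = nodes, edges = e[]),
            class = "chin")
}

#' @export
print.chin <- function(x, ...) {
  cat(sprintf("chin: promoter %s, %d nodes, %d edges\n",
              x$promoter, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Graph-distance class of enhancers in a ChIN
#'
#' An enhancer sharing the promoter's contact bin is `e0` (the bin test
#' precedes the graph test). Otherwise the class follows the shortest path
#' from the promoter in the subgraph whose intermediate nodes are all
#' enhancers (other promoters never mediate): path length 1 is `e1`, 2 is
#' `e2`, 3 is `e3`, and longer or unreachable is `einf`.
#'
#' @param chin A [build_chin()] object.
#' @param enhancer_id Character vector of enhancer ids to classify.
#' @param enhancer_bin,promoter_bin Contact-map bin of each enhancer and of
#'   the promoter (for the `e0` test); `promoter_bin` is recycled.
#' @return Character vector in `{"e0","e1","e2","e3","einf"}`.
#' @export
label_ep_distance <- function(chin, enhancer_id, enhancer_bin, promoter_bin) {
  known <- chin$nodes$element_id
  if (!all(enhancer_id %in% known))
    stop("enhancer id(s) absent from the ChIN node universe: ",
         paste(utils::head(setdiff(enhancer_id, known), 5L), collapse = ", "))
  promoter_bin <- rep_len(promoter_bin, length(enhancer_id))
  # subgraph: promoter + enhancer-kind nodes only
  keep <- chin$nodes$element_id[chin$nodes$kind == "enhancer" |
                                  chin$nodes$element_id == chin$promoter]
  e <- chin$edges[chin$edges$id1 %in% keep & chin$edges$id2 %in% keep, ]
  g <- igraph::graph_from_data_frame(
    e[, c("id1", "id2")], directed = FALSE,
    vertices = data.frame(name = keep))
  dist_row <- igraph::distances(g, v = chin$promoter, weights = NA)[1, ]
  out <- character(length(enhancer_id))
  for (i in seq_along(enhancer_id)) {
    if (enhancer_bin[i] == promoter_bin[i]) {
      out[i] <- "e0"
    } else {
      d <- if (enhancer_id[i] %in% names(dist_row))
        dist_row[[enhancer_id[i]]] else Inf
      out[i] <- if (d == 1) "e1" else if (d == 2) "e2" else if (d == 3) "e3"
      else "einf"
    }
  }
  out
}

#' Classify every candidate EP pair by ChIN distance
#'
#' Builds one ChIN per promoter (restricted to that promoter's candidate
#' enhancers, which are the tested set) and labels each pair.
#'
#' @param ep Candidate table with `enh_bin` and `tss_bin` columns (see
#'   [ep_attach_contact()]).
#' @param elements Element table.
#' @param edges Element-level significant edges.
#' @return Character vector of class labels aligned to `ep` rows.
#' @export
classify_ep_pairs <- function(ep, elements, edges) {
  stopifnot(all(c("enh_bin", "tss_bin") %in% names(ep)))
  out <- character(nrow(ep))
  for (p in unique(ep$tss_id)) {
    rows <- which(ep$tss_id == p)
    ch <- build_chin(edges, elements, p, unique(ep$enhancer_id[rows]))
    out[rows] <- label_ep_distance(ch, ep$enhancer_id[rows],
                                   ep$enh_bin[rows], ep$tss_bin[rows])
  }
  out
}

#' Partition pairs into direct and indirect contact classes
#'
#' `e1minus` comprises the direct-contact classes `e0` and `e1`; `e2plus`
#' comprises the indirect classes `e2`, `e3` and `einf`. The partition is
#' disjoint and exhaustive.
#'
#' @param labels Character vector of ChIN class labels.
#' @return Factor with levels `e1minus`, `e2plus`.
#' @export
partition_by_class <- function(labels) {
  stopifnot(all(labels %in% c("e0", "e1", "e2", "e3", "einf")))
  factor(ifelse(labels %in% c("e0", "e1"), "e1minus", "e2plus"),
         levels = c("e1minus", "e2plus"))
}
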