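# In-code fixtures and independent brute-force oracles shared across tests.

# small element table builder; positions are midpoints for 1-bp tss,
# enhancers get width 200 centred on the position
make_elements <- function(chrom, pos, kind, ids = NULL, ...) {
  n <- length(pos)
  if (is.null(ids)) {
    within_kind <- stats::ave(seq_len(n), kind, FUN = seq_along)
    ids <- sprintf("%s%02d", ifelse(kind == "enhancer", "e", "p"),
                   within_kind)
  }
  start <- ifelse(kind == "tss", pos, pos - 100L)
  end <- ifelse(kind == "tss", pos + 1L, pos + 100L)
  dt <- data.table::data.table(chrom = chrom, start = as.integer(start),
                               end = as.integer(end), element_id = ids,
                               kind = kind)
  extra <- list(...)
  for (nm in names(extra)) dt[[nm]] <- extra[[nm]]
  dt
}

# contact map from explicit element-pair contacts (uses midpoints and the
# given bin size); vals named by "id1|id2"
make_contacts <- function(elements, pairs, bin_size = 5000L) {
  mid <- setNames(eplearn::element_midpoint(elements), elements$element_id)
  ch <- setNames(elements$chrom, elements$element_id)
  entries <- data.table::data.table(
    chrom = ch[pairs$id1],
    bin_i = as.integer(mid[pairs$id1] %/% bin_size),
    bin_j = as.integer(mid[pairs$id2] %/% bin_size),
    contact = pairs$contact)
  eplearn::contact_map(entries, bin_size)
}

# ---- naive all-pairs feature oracle (explicit loops, no grouping tricks) ----

oracle_features <- function(elements, contacts, window_bp) {
  half <- window_bp / 2
  mid <- setNames(eplearn::element_midpoint(elements), elements$element_id)
  ch <- setNames(elements$chrom, elements$element_id)
  enh <- elements$element_id[elements$kind == "enhancer"]
  tss <- elements$element_id[elements$kind == "tss"]
  bs <- contacts$bin_size
  cval <- function(a, b) {
    eplearn::contact_lookup(contacts, ch[[a]],
                            mid[[a]] %/% bs, mid[[b]] %/% bs)
  }
  rows <- list()
  for (p in tss) for (e in enh) {
    if (ch[[e]] != ch[[p]]) next
    d <- abs(mid[[e]] - mid[[p]])
    if (d > half) next
    rows[[length(rows) + 1L]] <- data.frame(
      enhancer_id = e, tss_id = p, distance = d, contact = cval(e, p),
      stringsAsFactors = FALSE)
  }
  ep <- do.call(rbind, rows)
  n <- nrow(ep)
  out <- ep
  out$max.contact.to.TSS <- out$diff.from.max.contact.to.TSS <- NA_real_
  out$rank.contact.to.TSS <- NA_real_
  out$max.contact.from.enhancer <- NA_real_
  out$diff.from.max.contact.from.enhancer <- out$rank.contact.from.enhancer <- NA_real_
  out$remaining.TSS.contact.from.enhancer <- NA_real_
  out$remaining.enhancers.contact.to.TSS <- NA_real_
  out$Enhancer.count.near.TSS <- out$TSS.count.near.enhancer <- NA_integer_
  for (i in seq_len(n)) {
    e <- ep$enhancer_id[i]; p <- ep$tss_id[i]
    nb_tss <- ep$contact[ep$tss_id == p]          # enhancers near this TSS
    nb_enh <- ep$contact[ep$enhancer_id == e]     # TSSs near this enhancer
    out$max.contact.to.TSS[i] <- max(nb_tss)
    out$diff.from.max.contact.to.TSS[i] <- max(nb_tss) - ep$contact[i]
    out$rank.contact.to.TSS[i] <-
      match(ep$contact[i], sort(unique(nb_tss), decreasing = TRUE))
    out$max.contact.from.enhancer[i] <- max(nb_enh)
    out$diff.from.max.contact.from.enhancer[i] <- max(nb_enh) - ep$contact[i]
    out$rank.contact.from.enhancer[i] <-
      match(ep$contact[i], sort(unique(nb_enh), decreasing = TRUE))
    out$remaining.TSS.contact.from.enhancer[i] <- sum(nb_enh) - ep$contact[i]
    out$remaining.enhancers.contact.to.TSS[i] <- sum(nb_tss) - ep$contact[i]
    out$Enhancer.count.near.TSS[i] <-
      sum(vapply(enh, function(x) ch[[x]] == ch[[p]] &&
                   abs(mid[[x]] - mid[[p]]) <= half, logical(1)))
    out$TSS.count.near.enhancer[i] <-
      sum(vapply(tss, function(x) ch[[x]] == ch[[e]] &&
                   abs(mid[[x]] - mid[[e]]) <= half, logical(1)))
  }
  out[order(out$tss_id, out$enhancer_id), ]
}

oracle_abc <- function(ep, activity) {
  s <- numeric(nrow(ep))
  for (i in seq_len(nrow(ep))) {
    num <- activity[[ep$enhancer_id[i]]] * ep$contact[i]
    den <- 0
    for (j in which(ep$tss_id == ep$tss_id[i]))
      den <- den + activity[[ep$enhancer_id[j]]] * ep$contact[j]
    s[i] <- if (den > 0) num / den else 0
  }
  s
}

# ---- exhaustive enhancer-intermediate path oracle (graphs <= 12 nodes) ------

# edges: data.frame(id1, id2); kinds named by element id; returns shortest
# path length from promoter to target where all intermediates are enhancers,
# or Inf
oracle_chin_distance <- function(edges, kinds, promoter, target) {
  adj <- list()
  add <- function(a, b) adj[[a]] <<- union(adj[[a]], b)
  for (i in seq_len(nrow(edges))) {
    add(edges$id1[i], edges$id2[i]); add(edges$id2[i], edges$id1[i])
  }
  best <- Inf
  recurse <- function(node, visited, len) {
    if (len >= best) return()
    for (nb in adj[[node]]) {
      if (nb == target) { best <<- min(best, len + 1L); next }
      if (nb %in% visited) next
      if (kinds[[nb]] != "enhancer") next   # only enhancers mediate
      recurse(nb, c(visited, nb), len + 1L)
    }
  }
  if (is.null(adj[[promoter]])) return(Inf)
  recurse(promoter, promoter, 0L)
  best
}

oracle_chin_label <- function(edges, kinds, promoter, target,
                              same_bin = FALSE) {
  if (same_bin) return("e0")
  d <- oracle_chin_distance(edges, kinds, promoter, target)
  if (d == 1) "e1" else if (d == 2) "e2" else if (d == 3) "e3" else "einf"
}

# ---- brute-force metric oracles ---------------------------------------------

oracle_average_precision <- function(scores, labels) {
  ord <- order(-scores)
  l <- labels[ord]
  precisions <- c()
  for (r in seq_along(l)) {
    if (l[r] == 1) precisions <- c(precisions, sum(l[1:r]) / r)
  }
  mean(precisions)
}

oracle_threshold_at_recall <- function(scores, labels, target) {
  cands <- sort(unique(scores), decreasing = TRUE)
  feasible <- cands[vapply(cands, function(t)
    sum(labels == 1 & scores >= t) / sum(labels == 1) >= target, logical(1))]
  max(feasible)
}
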