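# Candidate EP enumeration and the feature families: ABC score, focal-vs-
# neighborhood relative contact, remaining-contact sums, element density,
# TF presence, and labeling from perturbation results.
#
# "Near" / "neighborhood" always means the same half-window (window_bp / 2,
# center-to-center) used for candidate pairing; there is one window knob.

#' Enumerate candidate enhancer-promoter pairs
#'
#' Pairs every enhancer with every TSS on the same chromosome whose
#' center-to-center distance is at most `window_bp / 2` (closed boundary).
#' The distance column is `|enhancer midpoint - TSS position|` in bp.
#'
#' @param elements Element table containing at least one TSS.
#' @param window_bp Total window span in bp (default 5 Mb, i.e. half-window
#'   2.5 Mb).
#' @return `data.table` with columns `enhancer_id`, `tss_id`, `gene_id` (if
#'   present on the TSS rows), `chrom`, `distance`, `enh_mid`, `tss_pos`.
#' @export
ep_candidates <- function(elements, window_bp = 5e6) {
  stopifnot(window_bp > 0)
  enh <- elements[elements$kind == "enhancer", ]
  tss <- elements[elements$kind == "tss", ]
  if (nrow(tss) == 0L) stop("element table contains no TSS")
  half <- window_bp / 2
  e <- data.table::data.table(chrom = enh$chrom, enhancer_id = enh$element_id,
                              enh_mid = element_midpoint(enh))
  t <- data.table::data.table(chrom = tss$chrom, tss_id = tss$element_id,
                              tss_pos = element_midpoint(tss))
  if ("gene_id" %in% names(tss)) t$gene_id <- tss$gene_id
  ep <- merge(e, t, by = "chrom", allow.cartesian = TRUE)
  ep[, distance := abs(enh_mid - tss_pos)]
  ep <- ep[distance <= half]
  data.table::setorderv(ep, c("chrom", "tss_id", "enhancer_id"))
  cols <- intersect(c("enhancer_id", "tss_id", "gene_id", "chrom",
                      "distance", "enh_mid", "tss_pos"), names(ep))
  ep[, cols, with = FALSE]
}

#' Attach the focal Hi-C contact value to each candidate pair
#'
#' Looks up the contact between the bins containing the enhancer midpoint and
#' the TSS; adds columns `enh_bin`, `tss_bin` and `contact`.
#'
#' @param ep Candidate table from [ep_candidates()].
#' @param contacts A [contact_map()].
#' @return The table with contact columns added (copy).
#' @export
ep_attach_contact <- function(ep, contacts) {
  out <- data.table::copy(ep)
  bs <- contacts$bin_size
  out[, enh_bin := as.integer(enh_mid %/% bs)]
  out[, tss_bin := as.integer(tss_pos %/% bs)]
  out[, contact := contact_lookup(contacts, chrom, enh_bin, tss_bin)]
  out[]
}

#' Activity-by-contact (ABC) score
#'
#' For each pair, activity times contact normalized by the sum of
#' activity x contact over all candidate enhancers of the same TSS:
#' `score(e,p) = A_e C_ep / sum_{e'} A_{e'} C_{e'p}`. A zero denominator
#' yields 0 for all of that TSS's pairs.
#'
#' @param ep Candidate table with a `contact` column (see
#'   [ep_attach_contact()]).
#' @param elements Element table carrying the enhancer activity signal.
#' @param activity_col Name of the enhancer activity column (default
#'   `normalized_H3K27ac_e`).
#' @return Numeric vector of scores aligned to `ep` rows.
#' @export
abc_score <- function(ep, elements, activity_col = "normalized_H3K27ac_e") {
  stopifnot("contact" %in% names(ep))
  act <- stats::setNames(elements[[activity_col]], elements$element_id)
  a <- act[ep$enhancer_id]
  if (any(is.na(a))) stop("missing activity for some enhancers")
  if (any(a < 0)) stop("negative enhancer activity")
  num <- unname(a * ep$contact)
  den <- stats::ave(num, ep$tss_id, FUN = sum)
  ifelse(den > 0, num / den, 0)
}

#' Relative-contact features
#'
#' For each pair, compares the focal contact with the contacts of its two
#' neighborhoods: all candidate enhancers of the focal TSS, and all candidate
#' TSSs of the focal enhancer. Emits, per side, the neighborhood maximum, the
#' difference from that maximum (0 when the focal contact is the strongest),
#' and the dense rank of the focal contact (rank 1 = strongest; ties share
#' the better rank).
#'
#' @param ep Candidate table with a `contact` column.
#' @return `data.table` of columns `max.contact.to.TSS`,
#'   `diff.from.max.contact.to.TSS`, `rank.contact.to.TSS`,
#'   `max.contact.from.enhancer`, `diff.from.max.contact.from.enhancer`,
#'   `rank.contact.from.enhancer`, aligned to `ep` rows.
#' @export
contact_relative_features <- function(ep) {
  stopifnot("contact" %in% names(ep))
  dense_rank_desc <- function(x) {
    u <- sort(unique(x), decreasing = TRUE)
    match(x, u)
  }
  out <- data.table::data.table(
    max.contact.to.TSS = stats::ave(ep$contact, ep$tss_id, FUN = max),
    rank.contact.to.TSS = as.numeric(
      stats::ave(ep$contact, ep$tss_id, FUN = dense_rank_desc)),
    max.contact.from.enhancer = stats::ave(ep$contact, ep$enhancer_id, FUN = max),
    rank.contact.from.enhancer = as.numeric(
      stats::ave(ep$contact, ep$enhancer_id, FUN = dense_rank_desc)))
  out[, diff.from.max.contact.to.TSS := max.contact.to.TSS - ep$contact]
  out[, diff.from.max.contact.from.enhancer :=
          max.contact.from.enhancer - ep$contact]
  data.table::setcolorder(out, c(
    "max.contact.to.TSS", "diff.from.max.contact.to.TSS",
    "rank.contact.to.TSS", "max.contact.from.enhancer",
    "diff.from.max.contact.from.enhancer", "rank.contact.from.enhancer"))
  out[]
}

#' Remaining-contact sums
#'
#' `remaining.TSS.contact.from.enhancer` is the sum of contacts between the
#' focal enhancer and all other candidate TSSs in its window;
#' `remaining.enhancers.contact.to.TSS` is the sum of contacts between the
#' focal TSS and all other candidate enhancers in its window.
#'
#' @param ep Candidate table with a `contact` column.
#' @return Two-column `data.table` aligned to `ep` rows.
#' @export
remaining_contact_sums <- function(ep) {
  stopifnot("contact" %in% names(ep))
  data.table::data.table(
    remaining.TSS.contact.from.enhancer =
      stats::ave(ep$contact, ep$enhancer_id, FUN = sum) - ep$contact,
    remaining.enhancers.contact.to.TSS =
      stats::ave(ep$contact, ep$tss_id, FUN = sum) - ep$contact)
}

#' Element-density counts
#'
#' `Enhancer.count.near.TSS` counts enhancers whose midpoint lies within the
#' half-window of the focal TSS; `TSS.count.near.enhancer` counts TSSs within
#' the half-window of the focal enhancer. The focal partner is included (the
#' counts are region totals), so both counts are at least 1 on candidate
#' rows.
#'
#' @param ep Candidate table.
#' @param elements Element table.
#' @param window_bp Window span in bp (half-window `window_bp/2`).
#' @return Two-column `data.table` aligned to `ep` rows.
#' @export
density_counts <- function(ep, elements, window_bp = 5e6) {
  half <- window_bp / 2
  count_near <- function(center_pos, center_chrom, targets) {
    tmid <- element_midpoint(targets)
    vapply(seq_along(center_pos), function(i) {
      sum(targets$chrom == center_chrom[i] & abs(tmid - center_pos[i]) <= half)
    }, integer(1))
  }
  enh <- elements[elements$kind == "enhancer", ]
  tss <- elements[elements$kind == "tss", ]
  # counts depend only on the focal element: compute per unique element
  ut <- unique(ep[, .(tss_id, chrom, tss_pos)])
  ut[, Enhancer.count.near.TSS := count_near(tss_pos, chrom, enh), by = seq_len(nrow(ut))]
  ue <- unique(ep[, .(enhancer_id, chrom, enh_mid)])
  ue[, TSS.count.near.enhancer := count_near(enh_mid, chrom, tss), by = seq_len(nrow(ue))]
  data.table::data.table(
    Enhancer.count.near.TSS =
      ut$Enhancer.count.near.TSS[match(ep$tss_id, ut$tss_id)],
    TSS.count.near.enhancer =
      ue$TSS.count.near.enhancer[match(ep$enhancer_id, ue$enhancer_id)])
}

#' TF presence at the enhancer and at the TSS
#'
#' For every TF peak set, emits `<TF>_e = 1` iff any peak interval overlaps
#' the enhancer interval (half-open intervals; abutting intervals do not
#' overlap), and `<TF>_TSS = 1` iff any peak overlaps the TSS position
#' extended by `tss_flank_bp` on each side.
#'
#' @param ep Candidate table.
#' @param elements Element table (supplies intervals).
#' @param peaks Named list of peak tables from [read_peaks()].
#' @param tss_flank_bp Promoter-side flank in bp (default 500).
#' @return Binary `data.table` with two columns per TF, aligned to `ep` rows.
#' @export
tf_presence <- function(ep, elements, peaks, tss_flank_bp = 500L) {
  if (anyDuplicated(names(peaks)))
    stop("duplicate TF names in peak list")
  # half-open BED [start, end) -> 1-based closed IRanges [start+1, end]
  enh_rows <- match(ep$enhancer_id, elements$element_id)
  tss_rows <- match(ep$tss_id, elements$element_id)
  enh_gr <- GenomicRanges::GRanges(
    elements$chrom[enh_rows],
    IRanges::IRanges(elements$start[enh_rows] + 1L, elements$end[enh_rows]))
  tss_pos <- element_midpoint(elements)[tss_rows]
  tss_gr <- GenomicRanges::GRanges(
    elements$chrom[tss_rows],
    IRanges::IRanges(pmax(1L, tss_pos + 1L - tss_flank_bp),
                     tss_pos + 1L + tss_flank_bp))
  out <- data.table::data.table(.row = seq_len(nrow(ep)))
  for (tf in names(peaks)) {
    pk <- peaks[[tf]]
    if (nrow(pk) == 0L) {
      out[, paste0(tf, "_e") := 0L]
      out[, paste0(tf, "_TSS") := 0L]
      next
    }
    pk_gr <- GenomicRanges::GRanges(
      pk$chrom, IRanges::IRanges(pk$start + 1L, pk$end))
    out[, paste0(tf, "_e") :=
            as.integer(IRanges::overlapsAny(enh_gr, pk_gr))]
    out[, paste0(tf, "_TSS") :=
            as.integer(IRanges::overlapsAny(tss_gr, pk_gr))]
  }
  out[, .row := NULL]
  out[]
}

#' TF presence columns from a precomputed element-by-TF matrix
#'
#' Broadcasts a binary element-level presence matrix (rownames = element ids)
#' to EP rows, producing the same `<TF>_e` / `<TF>_TSS` columns as
#' [tf_presence()].
#'
#' @param ep Candidate table.
#' @param tf_matrix Binary matrix, elements x TFs, with rownames and
#'   colnames.
#' @return Binary `data.table` aligned to `ep` rows.
#' @export
tf_presence_from_matrix <- function(ep, tf_matrix) {
  stopifnot(!is.null(rownames(tf_matrix)), !is.null(colnames(tf_matrix)))
  e <- tf_matrix[ep$enhancer_id, , drop = FALSE]
  t <- tf_matrix[ep$tss_id, , drop = FALSE]
  colnames(e) <- paste0(colnames(tf_matrix), "_e")
  colnames(t) <- paste0(colnames(tf_matrix), "_TSS")
  out <- data.table::as.data.table(cbind(e, t))
  out[]
}

#' Label positives from perturbation results
#'
#' A pair is positive iff its adjusted p-value is below `alpha_label` *and*
#' the perturbation effect direction is `down` (significant up-regulation is
#' not a positive). Rows with missing adjusted p carry no label and are
#' dropped from the labeled set.
#'
#' @param ep EP table with `adj_p` and `effect_direction` columns.
#' @param alpha_label Significance threshold in (0,1), default 0.1.
#' @return The subset of labeled rows with an integer `label` column added.
#' @export
label_positives <- function(ep, alpha_label = 0.1) {
  if (alpha_label <= 0 || alpha_label >= 1)
    stop("alpha_label must be in (0,1)")
  stopifnot(all(c("adj_p", "effect_direction") %in% names(ep)))
  out <- ep[!is.na(ep$adj_p), ]
  out$label <- as.integer(out$adj_p < alpha_label &
                            out$effect_direction == "down")
  out
}

#' Attach element-level activity signals to EP rows
#'
#' Copies the enhancer-side signals (suffix `_e` columns) and TSS-side
#' signals onto each pair row by element id.
#'
#' @param ep Candidate table.
#' @param elements Element table with signal columns.
#' @param enh_signals,tss_signals Character vectors of signal column names to
#'   take from enhancer rows and TSS rows respectively.
#' @return `data.table` of signal columns aligned to `ep` rows.
#' @export
ep_signal_columns <- function(ep, elements,
                              enh_signals = c("normalized_H3K27ac_e",
                                              "H3K4me3_e", "H3K27me3_e"),
                              tss_signals = c("H3K27ac.RPKM.quantile_TSS",
                                              "H3K4me3_TSS", "H3K27me3_TSS",
                                              "TargetGeneExpression")) {
  enh_rows <- match(ep$enhancer_id, elements$element_id)
  tss_rows <- match(ep$tss_id, elements$element_id)
  out <- data.table::data.table(.row = seq_len(nrow(ep)))
  for (s in intersect(enh_signals, names(elements)))
    out[, (s) := elements[[s]][enh_rows]]
  for (s in intersect(tss_signals, names(elements)))
    out[, (s) := elements[[s]][tss_rows]]
  out[, .row := NULL]
  out[]
}

#' Assemble the feature matrix
#'
#' Binds the computed feature-family columns into a single matrix keyed by
#' `(enhancer_id, tss_id)`, records column provenance, and applies the
#' missing-value policy.
#'
#' @param ep Candidate table (keys plus `distance` and `contact` are taken
#'   from it).
#' @param ... Named feature-family `data.table`s (name = family label), each
#'   aligned to `ep` rows.
#' @param na_policy `"drop"` (default) removes rows with any missing value;
#'   `"zero"` imputes 0.
#' @return A `data.table` with key columns, `distance`, `contact`, and all
#'   family columns; attribute `provenance` maps column name to family.
#' @export
assemble_features <- function(ep, ..., na_policy = c("drop", "zero")) {
  na_policy <- match.arg(na_policy)
  fams <- list(...)
  stopifnot(length(fams) == 0L || !is.null(names(fams)))
  out <- data.table::data.table(enhancer_id = ep$enhancer_id,
                                tss_id = ep$tss_id)
  prov <- c()
  if ("distance" %in% names(ep)) {
    out[, distance := ep$distance]; prov["distance"] <- "distance"
  }
  if ("contact" %in% names(ep)) {
    out[, contact := ep$contact]; prov["contact"] <- "contact"
  }
  for (fam in names(fams)) {
    cols <- fams[[fam]]
    stopifnot(nrow(cols) == nrow(ep))
    clash <- intersect(names(cols), names(out))
    if (length(clash))
      stop("conflicting feature column name(s): ", paste(clash, collapse = ", "))
    out <- cbind(out, cols)
    prov[names(cols)] <- fam
  }
  featcols <- setdiff(names(out), c("enhancer_id", "tss_id"))
  if (na_policy == "drop") {
    keep <- stats::complete.cases(out)
    out <- out[keep]
  } else {
    for (cc in featcols) data.table::set(out, which(is.na(out[[cc]])), cc, 0)
  }
  if (anyDuplicated(out[, .(enhancer_id, tss_id)]))
    stop("duplicate (enhancer_id, tss_id) keys")
  data.table::setattr(out, "provenance", prov)
  out[]
}

#' Build the full feature table of a simulated dataset
#'
#' Convenience wrapper assembling every feature family — distance, focal
#' contact, ABC score, relative-contact, remaining-contact sums, density
#' counts, element signals, TF presence, and per-side NMF cluster scores —
#' for the output of [simulate_ep_dataset()].
#'
#' @param sim List from [simulate_ep_dataset()].
#' @param nmf_k Number of NMF clusters per side.
#' @param window_bp Candidate/neighborhood window span in bp.
#' @param nmf_seed Seed for the NMF fits.
#' @param nmf_restarts Random restarts per NMF fit.
#' @return List with `features` (assembled table aligned to `sim$ep` rows),
#'   `nmf_enh`, `nmf_tss`.
#' @export
featurize_ep_dataset <- function(sim, nmf_k = 5L, window_bp = 5e6,
                                 nmf_seed = 1L, nmf_restarts = 2L) {
  ep <- sim$ep
  enh_ids <- unique(ep$enhancer_id)
  tss_ids <- unique(ep$tss_id)
  nmf_enh <- nmf_fit(sim$tf_matrix[enh_ids, , drop = FALSE], k = nmf_k,
                     seed = nmf_seed, side = "enhancer",
                     n_restarts = nmf_restarts)
  nmf_tss <- nmf_fit(sim$tf_matrix[tss_ids, , drop = FALSE], k = nmf_k,
                     seed = nmf_seed, side = "tss",
                     n_restarts = nmf_restarts)
  features <- assemble_features(
    ep,
    abc = data.table::data.table(abc_score = abc_score(ep, sim$elements)),
    relative = contact_relative_features(ep),
    remaining = remaining_contact_sums(ep),
    density = density_counts(ep, sim$elements, window_bp),
    signals = ep_signal_columns(ep, sim$elements),
    tf = tf_presence_from_matrix(ep, sim$tf_matrix),
    nmf_enh = nmf_features(nmf_enh, ep),
    nmf_tss = nmf_features(nmf_tss, ep))
  stopifnot(nrow(features) == nrow(ep))   # simulated features are complete
  list(features = features, nmf_enh = nmf_enh, nmf_tss = nmf_tss)
}

#' Extract the numeric feature matrix from an assembled table
#'
#' @param features Table from [assemble_features()].
#' @return Numeric matrix (rows = pairs, columns = features).
#' @export
feature_matrix <- function(features) {
  cols <- setdiff(names(features), c("enhancer_id", "tss_id"))
  as.matrix(features[, cols, with = FALSE])
}
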