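# Synthetic genomes with the statistical structure of a genome-wide CRISPRi
# enhancer screen: clustered element placement, distance-decaying contact,
# block-structured TF co-binding, insensitive promoters, and planted labels
# at ~2% prevalence. Test scaffolding for the pipeline, not a model of any
# particular dataset.

#' Simulation configuration
#'
#' Defaults are sized so that candidate enumeration at the default 5-Mb
#' window yields on the order of 20,000 EP pairs at ~2% positive prevalence,
#' matching the extreme imbalance regime of genome-wide screens.
#'
#' @param n_chrom Number of simulated chromosomes (named `chr1`, `chr2`, ...).
#' @param chrom_length_bp Length of each chromosome in bp.
#' @param n_enhancers,n_tss Total element counts across all chromosomes.
#' @param density_heterogeneity Non-negative; 0 places elements uniformly,
#'   larger values concentrate elements into high-density neighborhoods
#'   (log-normal tile weights with this log-sd).
#' @param contact_decay_exponent Power-law exponent of contact distance decay
#'   (> 0).
#' @param contact_noise_sd Log-normal multiplicative noise sd on contacts.
#' @param contact_scale_bp Reference distance at which the expected contact
#'   equals `contact_at_ref`.
#' @param contact_at_ref Expected contact at the reference distance.
#' @param window_bp Window beyond which contacts are zero (matches the
#'   candidate window).
#' @param n_tf Number of transcription factors.
#' @param n_tf_clusters Number of latent TF co-binding clusters.
#' @param tf_within_p,tf_background_p Presence probability of a TF at an
#'   element whose active cluster set does / does not include the TF's
#'   cluster.
#' @param insensitive_fraction Fraction of promoters flagged insensitive to
#'   enhancer perturbation (their active promoter marks are elevated).
#' @param target_prevalence Target positive fraction among candidate pairs.
#' @param effect_coefficients Named coefficients of the label logit:
#'   `contact`, `activity`, `distance`, `promoter_insensitivity` (negative),
#'   `tf_cluster`.
#' @param na_fraction Fraction of pairs whose perturbation result is missing
#'   (adjusted p encoded `NA`).
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 16L,
                       chrom_length_bp = 15e6,
                       n_enhancers = 1920L,
                       n_tss = 576L,
                       density_heterogeneity = 1,
                       contact_decay_exponent = 1,
                       contact_noise_sd = 0.5,
                       contact_scale_bp = 5000,
                       contact_at_ref = 0.02,
                       window_bp = 5e6,
                       n_tf = 30L,
                       n_tf_clusters = 5L,
                       tf_within_p = 0.7,
                       tf_background_p = 0.05,
                       insensitive_fraction = 0.15,
                       target_prevalence = 0.02,
                       effect_coefficients = c(contact = 1.0,
                                               activity = 1.0,
                                               distance = 1.5,
                                               promoter_insensitivity = -3.0,
                                               tf_cluster = 2.0),
                       na_fraction = 0.05,
                       seed = 1L) {
  cfg <- list(n_chrom = as.integer(n_chrom),
              chrom_length_bp = chrom_length_bp,
              n_enhancers = as.integer(n_enhancers),
              n_tss = as.integer(n_tss),
              density_heterogeneity = density_heterogeneity,
              contact_decay_exponent = contact_decay_exponent,
              contact_noise_sd = contact_noise_sd,
              contact_scale_bp = contact_scale_bp,
              contact_at_ref = contact_at_ref,
              window_bp = window_bp,
              n_tf = as.integer(n_tf),
              n_tf_clusters = as.integer(n_tf_clusters),
              tf_within_p = tf_within_p,
              tf_background_p = tf_background_p,
              insensitive_fraction = insensitive_fraction,
              target_prevalence = target_prevalence,
              effect_coefficients = effect_coefficients,
              na_fraction = na_fraction,
              seed = as.integer(seed))
  stopifnot(cfg$target_prevalence > 0, cfg$target_prevalence < 1,
            cfg$n_chrom > 0, cfg$n_tss > 0, cfg$n_enhancers >= 0,
            cfg$density_heterogeneity >= 0, cfg$contact_decay_exponent >= 0,
            cfg$n_tf >= cfg$n_tf_clusters)
  structure(cfg, class = "sim_config")
}

# element positions from an inhomogeneous point process: chromosome tiled
# into 250-kb tiles with iid log-normal weights; heterogeneity = log-sd.
sample_positions <- function(n, chrom_length_bp, heterogeneity,
                             tile_bp = 250e3) {
  n_tiles <- max(1L, as.integer(chrom_length_bp %/% tile_bp))
  w <- exp(heterogeneity * stats::rnorm(n_tiles))
  tiles <- sample.int(n_tiles, n, replace = TRUE, prob = w)
  pos <- (tiles - 1L) * tile_bp + floor(stats::runif(n) * tile_bp)
  sort(as.integer(pmin(pos, chrom_length_bp - 1001)))
}

#' Simulate regulatory elements
#'
#' Places enhancers and TSSs on `n_chrom` chromosomes by an inhomogeneous
#' point process (clustered for `density_heterogeneity > 0`), draws log-normal
#' activity signals, and flags a fraction of promoters as insensitive to
#' enhancer perturbation with elevated active promoter marks (H3K27ac,
#' H3K4me3 at the TSS).
#'
#' @param cfg A [sim_config()].
#' @return List with `elements` (an element table with signal and `gene_id`
#'   columns) and `truth` (per-promoter `insensitive` flags).
#' @export
simulate_elements <- function(cfg) {
  set.seed(cfg$seed)
  per_chrom_capacity <- cfg$chrom_length_bp / 2000
  if ((cfg$n_enhancers + cfg$n_tss) / cfg$n_chrom > per_chrom_capacity)
    stop("element count exceeds chromosome capacity")
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  n_e <- distribute_counts(cfg$n_enhancers, cfg$n_chrom)
  n_t <- distribute_counts(cfg$n_tss, cfg$n_chrom)
  rows <- list()
  for (i in seq_len(cfg$n_chrom)) {
    pe <- sample_positions(n_e[i], cfg$chrom_length_bp,
                           cfg$density_heterogeneity)
    width <- as.integer(200 + floor(stats::runif(n_e[i]) * 800))
    enh <- data.table::data.table(
      chrom = chroms[i], start = pe, end = pe + width,
      element_id = sprintf("e_%s_%04d", chroms[i], seq_len(n_e[i])),
      kind = "enhancer")
    pt <- sample_positions(n_t[i], cfg$chrom_length_bp,
                           cfg$density_heterogeneity)
    tss <- data.table::data.table(
      chrom = chroms[i], start = pt, end = pt + 1L,
      element_id = sprintf("p_%s_%04d", chroms[i], seq_len(n_t[i])),
      kind = "tss")
    rows[[i]] <- rbind(enh, tss)
  }
  el <- data.table::rbindlist(rows)
  data.table::setorderv(el, c("chrom", "start"))
  is_enh <- el$kind == "enhancer"
  n_enh <- sum(is_enh); n_tss <- sum(!is_enh)
  # enhancer-side signals
  el[, normalized_H3K27ac_e := NA_real_]
  el[, H3K4me3_e := NA_real_]
  el[, H3K27me3_e := NA_real_]
  el[is_enh, normalized_H3K27ac_e := stats::rlnorm(n_enh, 0, 0.5)]
  el[is_enh, H3K4me3_e := stats::rlnorm(n_enh, -1, 0.6)]
  el[is_enh, H3K27me3_e := stats::rlnorm(n_enh, -1.5, 0.6)]
  # promoter-side signals, insensitive promoters get elevated active marks
  insensitive <- stats::runif(n_tss) < cfg$insensitive_fraction
  boost <- ifelse(insensitive, 3, 1)
  el[, H3K27ac.RPKM.quantile_TSS := NA_real_]
  el[, H3K4me3_TSS := NA_real_]
  el[, H3K27me3_TSS := NA_real_]
  el[, TargetGeneExpression := NA_real_]
  el[!is_enh, H3K27ac.RPKM.quantile_TSS := stats::rlnorm(n_tss, 0, 0.5) * boost]
  el[!is_enh, H3K4me3_TSS := stats::rlnorm(n_tss, 0, 0.5) * boost]
  el[!is_enh, H3K27me3_TSS := stats::rlnorm(n_tss, -1.5, 0.6)]
  el[!is_enh, TargetGeneExpression := stats::rlnorm(n_tss, 1, 1)]
  el[, gene_id := ifelse(is_enh, NA_character_, sub("^p_", "g_", element_id))]
  truth <- list(insensitive = stats::setNames(insensitive,
                                              el$element_id[!is_enh]))
  list(elements = el[], truth = truth)
}

distribute_counts <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  base + c(rep(1L, extra), rep(0L, k - extra))
}

#' Simulate a distance-decaying contact map
#'
#' Expected contact between two bins at distance d is
#' `contact_at_ref * (d / contact_scale_bp)^(-decay)` with multiplicative
#' log-normal noise; entries exist for all bin pairs occupied by elements on
#' the same chromosome within `window_bp`, and the map is symmetric by
#' construction.
#'
#' @param elements Element table.
#' @param cfg A [sim_config()].
#' @param bin_size Bin width in bp.
#' @return A [contact_map()].
#' @export
simulate_contacts <- function(elements, cfg, bin_size = 5000L) {
  set.seed(cfg$seed + 1L)
  if (nrow(elements) == 0L) return(contact_map(NULL, bin_size))
  bins <- unique(data.table::data.table(
    chrom = elements$chrom,
    bin = element_bin(elements, bin_size)))
  out <- list()
  for (ch in unique(bins$chrom)) {
    b <- sort(bins$bin[bins$chrom == ch])
    pairs <- data.table::CJ(bin_i = b, bin_j = b)[bin_i < bin_j]
    pairs <- pairs[(bin_j - bin_i) * bin_size <= cfg$window_bp]
    if (nrow(pairs) == 0L) next
    d <- pmax((pairs$bin_j - pairs$bin_i) * bin_size, bin_size)
    mu <- cfg$contact_at_ref *
      (d / cfg$contact_scale_bp)^(-cfg$contact_decay_exponent)
    noise <- exp(stats::rnorm(nrow(pairs), 0, cfg$contact_noise_sd))
    out[[ch]] <- data.table::data.table(chrom = ch, bin_i = pairs$bin_i,
                                        bin_j = pairs$bin_j,
                                        contact = mu * noise)
  }
  contact_map(data.table::rbindlist(out), bin_size)
}

#' Simulate block-structured TF presence
#'
#' Plants `n_tf_clusters` co-binding clusters: each TF belongs to one
#' cluster; each element activates one (sometimes two) clusters, and a TF is
#' present with probability `tf_within_p` when its cluster is active at the
#' element, `tf_background_p` otherwise.
#'
#' @param elements Element table.
#' @param cfg A [sim_config()].
#' @return List with `tf_matrix` (binary elements x TFs matrix, dimnames
#'   set) and `truth` (`tf_cluster` per TF, `active_clusters` per element).
#' @export
simulate_tf_presence <- function(elements, cfg) {
  set.seed(cfg$seed + 2L)
  n_el <- nrow(elements)
  tf_names <- sprintf("TF%02d", seq_len(cfg$n_tf))
  tf_cluster <- rep(seq_len(cfg$n_tf_clusters), length.out = cfg$n_tf)
  tf_cluster <- sort(tf_cluster)
  names(tf_cluster) <- tf_names
  primary <- sample.int(cfg$n_tf_clusters, n_el, replace = TRUE)
  second <- sample.int(cfg$n_tf_clusters, n_el, replace = TRUE)
  has_second <- stats::runif(n_el) < 0.3
  p <- matrix(cfg$tf_background_p, n_el, cfg$n_tf)
  for (k in seq_len(cfg$n_tf_clusters)) {
    active <- primary == k | (has_second & second == k)
    p[active, tf_cluster == k] <- cfg$tf_within_p
  }
  m <- matrix(as.integer(stats::runif(n_el * cfg$n_tf) < p), n_el, cfg$n_tf,
              dimnames = list(elements$element_id, tf_names))
  list(tf_matrix = m,
       truth = list(tf_cluster = tf_cluster,
                    active_primary = stats::setNames(primary,
                                                     elements$element_id)))
}

#' Simulate perturbation labels for candidate pairs
#'
#' Plants a generative rule on pipeline-computable features plus one latent
#' flag: the true logit is
#' `a + b_contact*log1p(contact*1000) + b_activity*activity_e +
#'  b_distance*(-log10(distance)) + b_pi*insensitive + b_tf*cluster_score`,
#' where `cluster_score` is the fraction of cluster-1 TFs present at the
#' enhancer. The intercept `a` is calibrated by bisection so the mean
#' success probability equals `target_prevalence`; labels are Bernoulli
#' draws. Adjusted p-values and effect directions consistent with the
#' labeling rule are synthesized (positives: p < alpha with direction
#' `down`; a fraction of rows get missing p).
#'
#' @param ep Candidate table with `contact` attached.
#' @param elements Element table with signals.
#' @param tf Result of [simulate_tf_presence()].
#' @param truth_elements Truth list from [simulate_elements()].
#' @param cfg A [sim_config()].
#' @param alpha_label Significance threshold used when synthesizing adj_p.
#' @return List with `ep` (adds `adj_p`, `effect_direction`, `label`) and
#'   `truth` (`logit`, `prob`, intercept, causal feature map).
#' @export
simulate_labels <- function(ep, elements, tf, truth_elements, cfg,
                            alpha_label = 0.1) {
  set.seed(cfg$seed + 3L)
  beta <- cfg$effect_coefficients
  act <- stats::setNames(elements$normalized_H3K27ac_e, elements$element_id)
  activity_e <- act[ep$enhancer_id]
  insens <- as.numeric(truth_elements$insensitive[ep$tss_id])
  causal_cluster_tfs <- names(tf$truth$tf_cluster)[tf$truth$tf_cluster == 1L]
  cluster_score <- rowMeans(
    tf$tf_matrix[ep$enhancer_id, causal_cluster_tfs, drop = FALSE])
  parts <- beta[["contact"]] * log1p(ep$contact * 1000) +
    beta[["activity"]] * activity_e +
    beta[["distance"]] * (-log10(pmax(ep$distance, 1))) +
    beta[["promoter_insensitivity"]] * insens +
    beta[["tf_cluster"]] * cluster_score
  if (any(is.na(parts)))
    stop("missing values in planted logit components")
  if (any(beta != 0) && stats::var(parts) == 0)
    stop("unattainable prevalence calibration: features carry no signal ",
         "(all-zero features?)")
  intercept <- calibrate_intercept(parts, cfg$target_prevalence)
  prob <- stats::plogis(intercept + parts)
  label <- as.integer(stats::runif(nrow(ep)) < prob)
  out <- data.table::copy(ep)
  out[, label := label]
  out[, effect_direction := "none"]
  out[label == 1L, effect_direction := "down"]
  neg <- which(label == 0L)
  neg_dir <- sample(c("none", "down", "up"), length(neg), replace = TRUE,
                    prob = c(0.7, 0.2, 0.1))
  out[neg, effect_direction := neg_dir]
  adj_p <- numeric(nrow(out))
  adj_p[label == 1L] <- stats::runif(sum(label == 1L), 0, alpha_label)
  # negatives: uniform adj_p, except direction "down" which must sit above
  # alpha to stay consistent with the labeling rule
  adj_p[neg] <- stats::runif(length(neg))
  down_neg <- neg[neg_dir == "down"]
  adj_p[down_neg] <- stats::runif(length(down_neg), alpha_label, 1)
  out[, adj_p := adj_p]
  out[stats::runif(.N) < cfg$na_fraction, adj_p := NA_real_]
  truth <- list(logit = intercept + parts, prob = prob,
                intercept = intercept,
                causal_cluster_tfs = causal_cluster_tfs,
                cluster_score = cluster_score)
  list(ep = out[], truth = truth)
}

calibrate_intercept <- function(parts, target) {
  f <- function(a) mean(stats::plogis(a + parts)) - target
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0) stop("unattainable prevalence")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < 1e-10) break
  }
  (lo + hi) / 2
}

#' Observable feature columns of each planted effect
#'
#' For parameter-recovery checks: maps each planted effect of the label
#' logit to the feature columns through which a fitted model can express it.
#' The latent promoter-insensitivity flag surfaces through the elevated
#' active promoter marks; the causal TF cluster surfaces through its member
#' TFs' enhancer-side presence columns and, when an enhancer-side NMF fit is
#' supplied, through the NMF component most loaded on those TFs.
#'
#' @param truth Truth list from [simulate_ep_dataset()].
#' @param nmf_enh Optional enhancer-side [nmf_fit()] result.
#' @return Named list of character vectors of feature column names.
#' @export
planted_feature_sets <- function(truth, nmf_enh = NULL) {
  causal_tfs <- truth$labels$causal_cluster_tfs
  tf_cols <- paste0(causal_tfs, "_e")
  if (!is.null(nmf_enh)) {
    load_on_causal <- rowSums(nmf_enh$H[, causal_tfs, drop = FALSE])
    comp <- which.max(load_on_causal)
    tf_cols <- c(tf_cols, paste0("TF_NMF", comp, "_e"))
  }
  list(contact = "contact",
       activity = "normalized_H3K27ac_e",
       distance = "distance",
       promoter_insensitivity = c("H3K27ac.RPKM.quantile_TSS", "H3K4me3_TSS"),
       tf_cluster = tf_cols)
}

#' Simulate a complete EP dataset
#'
#' Convenience wrapper running element placement, contact simulation, TF
#' presence, candidate enumeration, and label planting under one seed.
#'
#' @param cfg A [sim_config()].
#' @param bin_size Contact bin width in bp.
#' @return List with `elements`, `contacts`, `tf_matrix`, `ep` (candidates
#'   with contact, labels, adj_p), and `truth` (element, TF, and label
#'   truths).
#' @export
simulate_ep_dataset <- function(cfg = sim_config(), bin_size = 5000L) {
  se <- simulate_elements(cfg)
  cm <- simulate_contacts(se$elements, cfg, bin_size)
  tf <- simulate_tf_presence(se$elements, cfg)
  ep <- ep_candidates(se$elements, cfg$window_bp)
  ep <- ep_attach_contact(ep, cm)
  lab <- simulate_labels(ep, se$elements, tf, se$truth, cfg)
  list(elements = se$elements, contacts = cm, tf_matrix = tf$tf_matrix,
       ep = lab$ep,
       truth = list(elements = se$truth, tf = tf$truth, labels = lab$truth))
}
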