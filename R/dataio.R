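# Readers/writers for the on-disk formats used throughout the pipeline.
# Coordinates are BED convention everywhere: 0-based, half-open [start, end).
# A TSS is a 1-bp interval at the transcription start.

#' @import data.table
#' @importFrom stats median quantile rbinom rnorm runif setNames rlnorm qbinom plogis
#' @importFrom utils head tail
NULL

ELEMENT_CORE_COLS <- c("chrom", "start", "end", "element_id", "kind")

#' Read a table of regulatory elements
#'
#' Parses a BED-like tab-separated file of enhancers and TSSs. The first five
#' columns are `chrom`, `start`, `end`, `element_id`, `kind` (either
#' `"enhancer"` or `"tss"`); any further columns are treated as named activity
#' signals (e.g. `normalized_H3K27ac_e`, `TargetGeneExpression`) and attached
#' by header name. A header line is recognised by its first field being
#' `chrom`; headerless five-column files are accepted.
#'
#' @param path Path to a tab-separated element file.
#' @return A `data.table` with one row per element, sorted stably by
#'   `(chrom, start)`.
#' @export
read_elements <- function(path) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1L)
  has_header <- startsWith(first, "chrom")
  dt <- data.table::fread(path, sep = "\t", header = has_header,
                          colClasses = list(character = 1))
  if (!has_header) {
    if (ncol(dt) < 5L)
      stop("element file must have at least 5 columns (chrom,start,end,element_id,kind)")
    data.table::setnames(dt, seq_len(5L), ELEMENT_CORE_COLS)
  }
  missing_cols <- setdiff(ELEMENT_CORE_COLS, names(dt))
  if (length(missing_cols))
    stop("element file missing columns: ", paste(missing_cols, collapse = ", "))
  validate_elements(dt)
  data.table::setorderv(dt, c("chrom", "start"))
  dt[]
}

validate_elements <- function(dt) {
  bad <- which(!(dt$start >= 0 & dt$start < dt$end))
  if (length(bad))
    stop("malformed coordinates (need 0 <= start < end) at line(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  dup <- dt$element_id[duplicated(dt$element_id)]
  if (length(dup))
    stop("duplicate element_id: ", paste(unique(utils::head(dup, 5L)), collapse = ", "))
  if (!all(dt$kind %in% c("enhancer", "tss")))
    stop("kind must be 'enhancer' or 'tss'")
  invisible(dt)
}

#' Write an element table
#'
#' Inverse of [read_elements()]; writes a tab-separated file with header so
#' that `read_elements(write_elements(x))` round-trips exactly.
#'
#' @param elements Element `data.table` as returned by [read_elements()].
#' @param path Output path.
#' @export
write_elements <- function(elements, path) {
  validate_elements(elements)
  extra <- setdiff(names(elements), ELEMENT_CORE_COLS)
  data.table::fwrite(elements[, c(ELEMENT_CORE_COLS, extra), with = FALSE],
                     path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Midpoint of an element
#'
#' Integer midpoint `(start + end) %/% 2` in BED coordinates; for the 1-bp TSS
#' interval this is the transcription start itself.
#'
#' @param elements Element table.
#' @return Integer vector of midpoints.
#' @export
element_midpoint <- function(elements) {
  (elements$start + elements$end) %/% 2L
}

# ---- contact maps -----------------------------------------------------------

#' Construct a sparse symmetric contact map
#'
#' A contact map stores KR-normalized (matrix-balanced) Hi-C contact values
#' between genomic bins of fixed width. Entries are stored once in canonical
#' order (`bin_i <= bin_j`) and queried symmetrically; absent pairs read as 0.
#'
#' @param entries `data.frame` with columns `chrom`, `bin_i`, `bin_j`,
#'   `contact` (non-negative).
#' @param bin_size Bin width in bp (default 5000).
#' @return An object of class `contact_map`.
#' @export
contact_map <- function(entries, bin_size = 5000L) {
  stopifnot(bin_size > 0)
  dt <- data.table::as.data.table(entries)
  if (nrow(dt) == 0L) {
    dt <- data.table::data.table(chrom = character(), bin_i = integer(),
                                 bin_j = integer(), contact = numeric())
  } else {
    stopifnot(all(c("chrom", "bin_i", "bin_j", "contact") %in% names(dt)))
    if (any(dt$contact < 0)) stop("negative contact value")
    lo <- pmin(dt$bin_i, dt$bin_j)
    hi <- pmax(dt$bin_i, dt$bin_j)
    dt <- data.table::data.table(chrom = dt$chrom, bin_i = lo, bin_j = hi,
                                 contact = dt$contact)
    dt <- dt[, .(contact = sum(contact)), by = .(chrom, bin_i, bin_j)]
  }
  data.table::setkeyv(dt, c("chrom", "bin_i", "bin_j"))
  structure(list(entries = dt, bin_size = as.integer(bin_size)),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: %d entries, bin_size %d bp\n",
              nrow(x$entries), x$bin_size))
  invisible(x)
}

#' Read contacts from a BEDPE-like file
#'
#' Rows are `chrom1 start1 end1 chrom2 start2 end2 value`. Anchors are mapped
#' to bins by integer division of the anchor start by `bin_size`.
#' Inter-chromosomal rows are skipped with a warning (the analysis is
#' intra-chromosomal); duplicate rows for one bin pair are summed with a
#' warning.
#'
#' @param path BEDPE file path.
#' @param bin_size Bin width in bp.
#' @return A [contact_map()].
#' @export
read_contacts <- function(path, bin_size = 5000L) {
  stopifnot(file.exists(path))
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          col.names = c("chrom1", "start1", "end1",
                                        "chrom2", "start2", "end2", "value"))
  if (any(dt$value < 0)) stop("negative contact value in ", path)
  inter <- dt$chrom1 != dt$chrom2
  if (any(inter)) {
    warning(sum(inter), " inter-chromosomal contact row(s) skipped")
    dt <- dt[!inter]
  }
  entries <- data.table::data.table(
    chrom = dt$chrom1,
    bin_i = as.integer(dt$start1 %/% bin_size),
    bin_j = as.integer(dt$start2 %/% bin_size),
    contact = dt$value)
  lo <- pmin(entries$bin_i, entries$bin_j)
  hi <- pmax(entries$bin_i, entries$bin_j)
  key <- paste(entries$chrom, lo, hi)
  if (anyDuplicated(key))
    warning("duplicate contact rows for the same bin pair were summed")
  contact_map(entries, bin_size)
}

#' Write a contact map as BEDPE
#'
#' @param cm A [contact_map()].
#' @param path Output path.
#' @export
write_contacts <- function(cm, path) {
  e <- cm$entries
  bs <- cm$bin_size
  out <- data.table::data.table(
    chrom1 = e$chrom, start1 = e$bin_i * bs, end1 = (e$bin_i + 1L) * bs,
    chrom2 = e$chrom, start2 = e$bin_j * bs, end2 = (e$bin_j + 1L) * bs,
    value = e$contact)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Look up contact values
#'
#' Vectorized symmetric lookup; absent pairs return 0.
#'
#' @param cm A [contact_map()].
#' @param chrom,bin_i,bin_j Vectors identifying bin pairs.
#' @return Numeric vector of contact values.
#' @export
contact_lookup <- function(cm, chrom, bin_i, bin_j) {
  lo <- pmin(bin_i, bin_j)
  hi <- pmax(bin_i, bin_j)
  q <- data.table::data.table(chrom = chrom, bin_i = as.integer(lo),
                              bin_j = as.integer(hi))
  res <- cm$entries[q, on = c("chrom", "bin_i", "bin_j")]$contact
  res[is.na(res)] <- 0
  res
}

#' Bin index of each element's midpoint
#'
#' @param elements Element table.
#' @param bin_size Bin width in bp.
#' @return Integer vector of bin indices.
#' @export
element_bin <- function(elements, bin_size) {
  as.integer(element_midpoint(elements) %/% bin_size)
}

# ---- TF peaks ---------------------------------------------------------------

#' Read TF ChIP-seq peak files
#'
#' Accepts BED or narrowPeak; only `chrom`, `start`, `end` are used and extra
#' columns are ignored. Overlapping peaks are kept as-is (no merging). The TF
#' name is taken from the file name without extension unless `tf_names` is
#' given. An empty file yields an empty interval set.
#'
#' @param paths Character vector of peak file paths.
#' @param tf_names Optional character vector of TF names, same length as
#'   `paths`.
#' @return Named list of `data.table`s with columns `chrom`, `start`, `end`.
#' @export
read_peaks <- function(paths, tf_names = NULL) {
  if (is.null(tf_names))
    tf_names <- sub("\\.(bed|narrowPeak|txt)$", "", basename(paths))
  if (anyDuplicated(tf_names))
    stop("duplicate TF names: ", paste(unique(tf_names[duplicated(tf_names)]), collapse = ", "))
  out <- lapply(paths, function(p) {
    stopifnot(file.exists(p))
    if (file.size(p) == 0L)
      return(data.table::data.table(chrom = character(), start = integer(),
                                    end = integer()))
    dt <- data.table::fread(p, sep = "\t", header = FALSE, select = 1:3,
                            col.names = c("chrom", "start", "end"))
    dt
  })
  stats::setNames(out, tf_names)
}

# ---- EP tables --------------------------------------------------------------

EP_MANDATORY_COLS <- c("enhancer_id", "tss_id", "adj_p", "effect_direction")

#' Read an enhancer-promoter results table
#'
#' Tab-separated with header; mandatory columns `enhancer_id`, `tss_id`,
#' `adj_p`, `effect_direction`. Missing adjusted p-values are encoded as the
#' literal string `NA` on disk and become `NA` in memory (those pairs carry no
#' label). Any additional feature columns are preserved verbatim.
#'
#' @param path TSV path.
#' @return A `data.table`.
#' @export
read_ep_table <- function(path) {
  stopifnot(file.exists(path))
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA")
  missing_cols <- setdiff(EP_MANDATORY_COLS, names(dt))
  if (length(missing_cols))
    stop("EP table missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  dt[]
}

#' Write an enhancer-promoter results table
#'
#' @param ep EP `data.table`.
#' @param path Output TSV path.
#' @export
write_ep_table <- function(ep, path) {
  missing_cols <- setdiff(EP_MANDATORY_COLS, names(ep))
  if (length(missing_cols))
    stop("EP table missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  data.table::fwrite(ep, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read loop-significance calls
#'
#' BEDPE-like rows `chrom1 start1 end1 chrom2 start2 end2 q` as produced by an
#' external loop-significance caller; anchors are binned like contacts.
#'
#' @param path File path.
#' @param bin_size Bin width in bp.
#' @return `data.table` with columns `chrom`, `bin_i`, `bin_j`, `q`.
#' @export
read_loops <- function(path, bin_size = 5000L) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          col.names = c("chrom1", "start1", "end1",
                                        "chrom2", "start2", "end2", "q"))
  dt <- dt[chrom1 == chrom2]
  bi <- as.integer(dt$start1 %/% bin_size)
  bj <- as.integer(dt$start2 %/% bin_size)
  data.table::data.table(chrom = dt$chrom1,
                         bin_i = pmin(bi, bj), bin_j = pmax(bi, bj), q = dt$q)
}

# ---- configuration ----------------------------------------------------------

#' Pipeline configuration
#'
#' Bundles the tunable constants of the analysis. Defaults follow the study
#' design: candidate pairing within a 5-Mb window, positives called at
#' adjusted p < 0.1, blocking gap of 5 Mb, a 4x4 nested blocked CV,
#' chromosomes 5/10/15/20 held out, NMF with k = 12, model comparison at
#' recall 0.70, and weak/strong contact thresholds of 0.002 (class analysis)
#' and 0.005 (distribution plots).
#'
#' @param window_bp Candidate window span in bp (pairs within `window_bp/2`
#'   center-to-center).
#' @param bin_size Hi-C bin width in bp.
#' @param alpha_label Adjusted-p threshold for calling a positive.
#' @param gap_bp Minimum genomic gap separating blocking groups.
#' @param outer_folds,inner_folds Nested CV fold counts.
#' @param holdout_chroms Chromosomes set aside as an independent test set.
#' @param nmf_k Number of NMF co-binding clusters per side.
#' @param recall_target Recall at which models are compared.
#' @param weak_contact_threshold Contact below this is "weak".
#' @param strong_contact_threshold_fig1 Alternative strong/weak split point.
#' @param tss_flank_bp Flank around the TSS for promoter-side TF overlap.
#' @param boruta_rounds Shadow-selection rounds.
#' @param tune_budget Hyper-parameter candidates evaluated per outer fold.
#' @param early_stop_rounds Early-stopping patience (boosting rounds).
#' @param seed Integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(window_bp = 5e6,
                            bin_size = 5000L,
                            alpha_label = 0.1,
                            gap_bp = 5e6,
                            outer_folds = 4L,
                            inner_folds = 4L,
                            holdout_chroms = c("chr5", "chr10", "chr15", "chr20"),
                            nmf_k = 12L,
                            recall_target = 0.70,
                            weak_contact_threshold = 0.002,
                            strong_contact_threshold_fig1 = 0.005,
                            tss_flank_bp = 500L,
                            boruta_rounds = 10L,
                            tune_budget = 6L,
                            early_stop_rounds = 25L,
                            seed = 1L) {
  cfg <- list(window_bp = window_bp, bin_size = as.integer(bin_size),
              alpha_label = alpha_label, gap_bp = gap_bp,
              outer_folds = as.integer(outer_folds),
              inner_folds = as.integer(inner_folds),
              holdout_chroms = holdout_chroms, nmf_k = as.integer(nmf_k),
              recall_target = recall_target,
              weak_contact_threshold = weak_contact_threshold,
              strong_contact_threshold_fig1 = strong_contact_threshold_fig1,
              tss_flank_bp = as.integer(tss_flank_bp),
              boruta_rounds = as.integer(boruta_rounds),
              tune_budget = as.integer(tune_budget),
              early_stop_rounds = as.integer(early_stop_rounds),
              seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  pos <- c("window_bp", "bin_size", "alpha_label", "gap_bp", "recall_target",
           "weak_contact_threshold", "strong_contact_threshold_fig1")
  for (f in pos) if (cfg[[f]] <= 0) stop(f, " must be positive")
  if (cfg$outer_folds < 2L || cfg$inner_folds < 2L)
    stop("fold counts must be >= 2")
  if (cfg$alpha_label >= 1) stop("alpha_label must be in (0,1)")
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror [pipeline_config()] arguments; unknown keys are an error, and
#' unspecified keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}
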