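# Non-negative matrix factorization of binary TF-presence matrices into
# co-binding clusters, fitted separately at TSSs and enhancers. Squared
# Frobenius objective, multiplicative updates, seeded multi-restart.

#' Fit NMF co-binding clusters
#'
#' Factorizes a non-negative elements x TF matrix `V ~ W H` with `W >= 0`
#' (elements x k cluster scores) and `H >= 0` (k x TF memberships) by
#' multiplicative updates minimizing the squared Frobenius reconstruction
#' error. Runs `n_restarts` seeded random initializations and keeps the best
#' fit. On return, rows of `H` are normalized to unit maximum (with `W`
#' rescaled inversely) so memberships are comparable across clusters.
#'
#' @param v Non-negative numeric matrix with dimnames (elements x TFs).
#' @param k Number of clusters, at most `min(dim(v))`.
#' @param seed Integer seed.
#' @param max_iter Maximum update iterations per restart.
#' @param tol Relative error-improvement convergence tolerance.
#' @param n_restarts Number of random restarts (best kept).
#' @param side Which element side the matrix describes (`"enhancer"` or
#'   `"tss"`); recorded for feature naming.
#' @return Object of class `ep_nmf` with `W`, `H`, `k`, `error`, `side`,
#'   `seed`.
#' @export
nmf_fit <- function(v, k, seed = 1L, max_iter = 500L, tol = 1e-8,
                    n_restarts = 5L, side = c("enhancer", "tss")) {
  side <- match.arg(side)
  v <- as.matrix(v)
  if (any(v < 0)) stop("NMF input must be non-negative")
  if (k > min(dim(v))) stop("k exceeds matrix dimensions")
  if (k < 1L) stop("k must be >= 1")
  eps <- 1e-10
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    w <- matrix(stats::runif(nrow(v) * k, 0.1, 1), nrow(v), k)
    h <- matrix(stats::runif(k * ncol(v), 0.1, 1), k, ncol(v))
    err_prev <- Inf
    for (it in seq_len(max_iter)) {
      h <- h * (crossprod(w, v) + eps) / (crossprod(w) %*% h + eps)
      w <- w * (v %*% t(h) + eps) / (w %*% tcrossprod(h) + eps)
      err <- sum((v - w %*% h)^2)
      if (is.finite(err_prev) && (err_prev - err) < tol * max(err_prev, eps))
        break
      err_prev <- err
    }
    err <- sum((v - w %*% h)^2)
    if (is.null(best) || err < best$error)
      best <- list(W = w, H = h, error = err)
  }
  # resolve scale indeterminacy: H rows to unit max
  hmax <- apply(best$H, 1, max)
  hmax[hmax == 0] <- 1
  H <- best$H / hmax
  W <- sweep(best$W, 2, hmax, `*`)
  rownames(W) <- rownames(v)
  colnames(H) <- colnames(v)
  colnames(W) <- rownames(H) <- paste0("NMF", seq_len(k))
  structure(list(W = W, H = H, k = k, error = best$error, side = side,
                 seed = seed),
            class = "ep_nmf")
}

#' @export
print.ep_nmf <- function(x, ...) {
  cat(sprintf("ep_nmf: k=%d, side=%s, reconstruction error %.4g\n",
              x$k, x$side, x$error))
  invisible(x)
}

#' NMF cluster-score feature columns
#'
#' Broadcasts the element-level `W` scores of a fitted side to EP rows,
#' producing columns named `TF_NMF<i>_e` (enhancer side) or `TF_NMF<i>_TSS`
#' (TSS side).
#'
#' @param fit An [nmf_fit()] result.
#' @param ep Candidate table.
#' @return `data.table` of `k` columns aligned to `ep` rows.
#' @export
nmf_features <- function(fit, ep) {
  ids <- if (fit$side == "enhancer") ep$enhancer_id else ep$tss_id
  if (!all(ids %in% rownames(fit$W)))
    stop("element(s) missing from the NMF fit: ",
         paste(utils::head(setdiff(ids, rownames(fit$W)), 5L), collapse = ", "))
  w <- fit$W[ids, , drop = FALSE]
  suffix <- if (fit$side == "enhancer") "_e" else "_TSS"
  colnames(w) <- paste0("TF_NMF", seq_len(fit$k), suffix)
  out <- data.table::as.data.table(w)
  out[]
}

#' Top TF members of one cluster
#'
#' TFs ranked by their `H` membership weight in the chosen cluster,
#' descending, ties broken by TF name.
#'
#' @param fit An [nmf_fit()] result.
#' @param cluster_index Cluster number in `1..k`.
#' @param top_n Number of TFs to return (truncated to the TF count).
#' @return `data.table` with columns `tf` and `membership`.
#' @export
cluster_members <- function(fit, cluster_index, top_n = 10L) {
  if (cluster_index < 1L || cluster_index > fit$k)
    stop("cluster_index out of range 1..", fit$k)
  h <- fit$H[cluster_index, ]
  ord <- order(-h, names(h))
  n <- min(top_n, length(h))
  data.table::data.table(tf = names(h)[ord][seq_len(n)],
                         membership = unname(h[ord])[seq_len(n)])
}
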