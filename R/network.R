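#' Spike raster container
#'
#' @param counts non-negative integer matrix, cells x time bins.
#' @param bin_s bin width in seconds (0.04 s at the native 25 Hz).
#' @return object of class `spike_raster` with `duration_s = bins * bin_s`.
#' @export
spike_raster <- function(counts, bin_s = 0.04) {
  if (!is.matrix(counts)) stop("'counts' must be a matrix", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("'counts' must be non-negative integers", call. = FALSE)
  if (bin_s <= 0) stop("'bin_s' must be > 0", call. = FALSE)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("cell%03d", seq_len(nrow(counts)))
  structure(list(counts = counts, bin_s = bin_s,
                 duration_s = ncol(counts) * bin_s),
            class = "spike_raster")
}

#' Cell centroid map
#'
#' @param x,y centroid coordinates in um.
#' @param cell_id unique cell identifiers (default `cell001`, ...).
#' @return data.frame of class `cell_map`.
#' @export
cell_map <- function(x, y, cell_id = sprintf("cell%03d", seq_along(x))) {
  stopifnot(length(x) == length(y), length(x) == length(cell_id))
  if (anyDuplicated(cell_id)) stop("'cell_id' must be unique", call. = FALSE)
  if (any(!is.finite(c(x, y)))) stop("coordinates must be finite", call. = FALSE)
  structure(data.frame(cell_id = as.character(cell_id), x = x, y = y,
                       stringsAsFactors = FALSE),
            class = c("cell_map", "data.frame"))
}

#' Infer spikes from calcium traces by sparse non-negative deconvolution
#'
#' Solves, per cell, `min_s 0.5 * ||y - K s||^2 + lambda * sum(s)` subject to
#' `s >= 0`, where `K` convolves a spike train with an AR(1) calcium kernel
#' `gamma^t` (FISTA iterations; both convolutions run through recursive
#' filters, so each iteration is linear in trace length). A deliberately
#' simple stand-in for dedicated deconvolution tools; rasters inferred
#' elsewhere can be passed straight to the downstream metrics.
#'
#' @param traces matrix, cells x time samples of deltaF/F.
#' @param fs sampling rate, Hz.
#' @param decay_s calcium decay time constant; `gamma = exp(-1/(fs*decay_s))`.
#' @param lambda L1 penalty (in trace units).
#' @param binarize_threshold spike counts are `round(s)` after thresholding
#'   tiny values below this fraction of the largest deconvolved weight.
#' @param max_iter,tol FISTA controls.
#' @return a [spike_raster()] with `bin_s = 1/fs`.
#' @export
infer_spikes <- function(traces, fs = 25, decay_s = 0.4, lambda = 0.1,
                         binarize_threshold = 0.1, max_iter = 200L,
                         tol = 1e-8) {
  if (!is.matrix(traces)) traces <- matrix(traces, nrow = 1L)
  if (any(!is.finite(traces))) stop("traces must be finite", call. = FALSE)
  gam <- exp(-1 / (fs * decay_s))
  Tn <- ncol(traces)
  conv_k <- function(s) as.numeric(stats::filter(s, gam, method = "recursive"))
  conv_kt <- function(r) rev(as.numeric(stats::filter(rev(r), gam,
                                                      method = "recursive")))
  L <- (1 / (1 - gam))^2  # Lipschitz bound for K'K
  infer1 <- function(y) {
    s <- z <- numeric(Tn); tk <- 1
    obj_old <- Inf
    for (it in seq_len(max_iter)) {
      grad <- conv_kt(conv_k(z) - y)
      s_new <- pmax(0, z - (grad + lambda) / L)
      tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
      z <- s_new + ((tk - 1) / tk_new) * (s_new - s)
      s <- s_new; tk <- tk_new
      r <- y - conv_k(s)
      obj <- 0.5 * sum(r^2) + lambda * sum(s)
      if (abs(obj_old - obj) < tol * max(1, obj)) break
      obj_old <- obj
    }
    s
  }
  S <- t(apply(traces, 1L, infer1))
  thr <- binarize_threshold * max(S, 1e-12)
  S[S < thr] <- 0
  spike_raster(round(S), bin_s = 1 / fs)
}

#' Per-cell spike counts over the session
#'
#' @param raster a [spike_raster()].
#' @return named numeric vector of row sums.
#' @export
spike_counts <- function(raster) {
  stopifnot(inherits(raster, "spike_raster"))
  rowSums(raster$counts)
}

# plug-in MI (bits) between two binary vectors
.binary_mi <- function(a, b) {
  n <- length(a)
  n11 <- sum(a & b); n10 <- sum(a & !b); n01 <- sum(!a & b)
  n00 <- n - n11 - n10 - n01
  p <- c(n00, n01, n10, n11) / n
  px <- c(n00 + n01, n10 + n11) / n
  py <- c(n00 + n10, n01 + n11) / n
  ex <- c(px[1] * py[1], px[1] * py[2], px[2] * py[1], px[2] * py[2])
  keep <- p > 0
  sum(p[keep] * log2(p[keep] / ex[keep]))
}

#' Mutual information from a joint distribution
#'
#' Plug-in `sum p * log2(p / (p_x p_y))` over a joint probability matrix.
#'
#' @param joint matrix of joint probabilities (must sum to 1).
#' @return MI in bits.
#' @export
mutual_information_joint <- function(joint) {
  if (abs(sum(joint) - 1) > 1e-8) stop("'joint' must sum to 1", call. = FALSE)
  px <- rowSums(joint); py <- colSums(joint)
  ex <- outer(px, py)
  keep <- joint > 0
  sum(joint[keep] * log2(joint[keep] / ex[keep]))
}

#' Pairwise mutual information grouped by inter-neuron distance
#'
#' Binarises each cell's bins (count > 0), computes the plug-in MI (bits)
#' for every unordered cell pair, and assigns each pair to the distance bin
#' of its centroid separation. No bias correction is applied; the analytic
#' plug-in bias bound `(K - 1)^2 / (2 N ln 2)` (K = 4 joint states) is
#' attached as attribute `"bias_bound_bits"`. Pairs involving a constant
#' (always-on or always-off) cell get MI 0 and `degenerate = TRUE`.
#'
#' @param raster a [spike_raster()].
#' @param cells a [cell_map()] matching the raster rows.
#' @param distance_breaks increasing distance bin edges in um; default
#'   25 um bins up to the maximal pairwise distance.
#' @return data.frame: `cell_a`, `cell_b`, `distance_um`, `distance_bin`,
#'   `mi_bits`, `degenerate`.
#' @export
pairwise_mutual_information <- function(raster, cells,
                                        distance_breaks = NULL) {
  stopifnot(inherits(raster, "spike_raster"))
  n <- nrow(raster$counts)
  if (n < 2L) stop("need at least 2 cells", call. = FALSE)
  if (nrow(cells) != n) stop("cell map does not match raster", call. = FALSE)
  B <- raster$counts > 0
  nb <- ncol(B)
  act <- rowSums(B)
  dmat <- as.matrix(stats::dist(cbind(cells$x, cells$y)))
  if (is.null(distance_breaks))
    distance_breaks <- seq(0, max(dmat) + 25, by = 25)
  if (is.unsorted(distance_breaks, strictly = TRUE))
    stop("'distance_breaks' must be strictly increasing", call. = FALSE)
  # joint (1,1) counts for all pairs at once
  n11 <- tcrossprod(B * 1)
  pairs <- which(upper.tri(dmat), arr.ind = TRUE)
  mi <- numeric(nrow(pairs)); degen <- logical(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    ai <- act[i]; aj <- act[j]
    if (ai %in% c(0L, nb) || aj %in% c(0L, nb)) { degen[r] <- TRUE; next }
    c11 <- n11[i, j]
    joint <- matrix(c(nb - ai - aj + c11, aj - c11, ai - c11, c11), 2L) / nb
    mi[r] <- mutual_information_joint(joint)
  }
  out <- data.frame(
    cell_a = rownames(raster$counts)[pairs[, 1L]],
    cell_b = rownames(raster$counts)[pairs[, 2L]],
    distance_um = dmat[pairs],
    mi_bits = mi, degenerate = degen, stringsAsFactors = FALSE)
  out$distance_bin <- cut(out$distance_um, breaks = distance_breaks,
                          include.lowest = TRUE)
  out <- out[, c("cell_a", "cell_b", "distance_um", "distance_bin", "mi_bits",
                 "degenerate")]
  attr(out, "bias_bound_bits") <- (4 - 1)^2 / (2 * nb * log(2))
  out
}

#' Deterministic activity-based community detection
#'
#' Builds a graph over cells whose edges are positive pairwise Pearson
#' correlations of binned activity above `r_threshold` (edge weight = r),
#' then maximises modularity with the Louvain algorithm under a fixed
#' internal seed and cell_id-ordered vertices, so the partition is
#' reproducible bit-for-bit. Cells without any supra-threshold edge become
#' singleton clusters.
#'
#' @param raster a [spike_raster()].
#' @param r_threshold correlation threshold for an edge (default 0.2).
#' @param rebin_s optionally re-bin counts to this width (s) before
#'   correlating.
#' @return object of class `cluster_assignment`: `membership` (named integer
#'   vector), `modularity`, `sizes`.
#' @export
cluster_activity <- function(raster, r_threshold = 0.2, rebin_s = NULL) {
  stopifnot(inherits(raster, "spike_raster"))
  cnt <- raster$counts
  if (nrow(cnt) < 2L) stop("need at least 2 cells", call. = FALSE)
  if (!is.null(rebin_s) && rebin_s > raster$bin_s) {
    f <- max(1L, round(rebin_s / raster$bin_s))
    nb <- floor(ncol(cnt) / f)
    idx <- rep(seq_len(nb), each = f)
    cnt <- t(apply(cnt[, seq_len(nb * f), drop = FALSE], 1L,
                   function(r) tapply(r, idx, sum)))
  }
  sds <- apply(cnt, 1L, sd)
  ok <- sds > 0
  R <- matrix(0, nrow(cnt), nrow(cnt))
  if (sum(ok) >= 2L) R[ok, ok] <- cor(t(cnt[ok, , drop = FALSE]))
  diag(R) <- 0
  R[R <= r_threshold] <- 0
  g <- igraph::graph_from_adjacency_matrix(R, mode = "undirected",
                                           weighted = TRUE)
  igraph::V(g)$name <- rownames(raster$counts)
  if (igraph::ecount(g) == 0L) {
    memb <- seq_len(nrow(raster$counts))
    names(memb) <- rownames(raster$counts)
    return(structure(list(membership = memb, modularity = NA_real_,
                          sizes = rep(1L, length(memb))),
                     class = "cluster_assignment"))
  }
  memb <- withr::with_seed(1L, igraph::membership(
    igraph::cluster_louvain(g, weights = igraph::E(g)$weight)))
  memb <- setNames(as.integer(memb), igraph::V(g)$name)
  structure(list(membership = memb,
                 modularity = igraph::modularity(g, memb,
                                                 weights = igraph::E(g)$weight),
                 sizes = as.integer(table(memb))),
            class = "cluster_assignment")
}

#' Cluster size distribution
#'
#' @param assignment a `cluster_assignment` from [cluster_activity()].
#' @return integer vector of cluster sizes (sums to the number of cells),
#'   sorted decreasingly.
#' @export
cluster_size_distribution <- function(assignment) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  sort(as.integer(table(assignment$membership)), decreasing = TRUE)
}

#' Flag hyperactive neurons by a firing-rate cutoff
#'
#' A configurable convenience following the common convention of classifying
#' neurons as hyperactive when their session-average event rate exceeds a
#' fixed cutoff; the cutoff itself is a study-level choice.
#'
#' @param raster a [spike_raster()].
#' @param rate_cutoff_hz rate above which a cell counts as hyperactive.
#' @return named logical vector, one entry per cell.
#' @export
classify_hyperactive <- function(raster, rate_cutoff_hz = 0.25) {
  stopifnot(inherits(raster, "spike_raster"))
  spike_counts(raster) / raster$duration_s > rate_cutoff_hz
}

#' Subsampled population entropy
#'
#' Shannon entropy (bits) of the empirical distribution of the per-bin
#' population state. The default state is the number of active cells in the
#' bin (a discretised population rate); `state = "word"` uses the full
#' binary activity word (requires coarse binning to avoid undersampling).
#' To compare sessions with different cell counts, `subsample_n` cells are
#' drawn at random, the entropy computed, and the mean over `repeats` draws
#' returned.
#'
#' @param raster a [spike_raster()].
#' @param subsample_n cells per draw (default 100). If the session has
#'   fewer cells, all are used and the result is flagged.
#' @param repeats number of random draws (default 100).
#' @param seed RNG seed for the draws.
#' @param state `"count"` (default) or `"word"`.
#' @return list: `entropy_bits` (mean over repeats), `per_repeat`,
#'   `subsampled` (FALSE when all cells were used).
#' @export
population_entropy <- function(raster, subsample_n = 100, repeats = 100,
                               seed = 1L, state = c("count", "word")) {
  state <- match.arg(state)
  stopifnot(inherits(raster, "spike_raster"))
  if (ncol(raster$counts) == 0L) stop("zero-duration raster", call. = FALSE)
  B <- raster$counts > 0
  n <- nrow(B)
  use_all <- n <= subsample_n
  ent <- function(rows) {
    s <- if (state == "count") colSums(B[rows, , drop = FALSE])
         else apply(B[rows, , drop = FALSE], 2L, paste, collapse = "")
    p <- table(s) / length(s)
    -sum(p * log2(p))
  }
  if (use_all) {
    e <- ent(seq_len(n))
    return(list(entropy_bits = e, per_repeat = e, subsampled = FALSE))
  }
  per <- withr::with_seed(seed, vapply(seq_len(repeats), function(i)
    ent(sample.int(n, subsample_n)), numeric(1)))
  list(entropy_bits = mean(per), per_repeat = per, subsampled = TRUE)
}
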