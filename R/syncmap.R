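# Synchronicity maps: per-voxel phase-of-minimum, 26-connected grouping,
# region ranking and the parametric physiological filter.

#' Per-voxel cardiac phase of the intensity minimum
#'
#' For each voxel of the preliminary CINE the frame index at which its
#' intensity time curve reaches its minimum (ties broken by the lowest
#' frame index). Voxels whose temporal mean is below
#' `floor_fraction * global mean` are marked invalid (background/noise) and
#' excluded from all downstream steps.
#'
#' @param cine A `cine_series` (or plain 4D array, frame = last dim).
#' @param floor_fraction Intensity floor as a fraction of the global mean.
#' @return Object of class `min_phase_map`: `phase` (3D integer array,
#'   1-based frame indices), `valid` (logical array), `n_frames`.
#' @export
compute_min_phase_map <- function(cine, floor_fraction = 0.2) {
  frames <- if (inherits(cine, "cine_series")) cine$frames else cine
  d <- dim(frames)
  nf <- d[4]
  m <- matrix(frames, prod(d[1:3]), nf)
  tmean <- rowMeans(m)
  gmean <- mean(tmean)
  valid <- tmean > 0 & tmean >= floor_fraction * gmean
  idx <- max.col(-m, ties.method = "first")
  structure(list(phase = array(idx, d[1:3]), valid = array(valid, d[1:3]),
                 n_frames = nf),
            class = "min_phase_map")
}

# linear ids of 26-neighbourhood same-phase pairs, one direction per offset
syncmap_edges <- function(phase, valid) {
  d <- dim(phase)
  ids <- array(seq_len(prod(d)), d)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = 0:1)
  offs <- offs[offs$dz == 1 | (offs$dz == 0 & (offs$dy == 1 |
                (offs$dy == 0 & offs$dx == 1))), ]   # 13 unique directions
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    o <- as.integer(offs[r, ])
    sx <- seq_len(d[1] - abs(o[1])); sy <- seq_len(d[2] - abs(o[2]))
    sz <- seq_len(d[3] - abs(o[3]))
    a <- ids[sx + max(0, -o[1]), sy + max(0, -o[2]), sz + max(0, -o[3])]
    b <- ids[sx + max(0, o[1]), sy + max(0, o[2]), sz + max(0, o[3])]
    ok <- valid[a] & valid[b] & phase[a] == phase[b]
    from <- c(from, a[ok]); to <- c(to, b[ok])
  }
  cbind(from, to)
}

#' Group synchronous voxels into 26-connected regions
#'
#' Voxels reaching their intensity minimum in the same cardiac phase are
#' grouped when their faces, edges or corners touch (26-connectivity);
#' groups smaller than `min_voxels` are dropped as noise. Region labels are
#' 1-based in decreasing size order.
#'
#' @param map A [compute_min_phase_map()] result.
#' @param min_voxels Minimum region size.
#' @return Object of class `synchronicity_map`: `labels` (3D integer array,
#'   `NA` outside regions), `regions` (data frame: `label`, `n_voxels`,
#'   `phase`), `n_frames`.
#' @export
connected_regions <- function(map, min_voxels = 10) {
  stopifnot(inherits(map, "min_phase_map"))
  el <- syncmap_edges(map$phase, map$valid)
  nv <- length(map$phase)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nv - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  memb[!map$valid] <- NA
  tab <- table(memb)
  keep <- as.integer(names(tab)[tab >= min_voxels])
  if (length(keep) == 0) stop("no synchronicity regions survive the size filter")
  sizes <- as.integer(tab[as.character(keep)])
  ord <- order(sizes, decreasing = TRUE)
  keep <- keep[ord]; sizes <- sizes[ord]
  relabel <- rep(NA_integer_, max(memb, na.rm = TRUE))
  relabel[keep] <- seq_along(keep)
  labels <- array(NA_integer_, dim(map$phase))
  ok <- !is.na(memb)
  labels[ok] <- relabel[memb[ok]]
  phase_of <- vapply(seq_along(keep),
                     function(i) map$phase[which(labels == i)[1]], integer(1))
  structure(list(labels = labels,
                 regions = data.frame(label = seq_along(keep),
                                      n_voxels = sizes, phase = phase_of),
                 n_frames = map$n_frames),
            class = "synchronicity_map")
}

#' Keep only the largest connected regions
#'
#' Regions are ranked by voxel count and the top
#' `ceiling(fraction * n_regions)` retained.
#'
#' @param sync A `synchronicity_map`.
#' @param fraction Fraction of regions to keep (default 0.25).
#' @return The pruned `synchronicity_map`.
#' @export
select_top_regions <- function(sync, fraction = 0.25) {
  stopifnot(inherits(sync, "synchronicity_map"),
            fraction > 0, fraction <= 1)
  k <- ceiling(fraction * nrow(sync$regions))
  keep <- sync$regions$label[order(sync$regions$n_voxels,
                                   decreasing = TRUE)][seq_len(k)]
  prune_regions(sync, keep)
}

prune_regions <- function(sync, keep) {
  labels <- sync$labels
  labels[!(labels %in% keep)] <- NA
  sync$labels <- labels
  sync$regions <- sync$regions[sync$regions$label %in% keep, , drop = FALSE]
  sync
}

region_time_curves <- function(sync, cine) {
  frames <- if (inherits(cine, "cine_series")) cine$frames else cine
  d <- dim(frames)
  m <- matrix(frames, prod(d[1:3]), d[4])
  lab <- as.vector(sync$labels)
  lapply(sync$regions$label, function(l) colMeans(m[which(lab == l), ,
                                                    drop = FALSE]))
}

#' Physiological filter on synchronicity regions
#'
#' For each region the interval between the extrema of its mean time curve
#' (circular distance, in ms via the mean RR, from the curve maximum to the
#' following minimum — the end-diastole-to-end-systole interval) is compared
#' against the systolic-interval model evaluated at the subject's average
#' heart rate; regions outside
#' `[model * (1 - margin_low), model * (1 + margin_high)]` are discarded.
#' This separates the left-ventricular region (whose extrema interval
#' matches the expected ejection time) from e.g. the outflow tract.
#'
#' @param sync A `synchronicity_map`.
#' @param cine The `cine_series` the map was derived from.
#' @param mean_rr_ms Mean RR interval (ms).
#' @param model A [stretch_model()] (its `a`, `b` coefficients are used).
#' @param margins Lower/upper acceptance margins (default `c(0.3, 0.3)`).
#' @return The filtered `synchronicity_map`; `regions` gains
#'   `extrema_interval_ms`.
#' @export
filter_physiological <- function(sync, cine, mean_rr_ms,
                                 model = stretch_model(),
                                 margins = c(0.3, 0.3)) {
  stopifnot(inherits(sync, "synchronicity_map"))
  curves <- region_time_curves(sync, cine)
  nf <- sync$n_frames
  interval_ms <- vapply(curves, function(cv) {
    ((which.min(cv) - which.max(cv)) %% nf) * (100 / nf) * mean_rr_ms / 100
  }, numeric(1))
  et <- systolic_interval_ms(model, 60000 / mean_rr_ms)
  lo <- et * (1 - margins[1]); hi <- et * (1 + margins[2])
  keep <- interval_ms >= lo & interval_ms <= hi
  sync$regions$extrema_interval_ms <- interval_ms
  if (!any(keep)) {
    stop("physiological filter rejected all regions (expected interval [",
         round(lo), ", ", round(hi), "] ms); region intervals: ",
         paste(round(interval_ms), collapse = ", "), " ms")
  }
  prune_regions(sync, sync$regions$label[keep])
}

#' Average (and min-max normalize) the time curves of masked voxels
#'
#' @param cine A `cine_series` or 4D array.
#' @param mask Logical 3D array (or a `synchronicity_map`, whose remaining
#'   regions form the mask).
#' @return Numeric vector of length `n_frames`, normalized to `[0, 1]`;
#'   attribute `raw_range` holds the pre-normalization min/max.
#' @export
mean_time_curve <- function(cine, mask) {
  frames <- if (inherits(cine, "cine_series")) cine$frames else cine
  if (inherits(mask, "synchronicity_map")) mask <- !is.na(mask$labels)
  if (!any(mask)) stop("empty mask: no voxels to average")
  d <- dim(frames)
  m <- matrix(frames, prod(d[1:3]), d[4])
  cv <- colMeans(m[as.vector(mask), , drop = FALSE])
  rng <- range(cv)
  out <- if (diff(rng) > 0) (cv - rng[1]) / diff(rng) else cv * 0
  attr(out, "raw_range") <- rng
  out
}
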