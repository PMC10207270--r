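# Ensemble-level analysis: per-residue-pair CO...CO distance distributions
# (narrow for helical ensembles, broad for disordered ones) and
# agglomerative clustering of frames on best-fit backbone RMSD.

#' Consecutive-pair distance distributions over an ensemble
#'
#' For every consecutive residue pair of the shared roster, collects the
#' O(i)...C(i+1) distance in each frame (uniform frame weights — frames are
#' counted identically, with no reweighting) and summarizes the resulting
#' distribution. `narrowness` = IQR / median is the dimensionless width
#' measure used to contrast well-folded (small) against disordered (large)
#' ensembles. A pair missing from some frames contributes only the frames
#' that have it; the shortfall is reported in `n_absent`.
#'
#' @param ensemble a [ttb_ensemble].
#' @param weighting frame weighting scheme; only `"uniform"` is defined.
#' @return a `ttb_distributions` data.frame with columns `pair`, `chain`,
#'   `res_i`, `res_j`, `n`, `n_absent`, `median`, `iqr`, `narrowness`, plus
#'   a list-column `distances` holding the raw per-frame values.
#' @examples
#' ens <- build_ensemble(helix_spec(n_residues = 8, noise_sigma = 5,
#'                                  n_frames = 25, seed = 3))
#' distance_distributions(ens)[, 1:9]
#' @export
distance_distributions <- function(ensemble, weighting = "uniform") {
  stopifnot(inherits(ensemble, "ttb_ensemble"))
  weighting <- match.arg(weighting, "uniform")
  per_frame <- lapply(ensemble$frames, pairwise_consecutive_distances)
  keys <- lapply(per_frame, function(df) paste(df$chain, df$res_i, df$res_j))
  shared <- Reduce(union, keys)
  if (length(shared) == 0L) stop("no consecutive residue pairs in the ensemble")
  # keep first-frame ordering, then any pairs only seen later
  ord <- unique(unlist(keys))
  shared <- ord[ord %in% shared]

  rows <- lapply(shared, function(k) {
    vals <- unlist(lapply(seq_along(per_frame), function(m) {
      df <- per_frame[[m]]
      hit <- which(keys[[m]] == k)
      if (length(hit) == 0L) NULL else df$d_OC[hit[1L]]
    }))
    first <- NULL
    for (m in seq_along(per_frame)) {
      hit <- which(keys[[m]] == k)
      if (length(hit) > 0L) { first <- per_frame[[m]][hit[1L], ]; break }
    }
    med <- stats::median(vals)
    iqr <- stats::IQR(vals)
    data.frame(pair = first$pair, chain = first$chain,
               res_i = first$res_i, res_j = first$res_j,
               n = length(vals), n_absent = ensemble$n_frames - length(vals),
               median = med, iqr = iqr,
               narrowness = iqr / med,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$distances <- lapply(shared, function(k) {
    unlist(lapply(seq_along(per_frame), function(m) {
      hit <- which(keys[[m]] == k)
      if (length(hit) == 0L) NULL else per_frame[[m]]$d_OC[hit[1L]]
    }))
  })
  rownames(out) <- NULL
  class(out) <- c("ttb_distributions", "data.frame")
  out
}

#' Best-fit RMSD between two coordinate sets
#'
#' Least-squares superposition (Kabsch rotation with reflection guard, via
#' bio3d) followed by root-mean-square deviation over the ordered atom
#' correspondence; symmetric in its arguments. With `fit = FALSE` the raw
#' RMSD in the original frames is returned.
#'
#' @param frame_a,frame_b numeric n x 3 coordinate matrices, n >= 3, same n.
#' @param fit superpose before measuring (default TRUE).
#' @return RMSD in angstroms.
#' @export
superpose_rmsd <- function(frame_a, frame_b, fit = TRUE) {
  frame_a <- as.matrix(frame_a)
  frame_b <- as.matrix(frame_b)
  if (nrow(frame_a) != nrow(frame_b))
    stop("coordinate sets differ in atom count")
  if (nrow(frame_a) < 3L) stop("need at least 3 atoms for superposition")
  av <- as.numeric(t(frame_a))
  bv <- as.numeric(t(frame_b))
  as.numeric(bio3d::rmsd(av, bv, fit = fit))
}

# Coordinate matrix of one frame for a given atom selection, rows ordered
# by (chain, resno, insert). Residues lacking a selected atom are dropped
# consistently across frames by the caller.
frame_coords <- function(frame, atoms) {
  ord <- order(frame$chain, frame$resno, frame$insert)
  frame <- frame[ord, , drop = FALSE]
  mats <- list()
  if ("CA" %in% atoms)
    mats$CA <- as.matrix(frame[, c("ca_x", "ca_y", "ca_z")])
  if ("CB" %in% atoms)
    mats$CB <- as.matrix(frame[, c("cb_x", "cb_y", "cb_z")])
  do.call(rbind, mats)
}

#' Cluster ensemble frames by backbone RMSD
#'
#' Agglomerative average-linkage clustering on the matrix of pairwise
#' best-fit RMSDs over the selected atoms; merging stops when the minimum
#' inter-cluster distance exceeds `epsilon` (tree cut at height epsilon).
#' Clusters are numbered by decreasing population (cluster 1 = most
#' populated); each cluster's centroid is the member frame minimizing the
#' summed RMSD to its co-members.
#'
#' @param ensemble a [ttb_ensemble] with >= 2 frames and CA coordinates.
#' @param epsilon merge threshold in angstroms (default 2).
#' @param atom_selection `"CA+CB"` (default) or `"CA"`; when CB atoms are
#'   absent from the ensemble the selection falls back to CA with a
#'   warning.
#' @param linkage agglomeration method; only `"average"` is defined.
#' @return data.frame with one row per cluster: `cluster` (1-based rank by
#'   size), `size`, `centroid` (frame index), and list-column `members`.
#' @export
cluster_frames <- function(ensemble, epsilon = 2,
                           atom_selection = c("CA+CB", "CA"),
                           linkage = "average") {
  stopifnot(inherits(ensemble, "ttb_ensemble"), epsilon > 0)
  atom_selection <- match.arg(atom_selection)
  linkage <- match.arg(linkage, "average")
  nf <- ensemble$n_frames
  if (nf < 2L) stop("clustering needs at least 2 frames")

  atoms <- if (atom_selection == "CA+CB") c("CA", "CB") else "CA"
  have_cb <- any(vapply(ensemble$frames,
                        function(f) any(!is.na(f$cb_x)), logical(1L)))
  if ("CB" %in% atoms && !have_cb) {
    warning("no CB atoms in ensemble; falling back to CA-only RMSD")
    atoms <- "CA"
  }
  coords <- lapply(ensemble$frames, frame_coords, atoms = atoms)
  coords <- lapply(coords, function(m) m[stats::complete.cases(m), , drop = FALSE])
  sizes <- vapply(coords, nrow, integer(1L))
  if (length(unique(sizes)) != 1L)
    stop("frames have mismatched atom counts for RMSD: frames ",
         paste(which(sizes != sizes[1L]), collapse = ", "))
  if (sizes[1L] < 3L) stop("too few atoms with coordinates for RMSD")

  dm <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1L)) {
    for (j in (i + 1L):nf) {
      dm[i, j] <- dm[j, i] <- superpose_rmsd(coords[[i]], coords[[j]])
    }
  }
  hc <- stats::hclust(stats::as.dist(dm), method = "average")
  memb <- stats::cutree(hc, h = epsilon)

  ids <- sort(unique(memb))
  members <- lapply(ids, function(k) which(memb == k))
  ordsz <- order(vapply(members, length, integer(1L)), decreasing = TRUE)
  members <- members[ordsz]
  centroid <- vapply(members, function(ix) {
    if (length(ix) == 1L) return(ix)
    ix[which.min(vapply(ix, function(i) sum(dm[i, ix]), numeric(1L)))]
  }, integer(1L))
  out <- data.frame(cluster = seq_along(members),
                    size = vapply(members, length, integer(1L)),
                    centroid = centroid)
  out$members <- members
  out
}
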