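# Geometric detection of C=O...C=O tetrel-bond (n->pi*) contacts.
#
# A contact is a donor oxygen O_i approaching the pi-hole face of an
# acceptor carbonyl carbon C_j. Two criteria define it: the O...C distance
# and the O...C=O approach angle, which for a nucleophile attacking a
# carbonyl clusters around the Burgi-Dunitz trajectory (~107 degrees).

#' Detect carbonyl-carbonyl tetrel-bond contacts in one frame
#'
#' Scans every ordered (donor, acceptor) carbonyl pair of a frame and
#' retains those with O_donor...C_acceptor distance at or below `cutoff`
#' and approach angle theta (O_donor...C_acceptor=O_acceptor) inside
#' `angle_window`. The default cutoff 3.6 A sits slightly above the longest
#' tetrel-bond distance reported for peptide backbones (~3.38 A) and near
#' the O/C van der Waals sum; the default angle window [95, 125] degrees
#' brackets the Burgi-Dunitz approach. The canonical helical contact is
#' O of residue i donating into C of residue i+1 (separation +1); both
#' directions are examined and the direction is carried by the sign of
#' `separation`.
#'
#' @param frame a [carbonyl_frame()].
#' @param cutoff maximum O...C distance in angstroms (> 0).
#' @param angle_window numeric length-2, admissible theta range in degrees,
#'   inside (0, 180).
#' @param min_separation minimum |sequence separation| between donor and
#'   acceptor residues of the same chain (inter-chain pairs always pass).
#' @return a `ttb_contacts` data.frame with columns `chain_i, res_i,
#'   name_i, chain_j, res_j, name_j, d_OC, theta, separation, model`,
#'   sorted by donor chain, donor residue, acceptor residue. Empty frame or
#'   no hits give a zero-row table.
#' @examples
#' fr <- build_backbone(helix_spec(n_residues = 10))
#' detect_contacts(fr)
#' @export
detect_contacts <- function(frame, cutoff = 3.6, angle_window = c(95, 125),
                            min_separation = 1L) {
  stopifnot(cutoff > 0, length(angle_window) == 2L,
            angle_window[1L] < angle_window[2L],
            angle_window[1L] > 0, angle_window[2L] < 180)
  empty <- data.frame(chain_i = character(0), res_i = integer(0),
                      name_i = character(0), chain_j = character(0),
                      res_j = integer(0), name_j = character(0),
                      d_OC = numeric(0), theta = numeric(0),
                      separation = integer(0), model = integer(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("ttb_contacts", "data.frame")
  n <- nrow(frame)
  if (is.null(n) || n < 2L) return(empty)

  idx <- sequence_index(frame)
  O <- as.matrix(frame[, c("o_x", "o_y", "o_z")])
  C <- as.matrix(frame[, c("c_x", "c_y", "c_z")])

  rows <- vector("list", 0L)
  for (i in seq_len(n)) {       # donor (O)
    for (j in seq_len(n)) {     # acceptor (C)
      if (i == j) next
      sep <- if (frame$chain[i] == frame$chain[j]) idx[j] - idx[i] else NA_integer_
      if (!is.na(sep) && abs(sep) < min_separation) next
      d <- vnorm(O[i, ] - C[j, ])
      if (d > cutoff) next
      th <- angle_deg(O[i, ], C[j, ], O[j, ])
      if (th < angle_window[1L] || th > angle_window[2L]) next
      rows[[length(rows) + 1L]] <- data.frame(
        chain_i = frame$chain[i], res_i = frame$resno[i],
        name_i = frame$resid[i], chain_j = frame$chain[j],
        res_j = frame$resno[j], name_j = frame$resid[j],
        d_OC = d, theta = th, separation = sep,
        model = frame$model[i], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$chain_i, out$res_i, out$res_j), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ttb_contacts", "data.frame")
  out
}

# 1-based position of each residue along its chain (ordered by residue
# number then insertion code); sequence separation is a difference of these.
sequence_index <- function(frame) {
  idx <- integer(nrow(frame))
  for (ch in unique(frame$chain)) {
    sel <- which(frame$chain == ch)
    ord <- sel[order(frame$resno[sel], frame$insert[sel])]
    idx[ord] <- seq_along(ord)
  }
  idx
}

#' Consecutive-residue O(i)...C(i+1) distances of a frame
#'
#' For each pair of sequence-consecutive residues of the same chain,
#' reports the distance from the carbonyl O of residue i to the carbonyl C
#' of residue i+1 — the quantity whose per-ensemble distribution separates
#' helical from disordered conformers. Pairs bridging a chain break
#' (CA(i)-CA(i+1) above 4.5 A, when CA coordinates are present) are
#' flagged.
#'
#' @param frame a [carbonyl_frame()].
#' @return data.frame with columns `pair` (label `"<resid_i> <resno_i> -
#'   <resid_j> <resno_j>"`), `chain`, `res_i`, `res_j`, `d_OC`,
#'   `chain_break`. Single-residue chains contribute no rows.
#' @export
pairwise_consecutive_distances <- function(frame) {
  out <- list()
  for (ch in unique(frame$chain)) {
    sel <- which(frame$chain == ch)
    sel <- sel[order(frame$resno[sel], frame$insert[sel])]
    if (length(sel) < 2L) next
    for (k in seq_len(length(sel) - 1L)) {
      i <- sel[k]; j <- sel[k + 1L]
      d <- vnorm(c(frame$o_x[i], frame$o_y[i], frame$o_z[i]) -
                 c(frame$c_x[j], frame$c_y[j], frame$c_z[j]))
      brk <- FALSE
      if (!anyNA(c(frame$ca_x[i], frame$ca_x[j]))) {
        dca <- vnorm(c(frame$ca_x[i], frame$ca_y[i], frame$ca_z[i]) -
                     c(frame$ca_x[j], frame$ca_y[j], frame$ca_z[j]))
        brk <- dca > 4.5
      }
      out[[length(out) + 1L]] <- data.frame(
        pair = sprintf("%s %d - %s %d", frame$resid[i], frame$resno[i],
                       frame$resid[j], frame$resno[j]),
        chain = ch, res_i = frame$resno[i], res_j = frame$resno[j],
        d_OC = d, chain_break = brk, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(pair = character(0), chain = character(0),
                      res_i = integer(0), res_j = integer(0),
                      d_OC = numeric(0), chain_break = logical(0)))
  do.call(rbind, out)
}

#' Annotate contacts with density and energy estimates
#'
#' Chains the geometric contact through the distance-to-density surrogate
#' and the density-to-energy calibration: `rho_est = predict(ddm, d_OC)`,
#' `dE_est` = tetrel-bond share of the calibrated line at `rho_est` (see
#' [estimate_ttb_energy()]).
#'
#' @param contacts a `ttb_contacts` table.
#' @param ddm a [fit_distance_density()] model (default: fitted to the
#'   bundled peptide tables).
#' @param calibration a [fit_calibration()] model (default: bundled model
#'   complexes 2-6).
#' @return `contacts` with `rho_est` and `dE_est` columns appended.
#' @export
annotate_energies <- function(contacts, ddm = default_distance_density(),
                              calibration = default_calibration()) {
  if (nrow(contacts) == 0L) {
    contacts$rho_est <- numeric(0)
    contacts$dE_est <- numeric(0)
    return(contacts)
  }
  contacts$rho_est <- predict(ddm, contacts$d_OC)
  est <- suppressWarnings(estimate_ttb_energy(contacts$rho_est, calibration))
  contacts$dE_est <- est$dE_ttb
  contacts
}
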