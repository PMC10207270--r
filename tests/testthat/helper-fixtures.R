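# Shared fixture builders: all synthetic, generated in code at test time.

# One fixed-column PDB coordinate record.
pdb_atom_line <- function(serial, name, resid, chain, resno, xyz,
                          occ = 1, b = 0, alt = "", record = "ATOM") {
  name4 <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name4, alt, resid, chain, resno,
          xyz[1L], xyz[2L], xyz[3L], occ, b, substr(name, 1L, 1L))
}

# PDB text for one backbone frame (N/CA/C/O per residue), optionally
# renaming residues or dropping atoms.
frame_to_pdb <- function(frame, drop_o_for = integer(0), resid_override = NULL) {
  lines <- character(0)
  k <- 0L
  for (i in seq_len(nrow(frame))) {
    resid <- if (is.null(resid_override)) frame$resid[i] else resid_override[i]
    atoms <- list(c("N", "n_x", "n_y", "n_z"),
                  c("CA", "ca_x", "ca_y", "ca_z"),
                  c("C", "c_x", "c_y", "c_z"),
                  c("O", "o_x", "o_y", "o_z"))
    for (a in atoms) {
      if (a[1L] == "O" && frame$resno[i] %in% drop_o_for) next
      k <- k + 1L
      lines <- c(lines, pdb_atom_line(k, a[1L], resid, frame$chain[i],
                                      frame$resno[i],
                                      as.numeric(frame[i, a[2:4]])))
    }
  }
  c(lines, "END")
}

# Apply a rigid rotation + translation to every coordinate block of a frame.
rigid_move_frame <- function(frame, axis = c(1, 2, 3), angle = 37,
                             shift = c(5.5, -3.2, 11.1)) {
  R <- ttbscan:::rotation_matrix(axis, angle)
  for (p in c("n", "ca", "cb", "c", "o")) {
    cols <- paste0(p, c("_x", "_y", "_z"))
    if (!all(cols %in% names(frame))) next
    m <- as.matrix(frame[, cols])
    ok <- stats::complete.cases(m)
    if (!any(ok)) next
    m[ok, ] <- t(R %*% t(m[ok, , drop = FALSE])) +
      matrix(shift, sum(ok), 3L, byrow = TRUE)
    frame[, cols] <- m
  }
  frame
}

# Independent all-pairs double-loop re-derivation of the contact criteria,
# kept deliberately naive (no sorting tricks, no shared code path).
brute_force_contacts <- function(frame, cutoff = 3.6,
                                 angle_window = c(95, 125),
                                 min_separation = 1L) {
  n <- nrow(frame)
  res <- data.frame()
  ord_idx <- function(ch, rn, ins) {
    sel <- which(frame$chain == ch)
    sel <- sel[order(frame$resno[sel], frame$insert[sel])]
    which(frame$resno[sel] == rn & frame$insert[sel] == ins)
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    o_i <- c(frame$o_x[i], frame$o_y[i], frame$o_z[i])
    c_j <- c(frame$c_x[j], frame$c_y[j], frame$c_z[j])
    o_j <- c(frame$o_x[j], frame$o_y[j], frame$o_z[j])
    d <- sqrt(sum((o_i - c_j)^2))
    if (d > cutoff) next
    u <- o_i - c_j
    v <- o_j - c_j
    th <- acos(max(-1, min(1, sum(u * v) / sqrt(sum(u * u) * sum(v * v))))) * 180 / pi
    if (th < angle_window[1L] || th > angle_window[2L]) next
    sep <- NA_integer_
    if (frame$chain[i] == frame$chain[j])
      sep <- ord_idx(frame$chain[j], frame$resno[j], frame$insert[j]) -
             ord_idx(frame$chain[i], frame$resno[i], frame$insert[i])
    if (!is.na(sep) && abs(sep) < min_separation) next
    res <- rbind(res, data.frame(res_i = frame$resno[i], res_j = frame$resno[j],
                                 d_OC = d, theta = th))
  }
  if (nrow(res) > 0L) res <- res[order(res$res_i, res$res_j), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Brute-force best-fit RMSD oracle: exhaustive Euler-angle grid with two
# refinement passes, on mean-centered coordinates.
grid_rmsd_oracle <- function(a, b) {
  a <- scale(as.matrix(a), scale = FALSE)
  b <- scale(as.matrix(b), scale = FALSE)
  rms_at <- function(ang) {
    R <- ttbscan:::rotation_matrix(c(0, 0, 1), ang[3L]) %*%
         ttbscan:::rotation_matrix(c(0, 1, 0), ang[2L]) %*%
         ttbscan:::rotation_matrix(c(1, 0, 0), ang[1L])
    sqrt(mean(rowSums((a %*% t(R) - b)^2)))
  }
  best <- c(0, 0, 0)
  bv <- rms_at(best)
  step <- 30
  grid <- expand.grid(seq(-180, 180, 30), seq(-90, 90, 30), seq(-180, 180, 30))
  for (k in seq_len(nrow(grid))) {
    v <- rms_at(as.numeric(grid[k, ]))
    if (v < bv) { bv <- v; best <- as.numeric(grid[k, ]) }
  }
  for (step in c(10, 3, 1, 0.3, 0.1, 0.03, 0.01)) {
    repeat {
      improved <- FALSE
      for (dim in 1:3) for (sgn in c(-1, 1)) {
        cand <- best
        cand[dim] <- cand[dim] + sgn * step
        v <- rms_at(cand)
        if (v < bv - 1e-12) { bv <- v; best <- cand; improved <- TRUE }
      }
      if (!improved) break
    }
  }
  bv
}

# Small deliberately non-helical random frame with plausible C=O units.
random_carbonyl_frame <- function(n, seed) {
  set.seed(seed)
  ca <- matrix(cumsum(stats::rnorm(n * 3L, 0, 1.3)), n, 3L) +
    3.8 * cbind(seq_len(n), 0, 0)
  dirs <- matrix(stats::rnorm(n * 3L), n, 3L)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  cc <- ca + 1.52 * dirs
  od <- matrix(stats::rnorm(n * 3L), n, 3L)
  od <- od / sqrt(rowSums(od^2))
  oo <- cc + 1.231 * od
  carbonyl_frame(chain = rep("A", n), resno = seq_len(n),
                 resid = rep("GLY", n), c_xyz = cc, o_xyz = oo, ca_xyz = ca)
}
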