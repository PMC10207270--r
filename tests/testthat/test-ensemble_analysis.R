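test_that("identical frames give zero-width distributions and a single cluster", {
  ens <- build_ensemble(helix_spec(n_residues = 6, noise_sigma = 0,
                                   n_frames = 10, seed = 1))
  dd <- distance_distributions(ens)
  expect_equal(nrow(dd), 5L)
  expect_equal(dd$n, rep(10L, 5L))
  expect_equal(dd$iqr, rep(0, 5L))
  expect_equal(dd$narrowness, rep(0, 5L))

  cl <- cluster_frames(ens, epsilon = 2, atom_selection = "CA")
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$size, 10L)
})

test_that("pairs absent from some frames are counted as absent, not zero", {
  full <- build_backbone(helix_spec(n_residues = 3, seed = 2))
  partial <- full[full$resno < 3L, ]
  class(partial) <- class(full)
  frames <- c(replicate(7, full, simplify = FALSE),
              replicate(3, partial, simplify = FALSE))
  expect_warning(ens <- as_ensemble(frames), "roster")
  dd <- suppressWarnings(distance_distributions(ens))
  row23 <- dd[dd$res_i == 2L & dd$res_j == 3L, ]
  expect_equal(row23$n, 7L)
  expect_equal(row23$n_absent, 3L)
  expect_length(row23$distances[[1L]], 7L)
  row12 <- dd[dd$res_i == 1L & dd$res_j == 2L, ]
  expect_equal(row12$n, 10L)
})

test_that("helical ensembles are narrower than coil ensembles", {
  helical <- build_ensemble(helix_spec(n_residues = 12, noise_sigma = 5,
                                       n_frames = 200, seed = 101))
  coil <- build_ensemble(helix_spec(n_residues = 12, noise_sigma = 40,
                                    n_frames = 200, seed = 202))
  dh <- distance_distributions(helical)
  dc <- distance_distributions(coil)
  expect_lt(stats::median(dh$narrowness), stats::median(dc$narrowness))
  expect_lt(stats::median(dh$iqr), stats::median(dc$iqr))
})

test_that("distributions are invariant under frame reordering", {
  ens <- build_ensemble(helix_spec(n_residues = 6, noise_sigma = 15,
                                   n_frames = 20, seed = 31))
  set.seed(5)
  perm <- sample(ens$n_frames)
  ens2 <- as_ensemble(ens$frames[perm], source_label = ens$source_label)
  a <- distance_distributions(ens)
  b <- distance_distributions(ens2)
  expect_equal(a$pair, b$pair)
  expect_equal(a$median, b$median)
  expect_equal(a$iqr, b$iqr)
  for (k in seq_len(nrow(a)))
    expect_equal(sort(a$distances[[k]]), sort(b$distances[[k]]))
})

test_that("superpose RMSD is zero on rigid copies and matches a grid-search oracle", {
  fr <- build_backbone(helix_spec(n_residues = 8, noise_sigma = 10, seed = 12))
  ca <- as.matrix(fr[, c("ca_x", "ca_y", "ca_z")])
  expect_equal(superpose_rmsd(ca, ca), 0, tolerance = 1e-12)

  moved <- rigid_move_frame(fr, angle = 54, shift = c(-4, 9, 2))
  ca_m <- as.matrix(moved[, c("ca_x", "ca_y", "ca_z")])
  expect_lt(superpose_rmsd(ca, ca_m), 1e-9)
  expect_equal(superpose_rmsd(ca, ca_m), superpose_rmsd(ca_m, ca),
               tolerance = 1e-9)

  # 4-point toy sets: one point displaced by 1.0 A
  a <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(0, 2, 1))
  b <- a
  b[2L, ] <- b[2L, ] + c(0, 0, 1)
  expect_equal(superpose_rmsd(a, b, fit = FALSE), 0.5, tolerance = 1e-12)
  expect_equal(superpose_rmsd(a, b), grid_rmsd_oracle(a, b), tolerance = 1e-3)
  expect_lt(superpose_rmsd(a, b), 0.5)

  expect_error(superpose_rmsd(a[1:2, ], b[1:2, ]), "at least 3")
  expect_error(superpose_rmsd(a, b[1:3, ]), "atom count")
})

test_that("two jittered conformations separate into two clusters at epsilon 2", {
  helix <- build_backbone(helix_spec(n_residues = 12, seed = 1))
  extended <- build_backbone(helix_spec(n_residues = 12, phi = -140, psi = 135,
                                        seed = 1))
  jitter <- function(fr, seed) {
    set.seed(seed)
    for (cc in grep("_(x|y|z)$", names(fr), value = TRUE))
      fr[[cc]] <- fr[[cc]] + stats::rnorm(nrow(fr), 0, 0.03)
    fr
  }
  frames <- c(lapply(1:5, function(s) jitter(helix, s)),
              lapply(6:10, function(s) jitter(extended, s)))
  ens <- as_ensemble(frames)
  expect_gt(superpose_rmsd(as.matrix(frames[[1]][, c("ca_x", "ca_y", "ca_z")]),
                           as.matrix(frames[[6]][, c("ca_x", "ca_y", "ca_z")])),
            4)
  cl <- suppressWarnings(cluster_frames(ens, epsilon = 2))
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$size, c(5L, 5L))
  expect_setequal(unlist(cl$members), 1:10)
  for (k in 1:2) expect_true(cl$centroid[k] %in% cl$members[[k]])
})

test_that("cluster count is non-increasing in epsilon and collapses in the limit", {
  ens <- build_ensemble(helix_spec(n_residues = 10, noise_sigma = 25,
                                   n_frames = 12, seed = 77))
  eps <- c(0.3, 0.8, 1.5, 3, 8, 1e6)
  counts <- vapply(eps, function(e)
    nrow(suppressWarnings(cluster_frames(ens, epsilon = e))), integer(1L))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[length(counts)], 1L)
})

test_that("clustering falls back to CA when CB atoms are absent", {
  ens <- build_ensemble(helix_spec(n_residues = 6, noise_sigma = 10,
                                   n_frames = 4, seed = 9))
  expect_warning(cluster_frames(ens, epsilon = 2, atom_selection = "CA+CB"),
                 "falling back to CA")
})

test_that("frames with mismatched atom counts are rejected with the offenders listed", {
  a <- build_backbone(helix_spec(n_residues = 6, seed = 1))
  b <- build_backbone(helix_spec(n_residues = 5, seed = 2))
  ens <- suppressWarnings(as_ensemble(list(a, a, b)))
  expect_error(suppressWarnings(cluster_frames(ens, epsilon = 2)),
               "mismatched atom counts")
})
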