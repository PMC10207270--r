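# Synthetic backbone generator: internal-coordinate (NeRF) chain build with
# Gaussian dihedral noise. Stands in for MD-derived conformational ensembles
# in tests and examples.

# Fixed covalent geometry of the peptide unit (angstroms / degrees).
# These are the generator's fixture constants: every generated frame carries
# exactly these bond lengths and angles, whatever the dihedral noise.
BACKBONE_GEOMETRY <- list(
  b_n_ca  = 1.458,  # N-CA bond
  b_ca_c  = 1.525,  # CA-C bond
  b_c_n   = 1.329,  # C-N peptide bond
  b_c_o   = 1.231,  # C=O bond
  a_n_ca_c  = 111.2,  # N-CA-C
  a_ca_c_n  = 116.2,  # CA-C-N
  a_c_n_ca  = 121.7,  # C-N-CA
  a_ca_c_o  = 120.8   # CA-C=O (O anti to the next N)
)

#' Specification of a synthetic backbone ensemble
#'
#' Defines a poly-alanine-like backbone built from ideal covalent geometry
#' with per-residue (phi, psi) dihedrals drawn around a target conformation.
#' The defaults (phi = -57, psi = -47, omega = 180) give an ideal alpha
#' helix; `noise_sigma` is the standard deviation (degrees) of independent
#' Gaussian perturbations applied to each residue's phi and psi, so small
#' sigma emulates a well-folded helical ensemble and large sigma (~40
#' degrees) a disordered, coil-like one.
#'
#' @param n_residues number of residues (>= 1).
#' @param phi,psi,omega backbone dihedrals in degrees; defaults are the ideal
#'   alpha-helix values.
#' @param noise_sigma per-residue dihedral noise s.d. in degrees (>= 0).
#' @param n_frames number of frames in the ensemble (>= 1).
#' @param seed integer master seed; frame i uses a seed derived
#'   deterministically from it (see [frame_seed()]).
#' @return an object of class `helix_spec`.
#' @examples
#' spec <- helix_spec(n_residues = 12)
#' frame <- build_backbone(spec)
#' @export
helix_spec <- function(n_residues, phi = -57, psi = -47, omega = 180,
                       noise_sigma = 0, n_frames = 1L, seed = 1L) {
  if (!is.numeric(n_residues) || length(n_residues) != 1L || n_residues < 1)
    stop("n_residues must be a single integer >= 1")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (n_frames < 1) stop("n_frames must be >= 1")
  structure(list(n_residues = as.integer(n_residues),
                 phi = phi, psi = psi, omega = omega,
                 noise_sigma = noise_sigma,
                 n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "helix_spec")
}

#' Derive the RNG seed for one frame of an ensemble
#'
#' SplitMix-style integer mixing of (master seed, frame index) so that
#' ensembles are reproducible frame-by-frame and extensible in `n_frames`
#' without disturbing earlier frames. Arithmetic stays below 2^53 so the
#' double-precision modular reduction is exact; the result is < 2^31.
#'
#' @param seed master integer seed.
#' @param i frame index (1-based).
#' @return a single integer seed.
#' @export
frame_seed <- function(seed, i) {
  m <- 2^31
  s <- (abs(as.numeric(seed)) + as.numeric(i) * 2654435.0) %% m
  s <- (s * 48271 + 3266489) %% m
  s <- (s * 69621 + 2654435) %% m
  as.integer(s)
}

#' Build one backbone frame from a helix specification
#'
#' Chain construction by natural extension of internal coordinates: residue
#' 1 is seeded in a canonical frame and each subsequent residue's N, CA, C
#' are placed from the running (psi, omega, phi) torsions; the carbonyl O is
#' placed in the peptide plane anti to the next backbone N (torsion psi +
#' 180). With `noise_sigma = 0` and default angles the result is an ideal
#' alpha helix (rise close to 1.5 A per residue, 3.6 residues per turn).
#'
#' @param spec a [helix_spec()].
#' @param frame_seed RNG seed for this frame's dihedral noise; defaults to
#'   the spec's master seed. Same spec + seed gives bit-identical
#'   coordinates.
#' @param model_index model number recorded on the returned frame.
#' @return a carbonyl frame (see [carbonyl_frame()]) with N coordinates in
#'   extra columns `n_x, n_y, n_z`.
#' @export
build_backbone <- function(spec, frame_seed = spec$seed, model_index = 1L) {
  stopifnot(inherits(spec, "helix_spec"))
  g <- BACKBONE_GEOMETRY
  n <- spec$n_residues

  set.seed(frame_seed)
  phis <- spec$phi + stats::rnorm(n, 0, spec$noise_sigma)
  psis <- spec$psi + stats::rnorm(n, 0, spec$noise_sigma)

  N <- CA <- C <- O <- matrix(NA_real_, n, 3L)
  # residue 1 in a canonical local frame
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(g$b_n_ca, 0, 0)
  ang <- g$a_n_ca_c * pi / 180
  C[1L, ] <- CA[1L, ] + g$b_ca_c * c(-cos(ang), sin(ang), 0)

  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      N[i + 1L, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                                g$b_c_n, g$a_ca_c_n, psis[i])
      CA[i + 1L, ] <- place_atom(CA[i, ], C[i, ], N[i + 1L, ],
                                 g$b_n_ca, g$a_c_n_ca, spec$omega)
      C[i + 1L, ] <- place_atom(C[i, ], N[i + 1L, ], CA[i + 1L, ],
                                g$b_ca_c, g$a_n_ca_c, phis[i + 1L])
    }
  }
  for (i in seq_len(n)) {
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         g$b_c_o, g$a_ca_c_o, psis[i] + 180)
  }

  out <- carbonyl_frame(chain = rep("A", n),
                        resno = seq_len(n),
                        resid = rep("ALA", n),
                        c_xyz = C, o_xyz = O, ca_xyz = CA,
                        model = as.integer(model_index))
  out$n_x <- N[, 1L]; out$n_y <- N[, 2L]; out$n_z <- N[, 3L]
  out
}

#' Build a synthetic backbone ensemble
#'
#' Generates `spec$n_frames` independent frames, each built by
#' [build_backbone()] with a per-frame seed from [frame_seed()].
#'
#' @param spec a [helix_spec()].
#' @param source_label label recorded on the ensemble.
#' @return a [ttb_ensemble] object.
#' @examples
#' ens <- build_ensemble(helix_spec(n_residues = 10, noise_sigma = 5,
#'                                  n_frames = 20, seed = 7))
#' @export
build_ensemble <- function(spec, source_label = "synthetic") {
  stopifnot(inherits(spec, "helix_spec"))
  frames <- lapply(seq_len(spec$n_frames), function(i)
    build_backbone(spec, frame_seed = frame_seed(spec$seed, i),
                   model_index = i))
  as_ensemble(frames, source_label = source_label)
}
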