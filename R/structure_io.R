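# Structure input/output: multi-model PDB parsing into backbone-carbonyl
# rosters, contact-table serialization, and multi-model PDB writing for
# synthetic ensembles. PDB records themselves are handled by bio3d; this
# layer adds validation, altloc resolution and the carbonyl extraction.

CARBONYL_COLS <- c("chain", "resno", "insert", "resid", "model",
                   "c_x", "c_y", "c_z", "o_x", "o_y", "o_z",
                   "ca_x", "ca_y", "ca_z", "cb_x", "cb_y", "cb_z")

# Residue names never treated as carbonyl carriers: waters and common
# monoatomic ions.
EXCLUDED_RESIDUES <- c("HOH", "WAT", "NA", "CL", "K", "MG", "CA", "ZN",
                       "MN", "FE", "BR", "IOD", "CS")

#' Construct a backbone-carbonyl frame
#'
#' A frame is a data.frame with one row per residue carrying the C=O unit
#' coordinates (and optionally CA/CB). Rows whose C=O bond length falls
#' outside (1.0, 1.6) A are rejected with a warning: such records are not
#' plausible carbonyls.
#'
#' @param chain chain identifiers.
#' @param resno author residue numbers (integer).
#' @param resid residue names (3-4 character codes; non-standard residues
#'   such as MK8/0EH/2JH are first-class citizens).
#' @param c_xyz,o_xyz n x 3 matrices of carbonyl C and O coordinates (A).
#' @param ca_xyz,cb_xyz optional n x 3 matrices (NA where absent).
#' @param insert insertion codes ("" when none).
#' @param model model index (integer >= 1).
#' @return data.frame of class `carbonyl_frame`.
#' @export
carbonyl_frame <- function(chain, resno, resid, c_xyz, o_xyz,
                           ca_xyz = NULL, cb_xyz = NULL,
                           insert = "", model = 1L) {
  n <- length(resno)
  c_xyz <- matrix(as.numeric(c_xyz), n, 3L)
  o_xyz <- matrix(as.numeric(o_xyz), n, 3L)
  if (is.null(ca_xyz)) ca_xyz <- matrix(NA_real_, n, 3L)
  if (is.null(cb_xyz)) cb_xyz <- matrix(NA_real_, n, 3L)
  df <- data.frame(chain = as.character(chain),
                   resno = as.integer(resno),
                   insert = rep_len(as.character(insert), n),
                   resid = as.character(resid),
                   model = rep_len(as.integer(model), n),
                   c_x = c_xyz[, 1L], c_y = c_xyz[, 2L], c_z = c_xyz[, 3L],
                   o_x = o_xyz[, 1L], o_y = o_xyz[, 2L], o_z = o_xyz[, 3L],
                   ca_x = ca_xyz[, 1L], ca_y = ca_xyz[, 2L], ca_z = ca_xyz[, 3L],
                   cb_x = cb_xyz[, 1L], cb_y = cb_xyz[, 2L], cb_z = cb_xyz[, 3L],
                   stringsAsFactors = FALSE)
  blen <- sqrt((df$c_x - df$o_x)^2 + (df$c_y - df$o_y)^2 + (df$c_z - df$o_z)^2)
  bad <- !is.na(blen) & (blen <= 1.0 | blen >= 1.6)
  if (any(bad)) {
    warning(sprintf("rejecting %d record(s) with implausible C=O bond length (%s)",
                    sum(bad),
                    paste(utils::head(sprintf("%s%d", df$resid[bad], df$resno[bad]), 5L),
                          collapse = ", ")))
    df <- df[!bad, , drop = FALSE]
  }
  key <- paste(df$chain, df$resno, df$insert, df$model)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, model) in carbonyl frame")
  rownames(df) <- NULL
  class(df) <- c("carbonyl_frame", "data.frame")
  df
}

#' Bundle frames into a structure ensemble
#'
#' Frames are expected to share the same (chain, residue) carbonyl roster;
#' if they do not, the ensemble records the full union but downstream
#' per-pair analyses operate on what each frame provides, and a warning is
#' emitted here.
#'
#' @param frames list of `carbonyl_frame` objects.
#' @param source_label free-text provenance label.
#' @return object of class `ttb_ensemble` with elements `frames`,
#'   `source_label`, `n_frames`.
#' @export
as_ensemble <- function(frames, source_label = "") {
  stopifnot(is.list(frames), length(frames) >= 1L)
  rosters <- lapply(frames, function(f) paste(f$chain, f$resno, f$insert))
  common <- Reduce(intersect, rosters)
  if (any(vapply(rosters, function(r) length(setdiff(r, common)) > 0, logical(1L))))
    warning("frames differ in carbonyl roster; analyses use the shared roster")
  structure(list(frames = frames,
                 source_label = source_label,
                 n_frames = length(frames)),
            class = "ttb_ensemble")
}

#' @export
print.ttb_ensemble <- function(x, ...) {
  cat(sprintf("ttb_ensemble: %d frame(s), %d carbonyl(s) in frame 1%s\n",
              x$n_frames, nrow(x$frames[[1L]]),
              if (nzchar(x$source_label)) paste0(" [", x$source_label, "]") else ""))
  invisible(x)
}

# Pre-scan PDB text for structurally broken coordinate records so parse
# errors can name the offending line (bio3d would silently mangle them).
validate_pdb_lines <- function(lines) {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop(sprintf("malformed ATOM/HETATM record at line %d: too short", i))
    coords <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (any(is.na(suppressWarnings(as.numeric(coords)))))
      stop(sprintf("malformed ATOM/HETATM record at line %d: bad coordinate field", i))
  }
  invisible(TRUE)
}

# Resolve alternate locations: keep the highest-occupancy conformer of each
# (chain, resno, insert, atom name), ties broken by altloc letter order.
resolve_altloc <- function(atom) {
  alt <- atom$alt
  alt[is.na(alt)] <- ""
  occ <- atom$o
  occ[is.na(occ)] <- 1
  key <- paste(atom$chain, atom$resno, atom$insert, atom$elety)
  ord <- order(key, -occ, alt)
  atom <- atom[ord, , drop = FALSE]
  key <- key[ord]
  atom[!duplicated(key), , drop = FALSE]
}

#' Parse a (multi-model) PDB structure into a carbonyl ensemble
#'
#' Reads PDB-format text and extracts one [carbonyl_frame()] per MODEL (a
#' single frame when the file has no MODEL records). Every residue that
#' carries atoms named "C" and "O" contributes a carbonyl, regardless of its
#' residue name, so non-natural amino acids (hydrocarbon-staple residues
#' MK8, 0EH, 2JH; protonation variants such as HIE) and suitable HETATM
#' groups are captured. Waters and monoatomic ions are excluded; residues
#' with a C but no O are skipped with a warning. Alternate locations keep
#' the highest-occupancy conformer (ties by altloc letter).
#'
#' @param pdb_source path to a PDB file, or a character vector of PDB lines.
#' @param source_label label stored on the ensemble; defaults to the file
#'   name.
#' @return a [ttb_ensemble].
#' @examples
#' ens <- build_ensemble(helix_spec(n_residues = 5, n_frames = 2, seed = 1))
#' path <- tempfile(fileext = ".pdb")
#' write_ensemble_pdb(ens, path)
#' parse_structure(path)
#' @export
parse_structure <- function(pdb_source, source_label = NULL) {
  if (length(pdb_source) == 1L && !grepl("\n", pdb_source) && file.exists(pdb_source)) {
    lines <- readLines(pdb_source, warn = FALSE)
    if (is.null(source_label)) source_label <- basename(pdb_source)
  } else {
    lines <- unlist(strsplit(pdb_source, "\n", fixed = TRUE))
    if (is.null(source_label)) source_label <- "<text>"
  }
  validate_pdb_lines(lines)
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, multi = TRUE, rm.alt = FALSE, verbose = FALSE)

  atom <- pdb$atom
  atom$insert[is.na(atom$insert)] <- ""
  atom <- atom[!(atom$resid %in% EXCLUDED_RESIDUES), , drop = FALSE]
  if (nrow(atom) == 0L) stop("no carbonyl groups could be extracted (empty structure)")
  # track the xyz column block of each atom row before altloc filtering
  atom$xyz_idx <- seq_len(nrow(pdb$atom))[!(pdb$atom$resid %in% EXCLUDED_RESIDUES)]
  atom <- resolve_altloc(atom)

  # drop single-atom het groups (ions slipping past the name list)
  rkey <- paste(atom$chain, atom$resno, atom$insert)
  multi <- names(which(table(rkey) > 1L))
  atom <- atom[rkey %in% multi, , drop = FALSE]
  if (nrow(atom) == 0L) stop("no carbonyl groups could be extracted (empty structure)")

  nmodels <- nrow(pdb$xyz)
  rkey <- paste(atom$chain, atom$resno, atom$insert)
  res_split <- split(seq_len(nrow(atom)), rkey)
  # preserve file order of residues
  res_split <- res_split[order(vapply(res_split, min, numeric(1L)))]

  get_xyz <- function(model, rows, name) {
    j <- rows[atom$elety[rows] == name]
    if (length(j) == 0L) return(rep(NA_real_, 3L))
    idx <- (atom$xyz_idx[j[1L]] - 1L) * 3L + 1:3
    as.numeric(pdb$xyz[model, idx])
  }

  skipped <- character(0)
  frames <- vector("list", nmodels)
  for (m in seq_len(nmodels)) {
    recs <- lapply(res_split, function(rows) {
      cc <- get_xyz(m, rows, "C")
      oo <- get_xyz(m, rows, "O")
      if (anyNA(cc) || anyNA(oo)) return(NULL)
      list(chain = atom$chain[rows[1L]],
           resno = atom$resno[rows[1L]],
           insert = atom$insert[rows[1L]],
           resid = atom$resid[rows[1L]],
           ca = get_xyz(m, rows, "CA"),
           cb = get_xyz(m, rows, "CB"),
           c = cc, o = oo)
    })
    if (m == 1L) {
      miss <- vapply(recs, is.null, logical(1L))
      if (any(miss))
        skipped <- names(res_split)[miss]
    }
    recs <- Filter(Negate(is.null), recs)
    if (length(recs) == 0L) stop("no carbonyl groups could be extracted (empty structure)")
    frames[[m]] <- carbonyl_frame(
      chain = vapply(recs, `[[`, "", "chain"),
      resno = vapply(recs, `[[`, 0L, "resno"),
      resid = vapply(recs, `[[`, "", "resid"),
      c_xyz = do.call(rbind, lapply(recs, `[[`, "c")),
      o_xyz = do.call(rbind, lapply(recs, `[[`, "o")),
      ca_xyz = do.call(rbind, lapply(recs, `[[`, "ca")),
      cb_xyz = do.call(rbind, lapply(recs, `[[`, "cb")),
      insert = vapply(recs, `[[`, "", "insert"),
      model = m)
  }
  if (length(skipped) > 0L)
    warning(sprintf("skipped %d residue(s) lacking a complete C=O unit: %s",
                    length(skipped), paste(skipped, collapse = ", ")))
  as_ensemble(frames, source_label = source_label)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Serializes the N/CA/C/O (and CB when present) atoms of every frame as
#' MODEL/ENDMDL blocks; round-trips through [parse_structure()] at PDB's
#' 3-decimal coordinate precision.
#'
#' @param ensemble a [ttb_ensemble].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "ttb_ensemble"))
  f1 <- ensemble$frames[[1L]]
  atom_sets <- list(c("n_x", "n_y", "n_z", "N"),
                    c("ca_x", "ca_y", "ca_z", "CA"),
                    c("cb_x", "cb_y", "cb_z", "CB"),
                    c("c_x", "c_y", "c_z", "C"),
                    c("o_x", "o_y", "o_z", "O"))
  build_rows <- function(fr) {
    rows <- list()
    for (i in seq_len(nrow(fr))) {
      for (as_ in atom_sets) {
        if (!all(as_[1:3] %in% names(fr))) next
        xyz <- as.numeric(fr[i, as_[1:3]])
        if (anyNA(xyz)) next
        rows[[length(rows) + 1L]] <- list(chain = fr$chain[i], resno = fr$resno[i],
                                          resid = fr$resid[i], elety = as_[4L],
                                          xyz = xyz)
      }
    }
    rows
  }
  con <- file(path, "w")
  on.exit(close(con))
  multi <- ensemble$n_frames > 1L
  for (m in seq_len(ensemble$n_frames)) {
    rows <- build_rows(ensemble$frames[[m]])
    if (multi) writeLines(sprintf("MODEL %8d", m), con)
    for (k in seq_along(rows)) {
      r <- rows[[k]]
      el <- substr(r$elety, 1L, 1L)
      name4 <- if (nchar(r$elety) < 4L) sprintf(" %-3s", r$elety) else r$elety
      writeLines(sprintf("ATOM  %5d %4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                         k, name4, r$resid, r$chain, r$resno,
                         r$xyz[1L], r$xyz[2L], r$xyz[3L], 1, 0, el), con)
    }
    writeLines(if (multi) "ENDMDL" else "TER", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Serialize a contact table
#'
#' Deterministic column order and table-style precision: distances and
#' angles to 3 decimals, energies and density estimates to 1 and 2 decimals
#' respectively (half away from zero), matching the precision used for
#' reporting throughout the package.
#'
#' @param contacts a `ttb_contacts` data.frame from [detect_contacts()],
#'   optionally annotated by [annotate_energies()].
#' @param format_choice `"tsv"` or `"json"`.
#' @return a single character scalar (TSV text or JSON text).
#' @export
write_contacts <- function(contacts, format_choice = c("tsv", "json")) {
  format_choice <- match.arg(format_choice)
  cols <- c("chain_i", "res_i", "name_i", "chain_j", "res_j", "name_j",
            "d_OC", "theta", "separation", "rho_est", "dE_est")
  df <- as.data.frame(contacts)
  for (cc in setdiff(cols, names(df))) df[[cc]] <- rep(NA, nrow(df))
  df <- df[, cols, drop = FALSE]
  out <- data.frame(
    chain_i = df$chain_i, res_i = df$res_i, name_i = df$name_i,
    chain_j = df$chain_j, res_j = df$res_j, name_j = df$name_j,
    d_OC = sprintf("%.3f", df$d_OC),
    theta = sprintf("%.3f", df$theta),
    separation = df$separation,
    rho_est = ifelse(is.na(df$rho_est), "NA", sprintf("%.2f", round_half_away(df$rho_est, 2L))),
    dE_est = ifelse(is.na(df$dE_est), "NA", sprintf("%.1f", round_half_away(df$dE_est, 1L))),
    stringsAsFactors = FALSE)
  if (format_choice == "tsv") {
    tc <- textConnection("tsv_out", "w", local = TRUE)
    utils::write.table(out, tc, sep = "\t", quote = FALSE, row.names = FALSE)
    close(tc)
    paste0(paste(tsv_out, collapse = "\n"), "\n")
  } else {
    as.character(jsonlite::toJSON(out, dataframe = "rows", na = "null",
                                  auto_unbox = FALSE, pretty = TRUE))
  }
}

#' Read a contact table written by [write_contacts()]
#'
#' @param text TSV or JSON text.
#' @param format_choice `"tsv"` or `"json"`.
#' @return a data.frame with numeric d_OC/theta/rho_est/dE_est columns.
#' @export
read_contacts <- function(text, format_choice = c("tsv", "json")) {
  format_choice <- match.arg(format_choice)
  df <- if (format_choice == "tsv") {
    utils::read.delim(textConnection(text), stringsAsFactors = FALSE,
                      colClasses = c(chain_i = "character", chain_j = "character",
                                     name_i = "character", name_j = "character"))
  } else {
    as.data.frame(jsonlite::fromJSON(text))
  }
  for (cc in c("d_OC", "theta", "rho_est", "dE_est"))
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  df
}
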