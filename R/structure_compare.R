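# Coordinate parsing, Kabsch superposition of C-alpha sets, asymmetric-unit
# chain inventories and sequence-derived average masses. File reading goes
# through bio3d; the unit cell and space group are taken from the CRYST1 /
# _cell records directly since bio3d's readers do not expose them.

# Average residue masses (Da) of the 20 standard amino acids; a chain adds
# one water (18.0153 Da) on top of the residue sum.
RESIDUE_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
WATER_MASS <- 18.0153

#' Average molecular mass of a polypeptide chain
#'
#' Sum of average residue masses plus one water; no modifications.
#'
#' @param sequence One-letter residue string (standard residues only).
#' @return Mass in Da.
#' @export
chain_mass <- function(sequence) {
  ch <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!ch %in% names(RESIDUE_MASS))
  if (length(bad) > 0)
    stop("non-standard residue '", ch[bad[1]], "' at position ", bad[1])
  sum(RESIDUE_MASS[ch]) + WATER_MASS
}

.parse_cryst1 <- function(lines) {
  ln <- grep("^CRYST1", lines, value = TRUE)
  if (length(ln) == 0) return(list(cell = NULL, space_group = NULL))
  ln <- ln[1]
  cell <- as.numeric(c(substr(ln, 7, 15), substr(ln, 16, 24),
                       substr(ln, 25, 33), substr(ln, 34, 40),
                       substr(ln, 41, 47), substr(ln, 48, 54)))
  names(cell) <- c("a", "b", "c", "alpha", "beta", "gamma")
  list(cell = cell, space_group = trimws(substr(ln, 56, 66)))
}

.parse_cif_cell <- function(lines) {
  grab <- function(tag) {
    ln <- grep(paste0("^", tag, "[[:space:]]"), lines, value = TRUE)
    if (length(ln) == 0) return(NA_real_)
    as.numeric(strsplit(trimws(ln[1]), "[[:space:]]+")[[1]][2])
  }
  cell <- c(a = grab("_cell.length_a"), b = grab("_cell.length_b"),
            c = grab("_cell.length_c"), alpha = grab("_cell.angle_alpha"),
            beta = grab("_cell.angle_beta"), gamma = grab("_cell.angle_gamma"))
  sg <- grep("^_symmetry.space_group_name_H-M", lines, value = TRUE)
  sg <- if (length(sg) > 0)
    gsub("['\"]", "", sub("^\\S+\\s+", "", trimws(sg[1]))) else NULL
  if (all(is.na(cell))) cell <- NULL
  list(cell = cell, space_group = sg)
}

#' Read a coordinate file into a structure model
#'
#' Accepts PDB or mmCIF (chosen by extension). All polymer chains of the
#' asymmetric unit are extracted with their C-alpha coordinates and
#' one-letter sequence (first alternate location kept); the unit cell and
#' space group are parsed when present.
#'
#' @param path Path to a `.pdb`/`.ent` or `.cif` file.
#' @param entry_id Optional entry identifier; defaults to the file stem.
#' @return A `dd_structure` list: `entry_id`, `chains` (named list with
#'   `sequence` and an n x 3 `ca` coordinate matrix in Angstrom), `cell`,
#'   `space_group`.
#' @export
read_structure <- function(path, entry_id = NULL) {
  if (!file.exists(path)) stop("coordinate file not found: ", path)
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  pdb <- if (is_cif) bio3d::read.cif(path) else bio3d::read.pdb(path)
  at <- pdb$atom
  ca <- at[at$elety == "CA" & at$type == "ATOM", , drop = FALSE]
  if (!is.null(ca$alt)) {
    keep <- is.na(ca$alt) | ca$alt %in% c("", "A", ".")
    ca <- ca[keep, , drop = FALSE]
  }
  if (nrow(ca) == 0) stop("no polymer chains in ", path)
  chains <- lapply(split(ca, ca$chain), function(cc) {
    cc <- cc[!duplicated(paste(cc$resno, cc$insert)), , drop = FALSE]
    list(sequence = paste(bio3d::aa321(cc$resid), collapse = ""),
         ca = as.matrix(cc[, c("x", "y", "z")]))
  })
  hdr_lines <- readLines(path, warn = FALSE)
  hdr <- if (is_cif) .parse_cif_cell(hdr_lines) else .parse_cryst1(hdr_lines)
  out <- list(entry_id = if (is.null(entry_id))
                sub("\\.[^.]+$", "", basename(path)) else entry_id,
              chains = chains, cell = hdr$cell,
              space_group = hdr$space_group)
  class(out) <- "dd_structure"
  out
}

#' Least-squares rigid superposition of paired points (Kabsch)
#'
#' Finds the proper rotation (determinant +1; reflections excluded) and
#' translation minimising the RMSD between `x` transformed and `y`.
#'
#' @param x,y n x 3 matrices of paired coordinates (n >= 3, not collinear).
#' @return A `dd_superposition` list: `rotation` (applied on the right of
#'   row-vector coordinates), `translation`, `rmsd` (Angstrom), `n_pairs`.
#' @export
kabsch_superpose <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(ncol(x) == 3, ncol(y) == 3, nrow(x) == nrow(y))
  n <- nrow(x)
  if (n < 3) stop("need at least 3 paired points")
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  if (svd(xc)$d[2] < 1e-8 * max(1, svd(xc)$d[1]) ||
      svd(yc)$d[2] < 1e-8 * max(1, svd(yc)$d[1]))
    stop("rank-deficient (collinear) point configuration")
  s <- svd(t(xc) %*% yc)
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  trans <- cy - as.vector(cx %*% rot)
  moved <- x %*% rot + matrix(trans, n, 3, byrow = TRUE)
  out <- list(rotation = rot, translation = trans,
              rmsd = sqrt(mean(rowSums((moved - y)^2))), n_pairs = n)
  class(out) <- "dd_superposition"
  out
}

# Sequence-alignment-based residue pairing of two chains; returns 1-based
# index pairs into the CA rows of each chain.
.pair_chain <- function(ca_a, ca_b) {
  aln <- align_pair(ca_a$sequence, ca_b$sequence,
                    gap_open = 11, gap_extend = 1)
  qc <- strsplit(aln$aligned_query, "")[[1]]
  rc <- strsplit(aln$aligned_ref, "")[[1]]
  ia <- 0L; ib <- 0L
  pairs <- matrix(0L, 0, 2)
  for (k in seq_along(qc)) {
    if (qc[k] != "-") ia <- ia + 1L
    if (rc[k] != "-") ib <- ib + 1L
    if (qc[k] != "-" && rc[k] != "-")
      pairs <- rbind(pairs, c(ia, ib))
  }
  pairs
}

.crop_core <- function(chain, core) {
  # core = 0-based half-open interval in chain residue coordinates
  if (is.null(core)) return(chain)
  idx <- (core[1] + 1L):min(core[2], nrow(chain$ca))
  list(sequence = substr(chain$sequence, core[1] + 1L, core[2]),
       ca = chain$ca[idx, , drop = FALSE])
}

#' Pair C-alpha atoms of two monomers or dimers
#'
#' Residues are paired through global sequence alignment. For a
#' dimer-versus-dimer comparison both chain-pair assignments are evaluated
#' and the one giving the lower superposition RMSD is kept.
#'
#' @param chains_a,chains_b Lists of one or two chain entries (as in the
#'   `chains` element of [read_structure()]).
#' @return A list: `xyz_a`, `xyz_b` (paired coordinate matrices),
#'   `assignment` (chain pairing used), `n_pairs`.
#' @export
pair_ca <- function(chains_a, chains_b) {
  stopifnot(length(chains_a) %in% 1:2, length(chains_b) %in% 1:2)
  assignments <- if (length(chains_a) == 2 && length(chains_b) == 2)
    list(c(1, 2), c(2, 1)) else list(seq_along(chains_b))
  best <- NULL
  for (asg in assignments) {
    xa <- NULL; xb <- NULL
    for (i in seq_along(chains_a)) {
      j <- asg[min(i, length(asg))]
      p <- .pair_chain(chains_a[[i]], chains_b[[j]])
      xa <- rbind(xa, chains_a[[i]]$ca[p[, 1], , drop = FALSE])
      xb <- rbind(xb, chains_b[[j]]$ca[p[, 2], , drop = FALSE])
    }
    if (nrow(xa) < 3) next
    fit <- kabsch_superpose(xa, xb)
    if (is.null(best) || fit$rmsd < best$rmsd)
      best <- list(xyz_a = xa, xyz_b = xb, assignment = asg,
                   n_pairs = nrow(xa), rmsd = fit$rmsd)
  }
  if (is.null(best)) stop("fewer than 3 residue pairs")
  best
}

#' Superpose two structures (monomer or dimer comparison)
#'
#' Pairs residues by sequence alignment (optionally restricted to a core
#' interval per chain), then performs a Kabsch superposition. An optional
#' iterative-trim mode repeats the fit after discarding pairs further than
#' `trim_factor` times the current RMSD.
#'
#' @param a,b `dd_structure` objects (mobile `a` fitted onto reference `b`).
#' @param chains_a,chains_b Chain identifiers to use (default: first one or
#'   two chains).
#' @param core_a,core_b Optional 0-based half-open residue intervals
#'   cropping each chain to the bundle core before pairing.
#' @param trim_cycles Number of trim cycles (0 = fit over all pairs).
#' @param trim_factor Distance cutoff in multiples of the current RMSD.
#' @return A `dd_superposition` with extra fields `assignment` and
#'   `n_trimmed`.
#' @export
superpose_structures <- function(a, b, chains_a = NULL, chains_b = NULL,
                                 core_a = NULL, core_b = NULL,
                                 trim_cycles = 0, trim_factor = 2) {
  pick <- function(s, want) {
    nm <- if (is.null(want)) names(s$chains)[seq_len(min(2, length(s$chains)))]
          else want
    lapply(s$chains[nm], identity)
  }
  ca <- lapply(pick(a, chains_a), .crop_core, core = core_a)
  cb <- lapply(pick(b, chains_b), .crop_core, core = core_b)
  paired <- pair_ca(ca, cb)
  xa <- paired$xyz_a; xb <- paired$xyz_b
  fit <- kabsch_superpose(xa, xb)
  trimmed <- 0L
  for (cyc in seq_len(trim_cycles)) {
    moved <- xa %*% fit$rotation +
      matrix(fit$translation, nrow(xa), 3, byrow = TRUE)
    dist <- sqrt(rowSums((moved - xb)^2))
    keep <- dist <= trim_factor * fit$rmsd
    if (all(keep) || sum(keep) < 3) break
    trimmed <- trimmed + sum(!keep)
    xa <- xa[keep, , drop = FALSE]
    xb <- xb[keep, , drop = FALSE]
    fit <- kabsch_superpose(xa, xb)
  }
  fit$assignment <- paired$assignment
  fit$n_trimmed <- trimmed
  fit
}
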