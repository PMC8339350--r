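# Synthetic-data generators with known ground truth: family-typical D/D
# sequences at controllable divergence, sequences evolved along a known
# tree, 1:1-model BLI data with multiplicative noise, and rigidly
# transformed point clouds. All generators are pure functions of their
# configuration and seed.

AA20 <- setdiff(AA_ALPHABET, "X")

.mutate_chars <- function(chars, mutable, p, rng_u, rng_pick) {
  # substitute mutable positions with prob p, uniform among the other 19
  hit <- mutable & rng_u < p
  if (any(hit)) {
    cur <- chars[hit]
    pick <- ceiling(rng_pick[hit] * 19)
    chars[hit] <- vapply(seq_along(cur), function(k)
      setdiff(AA20, cur[k])[pick[k]], character(1))
  }
  chars
}

#' Generate family-typical D/D sequences for a lineage
#'
#' Starts from the lineage consensus in the reference profile and mutates
#' every position independently with probability `divergence` (uniform
#' replacement among the other 19 residues). The lineage-defining motif
#' positions (loop prolines / hydrophobic Z, helix-I glycine, helix-II "YF",
#' as applicable, taken from the reference's `motif_positions`) are immune
#' to mutation, so generated sequences always carry their class motifs; a
#' leaky mode allows them to mutate with probability `motif_mut_prob`.
#'
#' @param lineage `"DPY30"`, `"R1D2"` or `"R2D2"`.
#' @param n Number of sequences (>= 0).
#' @param divergence Per-site substitution probability in `[0, 1]`.
#' @param seed Integer seed.
#' @param ref A `dd_reference` whose consensus set contains the lineage.
#' @param motif_mut_prob Mutation probability at motif positions (default 0).
#' @return A `dd_seqs` with ids `<lineage>_001`, ..., source `"synthetic"`.
#' @export
gen_family_sequences <- function(lineage, n, divergence, seed,
                                 ref = dd_reference(), motif_mut_prob = 0) {
  stopifnot(divergence >= 0, divergence <= 1, n >= 0)
  if (!lineage %in% names(ref$consensus))
    stop("unknown lineage: ", lineage)
  if (n == 0)
    return(dd_seqs(character(0), character(0), source = "synthetic"))
  cons <- strsplit(ref$consensus[[lineage]], "")[[1]]
  motif <- ref$motif_positions[[lineage]]
  protected <- seq_along(cons) %in% (motif + 1L)
  set.seed(as.integer(seed))
  res <- vapply(seq_len(n), function(i) {
    u <- stats::runif(length(cons))
    pick <- stats::runif(length(cons))
    chars <- .mutate_chars(cons, !protected, divergence, u, pick)
    if (motif_mut_prob > 0) {
      u2 <- stats::runif(length(cons))
      pick2 <- stats::runif(length(cons))
      chars <- .mutate_chars(chars, protected, motif_mut_prob, u2, pick2)
    }
    paste(chars, collapse = "")
  }, character(1))
  dd_seqs(sprintf("%s_%03d", lineage, seq_len(n)), res,
          source = "synthetic")
}

#' Evolve a root sequence along a tree
#'
#' Independent-site, 20-state Jukes-Cantor-type substitution process down
#' the tree: multiple hits per edge are allowed, replacements are uniform
#' across residues, so on an edge of length L a site shows a visible change
#' with probability `(19/20) * (1 - exp(-(20/19) * rate * L))` (about
#' `rate * L` for short edges, saturating at 19/20), the changed state
#' uniform among the other 19 residues.
#'
#' @param tree A `phylo` with non-negative branch lengths.
#' @param root_seq Non-empty residue string at the root.
#' @param rate Expected substitutions per site per unit branch length.
#' @param seed Integer seed.
#' @return Named character vector of tip sequences.
#' @export
evolve_on_tree <- function(tree, root_seq, rate, seed) {
  if (!nzchar(root_seq)) stop("empty root sequence")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  set.seed(as.integer(seed))
  tree <- ape::reorder.phylo(tree, "cladewise")
  nnode <- max(tree$edge)
  seqs <- vector("list", nnode)
  root <- tree$edge[1, 1]
  seqs[[root]] <- strsplit(root_seq, "")[[1]]
  for (e in seq_len(nrow(tree$edge))) {
    from <- tree$edge[e, 1]; to <- tree$edge[e, 2]
    p <- (19 / 20) * (1 - exp(-(20 / 19) * rate * tree$edge.length[e]))
    u <- stats::runif(length(seqs[[from]]))
    pick <- stats::runif(length(seqs[[from]]))
    seqs[[to]] <- .mutate_chars(seqs[[from]],
                                rep(TRUE, length(seqs[[from]])), p, u, pick)
  }
  ntip <- length(tree$tip.label)
  out <- vapply(seq_len(ntip), function(i)
    paste(seqs[[i]], collapse = ""), character(1))
  names(out) <- tree$tip.label
  out
}

#' Simulate 1:1-model BLI data with multiplicative noise
#'
#' Exact model values multiplied by `(1 + eps)` with
#' `eps ~ Normal(0, noise_cv)`; `noise_cv = 0` yields exact curves.
#' Steady-state mode returns one response per concentration; kinetic mode
#' returns association / dissociation traces sampled on a regular grid.
#'
#' @param Rmax Saturating response.
#' @param KD Equilibrium dissociation constant (molar). For kinetic traces
#'   give `kon` (1/M/s) and `koff` (1/s) instead (then `KD = koff / kon`).
#' @param concentrations Positive analyte concentrations (molar).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed.
#' @param type `"steady"` or `"kinetic"`.
#' @param kon,koff Kinetic rate constants (kinetic mode).
#' @param t_assoc,t_dissoc Phase durations in seconds (kinetic mode).
#' @param dt Sampling interval in seconds (kinetic mode).
#' @return Steady mode: data frame `conc`, `response` with the generating
#'   parameters in the `config` attribute. Kinetic mode: list of traces as
#'   consumed by [kinetic_fit()].
#' @export
gen_bli <- function(Rmax, KD = NULL, concentrations, noise_cv = 0, seed = 1,
                    type = c("steady", "kinetic"), kon = NULL, koff = NULL,
                    t_assoc = 300, t_dissoc = 300, dt = 1) {
  type <- match.arg(type)
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (!is.null(kon) && !is.null(koff)) {
    kd_kin <- koff / kon
    if (!is.null(KD) && abs(KD - kd_kin) > 1e-9 * max(KD, kd_kin))
      stop("KD inconsistent with koff / kon")
    KD <- kd_kin
  }
  if (is.null(KD)) stop("KD (or kon and koff) required")
  set.seed(as.integer(seed))
  cfg <- list(Rmax = Rmax, KD = KD, kon = kon, koff = koff,
              concentrations = concentrations, noise_cv = noise_cv,
              seed = seed, type = type)
  noisy <- function(x) x * (1 + stats::rnorm(length(x), 0, noise_cv))
  if (type == "steady") {
    out <- data.frame(conc = concentrations,
                      response = noisy(steady_state_response(
                        concentrations, Rmax, KD)))
    attr(out, "config") <- cfg
    return(out)
  }
  if (is.null(kon) || is.null(koff))
    stop("kinetic traces require kon and koff")
  traces <- lapply(concentrations, function(cc) {
    ta <- seq(0, t_assoc, by = dt)
    td <- seq(0, t_dissoc, by = dt)
    req <- steady_state_response(cc, Rmax, KD)
    kobs <- kon * cc + koff
    ra <- req * (1 - exp(-kobs * ta))
    r0 <- ra[length(ra)]
    rd <- r0 * exp(-koff * td)
    list(concentration = cc,
         association = data.frame(time = ta, response = noisy(ra)),
         dissociation = data.frame(time = td, response = noisy(rd)))
  })
  attr(traces, "config") <- cfg
  traces
}

#' Generate a rigidly transformed, noise-perturbed point-cloud pair
#'
#' The second cloud is a proper rotation plus translation of the first,
#' with optional isotropic Gaussian coordinate noise; the generating
#' transform is recorded for ground-truth checks.
#'
#' @param n_points Number of points (>= 4).
#' @param angle Rotation angle in radians about `axis`.
#' @param axis Length-3 rotation axis (normalised internally).
#' @param translation Length-3 translation (Angstrom).
#' @param noise_sd Isotropic per-coordinate noise SD (Angstrom).
#' @param seed Integer seed.
#' @param spread SD of the generating point cloud (Angstrom).
#' @return List `x`, `y` (n x 3 matrices), `rotation`, `translation`,
#'   `noise_sd`.
#' @export
gen_perturbed_coords <- function(n_points, angle = pi / 3,
                                 axis = c(0, 0, 1),
                                 translation = c(0, 0, 0),
                                 noise_sd = 0, seed = 1, spread = 5) {
  if (n_points < 4) stop("need at least 4 points")
  set.seed(as.integer(seed))
  x <- matrix(stats::rnorm(n_points * 3, sd = spread), n_points, 3)
  if (svd(sweep(x, 2, colMeans(x)))$d[2] < 1e-8)
    stop("degenerate (collinear) point cloud")
  a <- axis / sqrt(sum(axis^2))
  kmat <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
                 3, 3, byrow = TRUE)
  rot <- diag(3) + sin(angle) * kmat + (1 - cos(angle)) * (kmat %*% kmat)
  y <- x %*% t(rot) + matrix(translation, n_points, 3, byrow = TRUE)
  if (noise_sd > 0)
    y <- y + matrix(stats::rnorm(n_points * 3, sd = noise_sd), n_points, 3)
  list(x = x, y = y, rotation = rot, translation = translation,
       noise_sd = noise_sd)
}

#' Write sequences as FASTA with a config sidecar
#'
#' @param seqs A `dd_seqs`.
#' @param path Output FASTA path; a `<path>.json` sidecar records `config`.
#' @param config Optional list embedded in the sidecar.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path, config = NULL) {
  lines <- as.vector(rbind(paste0(">", seqs$id), seqs$residues))
  writeLines(lines, path)
  if (!is.null(config))
    jsonlite::write_json(config, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}
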