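# Diagnostic sequence features separating the DPY-30, R1D2 and R2D2
# lineages: the inter-helix loop motif (PxxP vs Pxx[ILV]), the predicted
# secondary structure of the N-flank, the glycine at the start of helix I,
# the "YF" mark in helix II, and conservation of the configured
# dimerization / docking determinant positions.

HYDROPHOBIC <- c("A", "I", "L", "M", "F", "V", "W", "Y")

#' Load a helix/strand propensity table
#'
#' Chou-Fasman-style per-residue propensities used for the transparent
#' N-flank secondary-structure call. The packaged default ships the
#' classical helix (P-alpha) and strand (P-beta) propensities.
#'
#' @param path Optional JSON path with `helix` and `strand` objects keyed by
#'   one-letter residue code; defaults to the packaged table.
#' @return A list with named numeric vectors `helix` and `strand` covering
#'   all 20 standard residues.
#' @export
propensity_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "propensity_chou_fasman.json",
                        package = "ddscan", mustWork = TRUE)
  tab <- jsonlite::read_json(path, simplifyVector = TRUE)
  tab <- list(helix = unlist(tab$helix), strand = unlist(tab$strand))
  aa <- setdiff(AA_ALPHABET, "X")
  if (!all(aa %in% names(tab$helix)) || !all(aa %in% names(tab$strand)))
    stop("propensity table must cover all 20 standard residues")
  if (any(c(tab$helix, tab$strand) <= 0))
    stop("propensities must be positive")
  tab
}

.region_interval <- function(rm, region) {
  row <- rm[rm$region == region, ]
  list(start = row$start, end = row$end, flag = row$flag)
}

.substr0 <- function(s, start, end) {
  # 0-based half-open extraction
  if (is.na(start) || is.na(end) || end <= start) return("")
  substr(s, start + 1L, end)
}

#' Classify the inter-helix loop motif
#'
#' Scans a window spanning the mapped loop plus one flanking residue on each
#' side for the pattern P-x-x-Z. The first (most N-terminal) window with a
#' leading proline and Z in `{P, I, L, V}` decides the call: `PxxP` when
#' Z = P, `PxxPhi` when Z is Ile/Leu/Val. A leading proline with any other
#' Z, or no leading proline at all, gives `other`.
#'
#' @param seq Residue string of the query (or single-row `dd_seqs`).
#' @param rm Its `dd_regionmap`.
#' @return `"PxxP"`, `"PxxPhi"` or `"other"`.
#' @export
loop_motif <- function(seq, rm) {
  res <- if (inherits(seq, "dd_seqs")) seq$residues else as.character(seq)
  lp <- .region_interval(rm, "loop")
  if (lp$flag == "absent") stop("loop unresolved: region absent")
  win <- .substr0(res, max(lp$start - 1L, 0L),
                  min(lp$end + 1L, nchar(res)))
  if (nchar(win) < 4) stop("loop unresolved: scan window shorter than 4")
  ch <- strsplit(win, "")[[1]]
  n <- length(ch)
  fallback <- FALSE
  for (i in seq_len(n - 3L)) {
    if (ch[i] != "P") next
    z <- ch[i + 3L]
    if (z == "P") return("PxxP")
    if (z %in% c("I", "L", "V")) return("PxxPhi")
    fallback <- TRUE
  }
  "other"
}

#' Secondary-structure class of the N-flank
#'
#' Averages helix and strand propensities over the mapped N-flank. The call
#' is `helix` when mean(helix) - mean(strand) exceeds `tau`, `strand` when
#' it is below `-tau`, otherwise `ambiguous`. Flanks shorter than 3 mapped
#' residues (or absent) are `ambiguous`; `X` residues are ignored.
#'
#' @param seq Residue string of the query (or single-row `dd_seqs`).
#' @param rm Its `dd_regionmap`.
#' @param table A propensity table from [propensity_table()].
#' @param tau Positive decision margin (dimensionless propensity units).
#' @return `"helix"`, `"strand"` or `"ambiguous"`.
#' @export
nflank_ss_class <- function(seq, rm, table = propensity_table(),
                            tau = 0.1) {
  stopifnot(tau > 0)
  res <- if (inherits(seq, "dd_seqs")) seq$residues else as.character(seq)
  nf <- .region_interval(rm, "nflank")
  if (nf$flag == "absent") return("ambiguous")
  ch <- strsplit(.substr0(res, nf$start, nf$end), "")[[1]]
  ch <- ch[ch != "X"]
  if (length(ch) < 3) return("ambiguous")
  diff <- mean(table$helix[ch]) - mean(table$strand[ch])
  if (diff > tau) "helix" else if (diff < -tau) "strand" else "ambiguous"
}

#' Extract the full diagnostic feature vector of a candidate
#'
#' @param seq Single-row `dd_seqs` (or residue string) of the query.
#' @param rm Its `dd_regionmap` (carrying the reference projection).
#' @param ref The `dd_reference` providing the configured dimerization and
#'   docking determinant positions (reference coordinates).
#' @param table Propensity table for the N-flank call.
#' @param tau Margin for the N-flank call.
#' @return A `dd_features` list: `loop_motif`, `nflank_ss`,
#'   `helix1_start_gly` (a G within the first two helix-I positions),
#'   `helix2_yf` (the dipeptide "YF" inside helix II),
#'   `dimer_hydrophobic_frac` (fraction of configured dimerization positions
#'   carrying a hydrophobic residue on the query; unprojected positions
#'   count as non-hydrophobic), `docking_match_count` (configured docking
#'   positions where the query equals the reference residue), and
#'   `loop_flagged` (TRUE when the loop was unresolved and the motif was
#'   reported as `other`).
#' @export
extract_features <- function(seq, rm, ref, table = propensity_table(),
                             tau = 0.1) {
  res <- if (inherits(seq, "dd_seqs")) seq$residues else as.character(seq)
  h1 <- .region_interval(rm, "helix1")
  h2 <- .region_interval(rm, "helix2")
  if (h1$flag == "absent" || h2$flag == "absent")
    stop("feature extraction requires helix1 and helix2 to be present")
  lm <- tryCatch(loop_motif(res, rm), error = function(e) NA_character_)
  flagged <- is.na(lm)
  if (flagged) lm <- "other"

  h1seq <- .substr0(res, h1$start, h1$end)
  h2seq <- .substr0(res, h2$start, h2$end)
  map <- attr(rm, "ref_to_query")
  chars <- strsplit(res, "")[[1]]
  qres_at <- function(refpos) {
    qp <- map[refpos + 1L]
    ifelse(is.na(qp), NA_character_, chars[qp + 1L])
  }
  dimer_q <- vapply(ref$dimer_positions, qres_at, character(1))
  dock_q <- vapply(ref$docking_positions, qres_at, character(1))
  refchars <- strsplit(ref$residues, "")[[1]]
  dock_ref <- refchars[ref$docking_positions + 1L]

  out <- list(
    loop_motif = lm,
    nflank_ss = nflank_ss_class(res, rm, table, tau),
    helix1_start_gly = grepl("G", substr(h1seq, 1, 2), fixed = TRUE),
    helix2_yf = grepl("YF", h2seq, fixed = TRUE),
    dimer_hydrophobic_frac =
      mean(!is.na(dimer_q) & dimer_q %in% HYDROPHOBIC),
    docking_match_count =
      sum(!is.na(dock_q) & dock_q == dock_ref),
    loop_flagged = flagged
  )
  class(out) <- "dd_features"
  out
}

#' Tabulate feature vectors as a data frame (one row per sequence)
#'
#' @param fvs Named list of `dd_features`.
#' @return A data frame suitable for TSV export.
#' @export
features_table <- function(fvs) {
  do.call(rbind, lapply(names(fvs), function(id) {
    fv <- fvs[[id]]
    data.frame(id = id, loop_motif = fv$loop_motif,
               nflank_ss = fv$nflank_ss,
               helix1_start_gly = fv$helix1_start_gly,
               helix2_yf = fv$helix2_yf,
               dimer_hydrophobic_frac = fv$dimer_hydrophobic_frac,
               docking_match_count = fv$docking_match_count,
               stringsAsFactors = FALSE)
  }))
}
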