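# Reading candidate sequences and mapping the extended D/D five-region
# architecture (N-flank, helix I, loop, helix II, C-flank) onto them.
# All coordinates are 0-based, half-open.

AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y","X")

#' Read candidate D/D sequences from a FASTA file
#'
#' Reads a multi-record (wrapped or unwrapped) protein FASTA file. Residues
#' are uppercased and a trailing `*` stop marker is stripped. Only the 20
#' standard one-letter codes plus `X` are accepted.
#'
#' @param path Path to a FASTA file.
#' @param source Provenance tag recorded for every record, one of
#'   `"user"`, `"fixture"`, `"synthetic"`.
#' @return A `dd_seqs` data frame with columns `id`, `organism`, `residues`,
#'   `source`; one row per record, input order preserved. An empty file
#'   yields zero rows.
#' @export
read_fasta <- function(path, source = c("user", "fixture", "synthetic")) {
  source <- match.arg(source)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1), 1)
  res <- toupper(as.character(set))
  res <- sub("\\*$", "", res)
  for (i in seq_along(res)) {
    bad <- which(!strsplit(res[i], "")[[1]] %in% AA_ALPHABET)
    if (length(bad) > 0)
      stop("illegal residue character in record '", ids[i],
           "' at position ", bad[1])
  }
  dd_seqs(id = ids, residues = res, source = source)
}

#' Construct a set of D/D candidate sequences
#'
#' @param id Character vector of sequence identifiers.
#' @param residues Uppercase one-letter amino-acid strings (20 standard
#'   letters plus `X`), each non-empty and at most 500 residues.
#' @param organism Optional character vector of source organisms.
#' @param source Provenance tag, recycled across records.
#' @return A `dd_seqs` data frame.
#' @export
dd_seqs <- function(id, residues, organism = NA_character_,
                    source = "user") {
  stopifnot(length(id) == length(residues))
  if (length(id) > 0) {
    if (any(!nzchar(residues))) stop("residues must be non-empty")
    if (any(nchar(residues) > 500)) stop("sequence longer than 500 residues")
    chars <- unique(unlist(strsplit(residues, "")))
    if (any(!chars %in% AA_ALPHABET))
      stop("residues outside the 20 standard letters plus 'X'")
  }
  out <- data.frame(id = as.character(id),
                    organism = rep_len(organism, length(id)),
                    residues = as.character(residues),
                    source = rep_len(source, length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("dd_seqs", "data.frame")
  out
}

#' Load the packaged extended D/D reference profile
#'
#' The reference profile carries a 77-residue family-typical extended D/D
#' sequence, the five-region architecture as 0-based half-open intervals,
#' per-class consensus sequences (DPY30, R1D2, R2D2), and the configured
#' dimerization / docking determinant positions. The packaged default is a
#' synthetic, family-typical profile (see the fixture documentation); users
#' may supply their own FASTA + JSON pair with the same layout.
#'
#' @param fasta Optional path to a FASTA file holding the reference sequence
#'   (first record) and one consensus record per class, named by class.
#' @param json Optional path to a JSON file with elements `name`, `regions`
#'   (named list of `[start, end)` pairs), `dimer_positions`,
#'   `docking_positions`, and `motif_positions` (per-class protected sites).
#' @return A `dd_reference` list.
#' @export
dd_reference <- function(fasta = NULL, json = NULL) {
  if (is.null(fasta))
    fasta <- system.file("extdata", "dd_reference_synthetic.fasta",
                         package = "ddscan", mustWork = TRUE)
  if (is.null(json))
    json <- system.file("extdata", "dd_reference_synthetic.json",
                        package = "ddscan", mustWork = TRUE)
  set <- Biostrings::readAAStringSet(fasta)
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1), 1)
  meta <- jsonlite::read_json(json, simplifyVector = TRUE)
  regions <- lapply(meta$regions, as.integer)
  .check_regions(regions, nchar(seqs[[1]]))
  ref <- list(name = meta$name,
              residues = unname(seqs[[1]]),
              regions = regions,
              consensus = seqs[-1],
              dimer_positions = as.integer(meta$dimer_positions),
              docking_positions = as.integer(meta$docking_positions),
              motif_positions = lapply(meta$motif_positions, function(x)
                as.integer(unlist(x))))
  class(ref) <- "dd_reference"
  ref
}

.check_regions <- function(regions, len) {
  need <- c("nflank", "helix1", "loop", "helix2", "cflank")
  if (!identical(names(regions), need))
    stop("regions must be exactly: ", paste(need, collapse = ", "))
  m <- do.call(rbind, regions)
  if (m[1, 1] != 0 || m[5, 2] != len ||
      any(m[-1, 1] != m[-5, 2]) || any(m[, 2] <= m[, 1]))
    stop("regions must contiguously tile [0, ", len, ")")
  if (diff(regions$helix1) < 8 || diff(regions$helix2) < 8)
    stop("helix1 and helix2 must each span at least 8 residues")
  invisible(regions)
}

# BLOSUM62 with the ambiguity code 'X' scoring 0 against everything,
# memoised per session.
.dd_env <- new.env(parent = emptyenv())

dd_submat <- function() {
  if (is.null(.dd_env$submat)) {
    mat <- get(utils::data("BLOSUM62", package = "Biostrings",
                           envir = environment()))
    mat["X", ] <- 0L
    mat[, "X"] <- 0L
    .dd_env$submat <- mat
  }
  .dd_env$submat
}

#' Global pairwise alignment of a candidate against the reference
#'
#' Needleman-Wunsch global alignment with affine gap penalties (a gap of
#' length L costs `gap_open + L * gap_extend`). The default substitution
#' matrix is BLOSUM62 with `X` scoring 0 against every residue. The
#' alignment returned for tied optima is deterministic.
#'
#' @param query A single-row `dd_seqs`, or a character string; an `id`
#'   attribute/name is carried through when present.
#' @param ref A `dd_reference`, or a plain character string to align against
#'   (e.g. one of the reference's consensus sequences).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param submat Substitution matrix; defaults to the X-neutral BLOSUM62.
#' @return A `dd_alignment` list: `query_id`, `ref_name`, `aligned_query`,
#'   `aligned_ref`, `score`, `identity` (matches over non-double-gap
#'   columns).
#' @export
align_pair <- function(query, ref, gap_open = 11, gap_extend = 1,
                       submat = dd_submat()) {
  if (inherits(query, "dd_seqs")) {
    stopifnot(nrow(query) == 1)
    qid <- query$id
    qres <- query$residues
  } else {
    qres <- as.character(query)
    qid <- if (!is.null(names(query))) names(query)[1] else "query"
  }
  if (nchar(qres) > 500) stop("query longer than 500 residues")
  if (inherits(ref, "dd_reference")) {
    rname <- ref$name
    rres <- ref$residues
  } else {
    rres <- as.character(ref)
    rname <- if (!is.null(names(ref))) names(ref)[1] else "reference"
  }
  pa <- Biostrings::pairwiseAlignment(qres, rres, type = "global",
                                      substitutionMatrix = submat,
                                      gapOpening = gap_open,
                                      gapExtension = gap_extend)
  aq <- as.character(Biostrings::alignedPattern(pa))
  ar <- as.character(Biostrings::alignedSubject(pa))
  qc <- strsplit(aq, "")[[1]]
  rc <- strsplit(ar, "")[[1]]
  comparable <- qc != "-" | rc != "-"
  out <- list(query_id = qid, ref_name = rname,
              aligned_query = aq, aligned_ref = ar,
              score = Biostrings::score(pa),
              identity = sum(qc == rc & qc != "-") / sum(comparable))
  class(out) <- "dd_alignment"
  out
}

# ref position (0-based) -> query position (0-based), NA where the
# reference residue is aligned to a gap.
.ref_to_query <- function(aln) {
  qc <- strsplit(aln$aligned_query, "")[[1]]
  rc <- strsplit(aln$aligned_ref, "")[[1]]
  map <- rep(NA_integer_, sum(rc != "-"))
  qi <- -1L
  ri <- -1L
  for (k in seq_along(qc)) {
    if (qc[k] != "-") qi <- qi + 1L
    if (rc[k] != "-") {
      ri <- ri + 1L
      if (qc[k] != "-") map[ri + 1L] <- qi
    }
  }
  map
}

#' Project the reference five-region architecture onto a query
#'
#' Each reference region interval is pushed through the alignment onto query
#' coordinates. A region whose reference positions align only to gaps is
#' flagged `absent`; one with some gapped positions is `partial`.
#'
#' @param aln A `dd_alignment` produced against the same reference.
#' @param ref The `dd_reference` used for the alignment.
#' @return A `dd_regionmap` data frame with columns `region`, `start`,
#'   `end` (0-based half-open on the query; `NA` when absent) and `flag`.
#'   The per-position reference-to-query projection is kept in the
#'   `ref_to_query` attribute.
#' @export
map_regions <- function(aln, ref) {
  stopifnot(inherits(aln, "dd_alignment"), inherits(ref, "dd_reference"))
  map <- .ref_to_query(aln)
  rows <- lapply(names(ref$regions), function(rn) {
    iv <- ref$regions[[rn]]
    qpos <- map[(iv[1] + 1L):iv[2]]   # map is 1-indexed by ref position + 1
    covered <- sum(!is.na(qpos))
    if (covered == 0L)
      data.frame(region = rn, start = NA_integer_, end = NA_integer_,
                 flag = "absent", stringsAsFactors = FALSE)
    else
      data.frame(region = rn, start = min(qpos, na.rm = TRUE),
                 end = max(qpos, na.rm = TRUE) + 1L,
                 flag = if (covered == length(qpos)) "full" else "partial",
                 stringsAsFactors = FALSE)
  })
  rm <- do.call(rbind, rows)
  if (rm$flag[rm$region == "helix1"] == "absent" &&
      rm$flag[rm$region == "helix2"] == "absent")
    stop("no D/D core: helix1 and helix2 both absent for '",
         aln$query_id, "'")
  attr(rm, "ref_to_query") <- map
  attr(rm, "query_id") <- aln$query_id
  class(rm) <- c("dd_regionmap", "data.frame")
  rm
}

#' Stack pairwise alignments into a reference-anchored alignment
#'
#' Each query is projected onto reference coordinates: column r of the
#' result holds the query residue aligned to reference position r (gap
#' where the reference position is unaligned). Query insertions relative
#' to the reference are dropped, yielding equal-length gapped sequences
#' suitable for distance computation.
#'
#' @param alns List of `dd_alignment`s against the same reference.
#' @param ref The common `dd_reference`.
#' @return Named character vector of equal-length gapped sequences.
#' @export
ref_anchored_alignment <- function(alns, ref) {
  len <- nchar(ref$residues)
  out <- vapply(alns, function(a) {
    map <- .ref_to_query(a)
    chars <- strsplit(gsub("-", "", a$aligned_query, fixed = TRUE),
                      "")[[1]]
    col <- ifelse(is.na(map), "-", chars[map + 1L])
    paste(col, collapse = "")
  }, character(1))
  names(out) <- vapply(alns, function(a) a$query_id, character(1))
  stopifnot(all(nchar(out) == len))
  out
}

#' Write region maps as a BED-like TSV
#'
#' @param maps A `dd_regionmap` or list of them.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_region_tsv <- function(maps, path) {
  if (inherits(maps, "dd_regionmap")) maps <- list(maps)
  tab <- do.call(rbind, lapply(maps, function(m) {
    data.frame(id = attr(m, "query_id"), as.data.frame(m),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
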