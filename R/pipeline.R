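# End-to-end orchestration: fasta -> regions -> features -> classification
# -> phylogeny, plus structure and binding entry points. Every run writes
# the fully resolved configuration (with seeds and package version) next to
# its results so outputs are reproducible byte for byte.

.write_resolved_config <- function(config, out_dir) {
  config$ddscan_version <- as.character(utils::packageVersion("ddscan"))
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the classification pipeline over a FASTA file
#'
#' Reads candidates, maps regions, extracts features, classifies
#' superfamily and lineage, and (for 3+ sequences) builds a bootstrapped
#' NJ tree with an optional outgroup and a per-class monophyly summary.
#'
#' @param fasta Input FASTA path.
#' @param out_dir Output directory (created if needed).
#' @param ref A `dd_reference`.
#' @param min_score,weights,delta,tau Classifier parameters (see
#'   [classify_sequences()]).
#' @param boot_reps Bootstrap replicates for the tree (0 disables supports).
#' @param seed Seed for the bootstrap resampling.
#' @param outgroup Optional character vector of outgroup ids for rooting.
#' @return Invisibly, the named vector of files written: region map TSV,
#'   feature TSV, classification TSV and JSON, Newick tree, monophyly TSV,
#'   resolved config JSON.
#' @export
run_classify <- function(fasta, out_dir, ref = dd_reference(),
                         min_score = 100,
                         weights = default_lineage_weights(), delta = 1,
                         tau = 0.1, boot_reps = 100, seed = 1,
                         outgroup = NULL) {
  seqs <- read_fasta(fasta)
  if (nrow(seqs) == 0) stop("no sequences in ", fasta)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- propensity_table()

  alns <- lapply(seq_len(nrow(seqs)), function(i) align_pair(seqs[i, ], ref))
  maps <- lapply(alns, map_regions, ref = ref)
  files <- c(regions = file.path(out_dir, "region_map.tsv"))
  write_region_tsv(maps, files[["regions"]])

  fvs <- lapply(seq_len(nrow(seqs)), function(i)
    extract_features(seqs[i, ], maps[[i]], ref, tab, tau))
  names(fvs) <- seqs$id
  files[["features"]] <- file.path(out_dir, "features.tsv")
  utils::write.table(features_table(fvs), files[["features"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  cls <- classify_sequences(seqs, ref, min_score, weights, delta, tab, tau)
  files[["classes"]] <- file.path(out_dir, "classification.tsv")
  utils::write.table(cls, files[["classes"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files[["classes_json"]] <- file.path(out_dir, "classification.json")
  jsonlite::write_json(cls, files[["classes_json"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  if (nrow(seqs) >= 3) {
    gapped <- ref_anchored_alignment(alns, ref)
    tree <- if (boot_reps > 0)
      bootstrap_supports(gapped, boot_reps, seed)
    else nj_tree(pdistance_matrix(gapped))
    if (!is.null(outgroup)) tree <- root_with_outgroup(tree, outgroup)
    files[["tree"]] <- file.path(out_dir, "tree.nwk")
    ape::write.tree(tree, files[["tree"]])
    labels <- stats::setNames(cls$lineage, cls$id)
    files[["monophyly"]] <- file.path(out_dir, "monophyly.tsv")
    mono <- check_monophyly(ape::unroot(tree), labels)
    utils::write.table(data.frame(class = names(mono),
                                  monophyletic = unname(mono)),
                       files[["monophyly"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  .write_resolved_config(list(min_score = min_score,
                              weights = as.list(weights), delta = delta,
                              tau = tau, boot_reps = boot_reps, seed = seed,
                              outgroup = outgroup, fasta = basename(fasta)),
                         out_dir)
  files[["config"]] <- file.path(out_dir, "config.json")
  invisible(files)
}

#' Run the structure comparison pipeline
#'
#' Writes the chain inventory (with sequence-derived masses) of each input
#' and, when two structures are given, a superposition report in both the
#' all-pair and iterative-trim modes.
#'
#' @param mobile Path to the mobile coordinate file (PDB/mmCIF).
#' @param reference Optional path to the reference coordinate file.
#' @param out_dir Output directory.
#' @param chains_mobile,chains_ref Chain ids used for the comparison
#'   (default: first two).
#' @param core_mobile,core_ref Optional 0-based half-open core intervals.
#' @return Invisibly, the named vector of files written.
#' @export
run_structure <- function(mobile, reference = NULL, out_dir,
                          chains_mobile = NULL, chains_ref = NULL,
                          core_mobile = NULL, core_ref = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inventory <- function(s) {
    data.frame(entry = s$entry_id, chain = names(s$chains),
               n_res = vapply(s$chains, function(ch)
                 nrow(ch$ca), integer(1)),
               mass_da = vapply(s$chains, function(ch)
                 tryCatch(chain_mass(ch$sequence),
                          error = function(e) NA_real_), numeric(1)),
               stringsAsFactors = FALSE)
  }
  a <- read_structure(mobile)
  inv <- inventory(a)
  files <- c(inventory = file.path(out_dir, "chain_inventory.tsv"))
  if (!is.null(reference)) {
    b <- read_structure(reference)
    inv <- rbind(inv, inventory(b))
    fit_all <- superpose_structures(a, b, chains_mobile, chains_ref,
                                    core_mobile, core_ref, trim_cycles = 0)
    fit_trim <- superpose_structures(a, b, chains_mobile, chains_ref,
                                     core_mobile, core_ref, trim_cycles = 5)
    rep <- list(mobile = a$entry_id, reference = b$entry_id,
                all_pairs = list(rmsd = fit_all$rmsd,
                                 n_pairs = fit_all$n_pairs,
                                 rotation = fit_all$rotation,
                                 translation = fit_all$translation),
                trimmed = list(rmsd = fit_trim$rmsd,
                               n_pairs = fit_trim$n_pairs,
                               n_trimmed = fit_trim$n_trimmed))
    files[["superposition"]] <- file.path(out_dir, "superposition.json")
    jsonlite::write_json(rep, files[["superposition"]], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  utils::write.table(inv, files[["inventory"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  .write_resolved_config(list(mobile = basename(mobile),
                              reference = if (is.null(reference)) NULL
                                          else basename(reference),
                              core_mobile = core_mobile,
                              core_ref = core_ref), out_dir)
  files[["config"]] <- file.path(out_dir, "config.json")
  invisible(files)
}

#' Run the binding-analysis pipeline on a titration CSV
#'
#' @param csv Input CSV (see [read_binding_csv()]).
#' @param out_dir Output directory.
#' @param model `"steady"` (concentration/response rows) or `"kinetic"`
#'   (time/response rows per phase and concentration).
#' @param conc_unit Concentration unit of the CSV.
#' @return Invisibly, the named vector of files written (fit report JSON
#'   with residuals, resolved config).
#' @export
run_binding <- function(csv, out_dir, model = c("steady", "kinetic"),
                        conc_unit = "M") {
  model <- match.arg(model)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dat <- read_binding_csv(csv, conc_unit)
  if (model == "steady") {
    if (length(unique(dat$concentration)) < 3)
      stop("fewer than 3 concentrations in ", csv)
    fit <- steady_state_fit(dat$concentration, dat$response)
    resid <- dat$response - steady_state_response(dat$concentration,
                                                  fit$Rmax, fit$KD)
  } else {
    need <- c("time", "phase")
    if (!all(need %in% names(dat)))
      stop("kinetic CSV must contain columns time and phase (line 1)")
    traces <- lapply(split(dat, dat$concentration), function(dd) {
      list(concentration = dd$concentration[1],
           association = dd[dd$phase == "association",
                            c("time", "response")],
           dissociation = dd[dd$phase == "dissociation",
                             c("time", "response")])
    })
    fit <- kinetic_fit(traces)
    resid <- NULL
  }
  report <- binding_fit_report(fit)
  report$residuals <- resid
  files <- c(fit = file.path(out_dir, "binding_fit.json"))
  jsonlite::write_json(report, files[["fit"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  .write_resolved_config(list(csv = basename(csv), model = model,
                              conc_unit = conc_unit), out_dir)
  files[["config"]] <- file.path(out_dir, "config.json")
  invisible(files)
}
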