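#' Assemble a pipeline configuration
#'
#' Collects every input of the end-to-end analysis: annotated sequences,
#' reference and model structures, the subunit-to-chain and native-to-model
#' chain maps, and module toggles. The configuration round-trips through
#' JSON losslessly, and all referenced paths are checked by
#' [validate_inputs()] before any compute.
#'
#' @param fasta Path to the native-subunit FASTA.
#' @param segments Path to the TM segment TSV (`id`, `start`, `end`).
#' @param reference_path Path to the reference (e.g. CryoEM) structure.
#' @param model_path Path to the predicted analog structure.
#' @param subunit_chains Named character vector: subunit ID -> reference
#'   chain ID.
#' @param chain_map Named character vector: reference chain -> model chain
#'   (`NULL` pairs identical IDs).
#' @param run_sequence,run_structures,run_sasa,run_dockq Module toggles.
#' @param outlier_rejection `NULL` or `list(cutoff =, max_cycles =)` for the
#'   superpositions.
#' @param out_dir Output directory (`NULL` = return results only).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fasta = NULL, segments = NULL,
                            reference_path = NULL, model_path = NULL,
                            subunit_chains = NULL, chain_map = NULL,
                            run_sequence = TRUE, run_structures = TRUE,
                            run_sasa = TRUE, run_dockq = TRUE,
                            outlier_rejection = NULL, out_dir = NULL) {
  structure(list(fasta = fasta, segments = segments,
                 reference_path = reference_path, model_path = model_path,
                 subunit_chains = subunit_chains, chain_map = chain_map,
                 run_sequence = run_sequence, run_structures = run_structures,
                 run_sasa = run_sasa, run_dockq = run_dockq,
                 outlier_rejection = outlier_rejection, out_dir = out_dir),
            class = "pipeline_config")
}

#' Pre-flight diagnostics for a pipeline configuration
#'
#' Checks, without heavy compute, that referenced files exist, mapped chains
#' are present in the structures, annotated sequences exist for every
#' subunit, and sequence/structure residue counts agree.
#'
#' @param config A `pipeline_config`.
#' @return Character vector of diagnostics (empty when clean).
#' @export
validate_inputs <- function(config) {
  diag <- character(0)
  say <- function(...) diag <<- c(diag, sprintf(...))
  for (f in c("fasta", "segments", "reference_path", "model_path")) {
    p <- config[[f]]
    if (!is.null(p) && !file.exists(p)) say("missing file (%s): %s", f, p)
  }
  recs <- NULL
  if (!is.null(config$fasta) && file.exists(config$fasta)) {
    recs <- read_protein_records(config$fasta, config$segments)
    for (r in recs)
      if (nrow(r$tm_segments) == 0L) say("sequence '%s' has no TM annotation", r$id)
  }
  ref <- mod <- NULL
  if (!is.null(config$reference_path) && file.exists(config$reference_path))
    ref <- suppressWarnings(read_structure(config$reference_path,
                                           source = "cryoem_reference"))
  if (!is.null(config$model_path) && file.exists(config$model_path))
    mod <- suppressWarnings(read_structure(config$model_path))
  if (!is.null(ref) && !is.null(config$subunit_chains)) {
    absent <- setdiff(unname(config$subunit_chains), chain_ids(ref))
    for (ch in absent) say("mapped chain '%s' absent from reference", ch)
    if (!is.null(recs)) {
      for (su in names(config$subunit_chains)) {
        ch <- config$subunit_chains[[su]]
        if (!su %in% names(recs)) { say("no sequence for subunit '%s'", su); next }
        if (!ch %in% chain_ids(ref)) next
        n_seq <- nchar(recs[[su]]$sequence)
        n_str <- nrow(chain_residues(ref, ch))
        if (n_str > n_seq)
          say("subunit '%s': structure chain %s has %d residues but sequence %d",
              su, ch, n_str, n_seq)
      }
    }
  }
  if (!is.null(mod) && !is.null(config$chain_map)) {
    absent <- setdiff(unname(config$chain_map), chain_ids(mod))
    for (ch in absent) say("mapped chain '%s' absent from model", ch)
  }
  diag
}

#' Run the full solubilization analysis
#'
#' Orchestrates the per-subunit QTY conversion and characteristics table,
#' the loop-trimmed per-subunit C-alpha superpositions, the hydrophobic
#' surface fractions of reference vs model, and the per-interface DockQ
#' report of the complex. Stages toggled off, or whose inputs are missing,
#' are skipped; a failing stage is recorded in `$failures` and the remaining
#' independent stages still run. Results are deterministic for fixed inputs
#' and carry input MD5 hashes as provenance.
#'
#' @param config A `pipeline_config`.
#' @return A `study_report` list: `characteristics` (per-subunit table with
#'   an `rmsd` column when structures ran), `superpositions`
#'   ([rmsd_report()] output), `hydrophobicity` (reference/model TM-restricted
#'   hydrophobic fractions), `dockq` ([score_complex()] report), `failures`,
#'   `provenance`. When `config$out_dir` is set, TSV/JSON files are also
#'   written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(characteristics = NULL, superpositions = NULL,
                 hydrophobicity = NULL, dockq = NULL,
                 failures = character(0), provenance = NULL)
  fail <- function(stage, e) {
    report$failures <<- c(report$failures,
                          sprintf("%s: %s", stage, conditionMessage(e)))
  }
  paths <- Filter(Negate(is.null),
                  config[c("fasta", "segments", "reference_path", "model_path")])
  report$provenance <- list(
    inputs = vapply(paths, function(p) unname(tools::md5sum(p)), character(1)),
    r_version = as.character(getRversion()))

  recs <- qty <- NULL
  if (config$run_sequence && !is.null(config$fasta)) {
    tryCatch({
      recs <- read_protein_records(config$fasta, config$segments)
      qty <- lapply(recs, apply_qty_code)
      report$characteristics <- characteristics_table(qty)
    }, error = function(e) fail("sequence", e))
  }

  ref <- mod <- NULL
  if ((config$run_structures || config$run_sasa || config$run_dockq) &&
      !is.null(config$reference_path) && !is.null(config$model_path)) {
    tryCatch({
      ref <- suppressWarnings(read_structure(config$reference_path,
                                             source = "cryoem_reference"))
      mod <- suppressWarnings(read_structure(config$model_path))
    }, error = function(e) fail("structure_io", e))
  }

  if (config$run_structures && !is.null(ref) && !is.null(mod)) {
    tryCatch({
      sup <- list()
      su_ch <- config$subunit_chains
      if (is.null(su_ch)) {
        common <- intersect(chain_ids(ref), chain_ids(mod))
        su_ch <- setNames(common, common)
      }
      for (su in names(su_ch)) {
        ch_ref <- su_ch[[su]]
        ch_mod <- if (is.null(config$chain_map)) ch_ref else
          config$chain_map[[ch_ref]]
        corr <- build_correspondence(ref, mod, setNames(ch_mod, ch_ref))
        sup[[su]] <- kabsch_superpose(corr, ref, mod,
                                      outlier_rejection = config$outlier_rejection)
      }
      report$superpositions <- rmsd_report(sup)
      if (!is.null(report$characteristics)) {
        i <- match(report$characteristics$id, report$superpositions$table$subunit)
        report$characteristics$rmsd <- report$superpositions$table$rmsd[i]
      }
    }, error = function(e) fail("superposition", e))
  }

  if (config$run_sasa && !is.null(ref) && !is.null(mod)) {
    tryCatch({
      tm_res <- NULL
      if (!is.null(recs) && !is.null(config$subunit_chains)) {
        tm_res <- do.call(rbind, lapply(names(config$subunit_chains), function(su) {
          if (!su %in% names(recs)) return(NULL)
          m <- which(tm_mask(recs[[su]]))
          if (!length(m)) return(NULL)
          data.frame(chain = config$subunit_chains[[su]], resno = m)
        }))
      }
      frac <- function(model, tm) {
        rep <- shrake_rupley_sasa(model)
        hydrophobic_fraction(rep, tm_residues = tm)
      }
      tm_mod <- if (is.null(tm_res) || is.null(config$chain_map)) tm_res else
        data.frame(chain = unname(config$chain_map[tm_res$chain]),
                   resno = tm_res$resno)
      report$hydrophobicity <- list(reference = frac(ref, tm_res),
                                    model = frac(mod, tm_mod))
    }, error = function(e) fail("hydrophobicity", e))
  }

  if (config$run_dockq && !is.null(ref) && !is.null(mod)) {
    tryCatch({
      report$dockq <- score_complex(ref, mod, config$chain_map)
    }, error = function(e) fail("dockq", e))
  }

  class(report) <- "study_report"
  if (!is.null(config$out_dir)) write_study_report(report, config$out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  if (!is.null(x$characteristics))
    cat(sprintf("  characteristics: %d subunit(s)\n", nrow(x$characteristics)))
  if (!is.null(x$superpositions))
    cat(sprintf("  superpositions: RMSD %.3f-%.3f A (median %.3f)\n",
                x$superpositions$summary["min"], x$superpositions$summary["max"],
                x$superpositions$summary["median"]))
  if (!is.null(x$hydrophobicity))
    cat(sprintf("  hydrophobic fraction (TM): reference %.3f -> model %.3f\n",
                x$hydrophobicity$reference$fraction,
                x$hydrophobicity$model$fraction))
  if (!is.null(x$dockq))
    cat(sprintf("  DockQ: overall %.3f over %d interface(s)\n",
                x$dockq$overall_dockq, x$dockq$n_interfaces))
  if (length(x$failures)) cat("  failures:", paste(x$failures, collapse = "; "), "\n")
  invisible(x)
}

# write the report's tables as TSV and the summary as JSON
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$characteristics))
    write.table(report$characteristics,
                file.path(out_dir, "characteristics.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(report$superpositions))
    write.table(report$superpositions$table, file.path(out_dir, "rmsd.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(report$dockq) && !is.null(report$dockq$per_interface))
    write.table(report$dockq$per_interface, file.path(out_dir, "dockq.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  summary <- list(
    rmsd = if (!is.null(report$superpositions)) as.list(report$superpositions$summary),
    dockq = if (!is.null(report$dockq))
      list(overall = report$dockq$overall_dockq,
           medians = as.list(report$dockq$medians),
           n_interfaces = report$dockq$n_interfaces),
    hydrophobicity = report$hydrophobicity,
    failures = report$failures,
    provenance = report$provenance)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
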