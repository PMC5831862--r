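# End-to-end orchestration: simulate? -> qc -> classify -> families ->
# evolve; expression; targets. Configs are JSON (per-module parameter
# blocks); every stage writes machine-readable outputs into the run
# directory and a manifest records seeds and md5 hashes.

#' Validate and normalize a pipeline configuration
#'
#' Accepts a JSON file path or a list. Top-level keys: `seed`,
#' `simulate` (logical), `tree` (newick path; optional, defaults to the
#' bundled topology), `focal_species`, `qc`, `families`, `expression`,
#' `targets` parameter blocks, and (when `simulate` is false) an
#' `inputs` block of file paths. Unknown keys are rejected; referenced
#' files must exist.
#'
#' @param config list or path to a JSON file.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  known <- c("seed", "simulate", "tree", "focal_species", "qc",
             "families", "expression", "targets", "simulation", "inputs")
  bad <- setdiff(names(config), known)
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  }
  if (is.null(config$seed)) config$seed <- 1L
  config$seed <- as.integer(config$seed)
  if (is.null(config$simulate)) config$simulate <- TRUE
  if (is.null(config$focal_species)) config$focal_species <- "Csavignyi"
  if (!is.null(config$tree) && !file.exists(config$tree)) {
    stop("tree file not found: ", config$tree)
  }
  for (f in unlist(config$inputs)) {
    if (!file.exists(f)) stop("input file not found: ", f)
  }
  class(config) <- c("pipeline_config", "list")
  config
}

#' Demo configuration for a fast synthetic end-to-end run
#'
#' @param seed RNG seed.
#' @return a [pipeline_config()] with small simulation sizes.
#' @export
demo_config <- function(seed = 1L) {
  pipeline_config(list(
    seed = as.integer(seed), simulate = TRUE,
    simulation = list(n_reads = 2000L, n_families = 40L,
                      n_mirnas = 20L)))
}

#' Run the pipeline end to end
#'
#' Runs the stages in dependency order, writing per-stage outputs and a
#' `manifest.json` (package version, seed, per-file md5 hashes) into
#' `out_dir`. A failing stage aborts with the stage named; outputs of
#' completed stages are retained. Reruns with the same config are
#' byte-identical for the deterministic stages.
#'
#' @param config a [pipeline_config()], list, or JSON path.
#' @param out_dir run directory (created if needed).
#' @return list of per-stage results, invisibly; `manifest` element
#'   included.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  tree <- if (!is.null(config$tree)) ape::read.tree(config$tree)
          else default_species_tree()
  sim_args <- c(list(seed = config$seed, tree = tree),
                config$simulation)
  cfg <- do.call(simulation_config, sim_args)
  if (!isTRUE(config$simulate)) {
    stop("non-simulated inputs: run the per-stage commands with your ",
         "own files (see mirmeta_cli); run_pipeline drives the ",
         "simulated demo")
  }

  results$simulate <- stage("simulate", function() {
    sim_dir <- file.path(out_dir, "simulate")
    reads <- gen_reads(cfg, out_dir = sim_dir)
    hist <- gen_family_history(tree, cfg)
    seqs <- gen_family_sequences(hist$matrix, cfg)
    expr <- gen_expression(cfg, out_dir = sim_dir)
    preds <- gen_prediction_tables(cfg, out_dir = sim_dir)
    fa <- setNames(as_dna(seqs$sequence),
                   paste(seqs$id, seqs$species, sep = "|"))
    write_fasta(fa, file.path(sim_dir, "mirna_catalog.fa"))
    ape::write.tree(tree, file.path(sim_dir, "species_tree.nwk"))
    list(reads = reads, history = hist, sequences = seqs, expr = expr,
         preds = preds)
  })
  sim <- results$simulate

  results$qc <- stage("qc", function() {
    qp <- do.call(qc_params, as.list(config$qc))
    qc <- filter_reads(sim$reads$reads, adapter_3p = cfg$adapter_3p,
                       adapter_5p = cfg$adapter_5p, params = qp)
    jsonlite::write_json(qc$report, file.path(out_dir, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA)
    write_fasta(setNames(qc$clean$seq, qc$clean$id),
                file.path(out_dir, "clean_reads.fa"))
    qc
  })

  results$classify <- stage("classify", function() {
    idx <- annotation_index(sim$reads$references)
    cls <- classify_reads(results$qc$clean, idx)
    book <- remove_annotated(cls$labels)
    jsonlite::write_json(
      list(counts = cls$report$counts, mapped = book$mapped,
           removed = book$removed, remaining = book$remaining,
           candidates = length(book$candidates)),
      file.path(out_dir, "classification.json"),
      auto_unbox = TRUE, digits = NA)
    write.table(data.frame(id = results$qc$clean$id, label = cls$labels),
                file.path(out_dir, "read_labels.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(classification = cls, bookkeeping = book)
  })

  results$families <- stage("families", function() {
    fp <- do.call(family_params, as.list(config$families))
    mir <- data.frame(id = sim$sequences$id,
                      species = sim$sequences$species,
                      sequence = sim$sequences$sequence,
                      stringsAsFactors = FALSE)
    part <- build_families(mir, fp)
    mat <- presence_absence(part, tree$tip.label)
    write.table(data.frame(family = names(part$membership)[
                             match(mir$id, names(part$membership))],
                           mirna = mir$id),
                file.path(out_dir, "family_members.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(family = rownames(mat), mat,
                           check.names = FALSE),
                file.path(out_dir, "presence_absence.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(partition = part, matrix = mat)
  })

  results$evolve <- stage("evolve", function() {
    rec <- dollo_reconstruct(results$families$matrix, tree)
    acq <- assign_acquisition(rec)
    summ <- node_summary(rec, focal_species =
                           if (config$focal_species %in% tree$tip.label)
                             config$focal_species else NULL)
    write.table(acq, file.path(out_dir, "acquisitions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(summ, file.path(out_dir, "node_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(reconstruction = rec, acquisitions = acq, summary = summ)
  })

  results$expression <- stage("expression", function() {
    ref_stage <- config$expression$reference_stage %||% cfg$stages[1]
    alpha <- config$expression$alpha %||% 0.01
    res <- ddct(sim$expr$ct, reference_stage = ref_stage)
    tests <- stage_test(res, alpha = alpha)
    write.table(merge(res$summary, tests, by = "mirna"),
                file.path(out_dir, "expression_results.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(ddct = res, tests = tests)
  })

  results$targets <- stage("targets", function() {
    max_r <- config$targets$max_r %||% 0
    edges <- integrate_targets(sim$preds$table_a, sim$preds$table_b,
                               sim$preds$mirna_profiles,
                               sim$preds$gene_profiles, max_r = max_r)
    export_network(edges, file.path(out_dir, "network_edges.tsv"))
    enr <- enrich(unique(edges$gene), sim$preds$gene_sets,
                  sim$preds$universe)
    write.table(enr, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(edges = edges, enrichment = enr)
  })

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  manifest <- list(
    package = as.character(packageVersion("mirmeta")),
    seed = config$seed,
    files = as.list(setNames(unname(md5sum(files)),
                             sub(paste0("^", out_dir, "/?"), "", files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' `mirmeta run --config cfg.json --out DIR [--seed N]` runs the full
#' pipeline; `mirmeta demo --out DIR [--seed N]` runs the bundled
#' synthetic demo. Install the launcher from
#' `system.file("cli", "mirmeta.R", package = "mirmeta")`.
#'
#' @param args character vector (default: command-line arguments).
#' @return exit status, invisibly (0 on success).
#' @export
mirmeta_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: mirmeta <run|demo> --out DIR [--config cfg.json] [--seed N]"
  if (length(args) < 1L) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- args[[1]]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--out", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL)))
  opt <- optparse::parse_args(parser, args = args[-1])
  status <- tryCatch({
    if (is.null(opt$out)) stop(usage)
    config <- switch(cmd,
      demo = demo_config(seed = opt$seed %||% 1L),
      run = {
        if (is.null(opt$config)) stop("run requires --config")
        cf <- pipeline_config(opt$config)
        if (!is.null(opt$seed)) cf$seed <- opt$seed
        cf
      },
      stop("unknown command: ", cmd, "\n", usage))
    run_pipeline(config, opt$out)
    message("pipeline complete: ", opt$out)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
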