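#' @importFrom yaml read_yaml
NULL

pipelineDefaults <- function() {
  list(
    genomes = character(0),        # GenBank file paths
    alignment = NULL,              # aligned FASTA path
    reference_taxon = NULL,        # row label used by annotateRegions
    stages = c("summary", "codon", "repeats", "junctions", "diversity",
               "kaks"),
    out_dir = "plastomics_out",
    seed = 1L,
    window = 600L, step = 200L,
    pi_quantile = 0.95, snp_min = 25L,
    ssr_thresholds = c(10L, 6L, 5L, 4L, 3L, 3L),
    min_repeat_len = 30L, max_repeats_reported = 5000L,
    min_ir_len = 1000L,
    genetic_code = "11")
}

checkers <- list(
  genomes = function(v) is.character(v),
  alignment = function(v) is.null(v) || (is.character(v) && length(v) == 1),
  reference_taxon = function(v) is.null(v) ||
    (is.character(v) && length(v) == 1),
  stages = function(v) is.character(v) &&
    all(v %in% c("summary", "codon", "repeats", "junctions", "diversity",
                 "kaks")),
  out_dir = function(v) is.character(v) && length(v) == 1,
  seed = function(v) is.numeric(v) && length(v) == 1,
  window = function(v) is.numeric(v) && length(v) == 1 && v >= 1,
  step = function(v) is.numeric(v) && length(v) == 1 && v >= 1,
  pi_quantile = function(v) is.numeric(v) && length(v) == 1 &&
    v > 0 && v < 1,
  snp_min = function(v) is.numeric(v) && length(v) == 1 && v >= 0,
  ssr_thresholds = function(v) is.numeric(v) && length(v) == 6 &&
    all(v >= 1),
  min_repeat_len = function(v) is.numeric(v) && length(v) == 1 && v >= 8,
  max_repeats_reported = function(v) is.numeric(v) && length(v) == 1 &&
    v >= 1,
  min_ir_len = function(v) is.numeric(v) && length(v) == 1 && v >= 1,
  genetic_code = function(v) is.character(v) && length(v) == 1)

#' Validate a pipeline configuration
#'
#' Fills defaults (the standard comparative-plastome settings: 600/200 bp
#' sliding window, top-5\% Pi with SNP > 25, MISA thresholds 10/6/5/4/3/3,
#' 30 bp minimum long-repeat size, 1000 bp minimum IR, genetic code 11),
#' rejects unknown keys and out-of-range values, and reports every problem
#' at once.
#'
#' @param config path to a YAML config file, or a named list.
#' @return a validated config list of class \code{PipelineConfig}.
#' @export
validateConfig <- function(config = list()) {
  if (is.character(config)) config <- read_yaml(config)
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))
  defaults <- pipelineDefaults()
  problems <- character(0)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    problems <- c(problems, paste0("unknown key(s): ",
                                   paste(unknown, collapse = ", ")))
  merged <- defaults
  for (k in intersect(names(config), names(defaults))) {
    v <- config[[k]]
    if (!checkers[[k]](v))
      problems <- c(problems, paste0("invalid value for '", k, "'"))
    else merged[[k]] <- v
  }
  if (merged$window < merged$step)
    problems <- c(problems,
                  "'window' must be >= 'step' (sliding-window settings)")
  if (length(problems))
    stop("configuration errors:\n  - ",
         paste(problems, collapse = "\n  - "))
  for (k in c("seed", "window", "step", "snp_min", "min_repeat_len",
              "max_repeats_reported", "min_ir_len"))
    merged[[k]] <- as.integer(merged[[k]])
  merged$ssr_thresholds <- as.integer(merged$ssr_thresholds)
  class(merged) <- "PipelineConfig"
  merged
}

tsvHeader <- function(con, params) {
  writeLines(paste0("# plastomics ",
                    as.character(utils::packageVersion("plastomics"))), con)
  for (k in names(params))
    writeLines(paste0("# ", k, "=", paste(params[[k]], collapse = ",")), con)
}

writeStageTable <- function(df, path, params) {
  con <- file(path, "w")
  tsvHeader(con, params)
  close(con)
  suppressWarnings(
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                append = TRUE))
  invisible(path)
}

#' Run the comparative-plastome pipeline
#'
#' Executes the requested stages in dependency order: each genome is read,
#' its quadripartite structure detected and canonicalized, then the
#' per-genome stages (summary, codon usage, repeats, junctions) and the
#' cross-genome stages (diversity from the alignment; Ka/Ks from the
#' genome cohort) run.  Per-stage failures are caught, logged and
#' summarized; a missing prerequisite aborts only its dependents.  Every
#' output TSV carries a metadata header with the package version and the
#' stage parameters.
#'
#' @param config a \code{PipelineConfig} from [validateConfig()], a config
#'   file path, or a list.
#' @return (invisibly) a list with per-stage results, the output file
#'   paths, and \code{errors} (named character vector of stage failures;
#'   empty on full success).
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "PipelineConfig")) config <- validateConfig(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  errors <- character(0)
  results <- list(files = character(0))
  logmsg <- function(...) message("[plastomics] ", ...)
  runStage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      logmsg("stage '", name, "' failed: ", conditionMessage(e))
      NULL
    })
  }
  emit <- function(df, fname, params) {
    path <- file.path(config$out_dir, fname)
    writeStageTable(df, path, params)
    results$files <<- c(results$files, path)
    path
  }

  genomes <- list()
  for (p in config$genomes) {
    g <- runStage(paste0("read:", p), {
      if (grepl("\\.(fa|fasta|fna)$", p, ignore.case = TRUE))
        readPlastomeFasta(p) else readGenBank(p)
    })
    if (!is.null(g)) genomes[[plastomeId(g)]] <- g
  }

  canon <- list()
  for (id in names(genomes)) {
    part <- runStage(paste0("partition:", id),
                     detectQuadripartite(genomes[[id]], config$min_ir_len))
    if (is.null(part)) {
      logmsg("no quadripartite structure in ", id)
      next
    }
    canon[[id]] <- canonicalizePlastome(genomes[[id]], part)
  }

  if ("summary" %in% config$stages && length(canon)) {
    sums <- runStage("summary", lapply(canon, function(cg)
      summarizeGenome(cg$genome, cg$partition)))
    if (!is.null(sums)) {
      results$summaries <- sums
      path <- file.path(config$out_dir, "genome_summary.tsv")
      writeGenomeSummary(unname(sums), path)
      results$files <- c(results$files, path)
    }
  }

  if ("codon" %in% config$stages && length(canon)) {
    res <- runStage("codon", {
      tabs <- lapply(canon, function(cg) {
        cds <- suppressMessages(extractCDS(cg$genome,
                                           genetic_code = config$genetic_code))
        computeRSCU(countCodons(cds, config$genetic_code))
      })
      bias <- rscuBiasSummary(tabs)
      writeRSCUMatrix(tabs, file.path(config$out_dir, "rscu_matrix.tsv"))
      list(rscu = tabs, bias = bias)
    })
    if (!is.null(res)) {
      results$codon <- res
      results$files <- c(results$files,
                         file.path(config$out_dir, "rscu_matrix.tsv"))
    }
  }

  if ("repeats" %in% config$stages && length(canon)) {
    res <- runStage("repeats", {
      out <- lapply(names(canon), function(id) {
        cg <- canon[[id]]
        ssr <- findSSRs(cg$genome, config$ssr_thresholds)
        if (nrow(ssr))
          ssr <- cbind(genome = id, ssr,
                       classifyRepeatLocation(ssr$start, ssr$end,
                                              cg$genome, cg$partition))
        lr <- findLongRepeats(cg$genome, config$min_repeat_len,
                              config$max_repeats_reported,
                              partition = cg$partition)
        if (nrow(lr)) lr <- cbind(genome = id, lr)
        list(ssr = ssr, lr = lr)
      })
      names(out) <- names(canon)
      ssr_all <- do.call(rbind, lapply(out, function(x)
        if (nrow(x$ssr)) x$ssr else NULL))
      lr_all <- do.call(rbind, lapply(out, function(x)
        if (nrow(x$lr)) x$lr else NULL))
      params <- list(ssr_thresholds = config$ssr_thresholds,
                     min_repeat_len = config$min_repeat_len)
      if (!is.null(ssr_all)) emit(ssr_all, "ssrs.tsv", params)
      if (!is.null(lr_all)) emit(lr_all, "long_repeats.tsv", params)
      out
    })
    if (!is.null(res)) results$repeats <- res
  }

  if ("junctions" %in% config$stages && length(canon)) {
    res <- runStage("junctions", {
      reps <- lapply(canon, function(cg)
        junctionReport(cg$genome, cg$partition))
      emit(do.call(rbind, unname(reps)), "junctions.tsv", list())
      reps
    })
    if (!is.null(res)) results$junctions <- res
  }

  if ("diversity" %in% config$stages) {
    if (is.null(config$alignment)) {
      if ("diversity" %in% config$stages && length(config$genomes))
        logmsg("diversity stage skipped: no alignment supplied")
    } else {
      res <- runStage("diversity", {
        aln <- readAlignment(config$alignment)
        win <- windowScan(aln, config$window, config$step)
        reg <- mergeHypervariable(win, aln, config$pi_quantile,
                                  config$snp_min)
        ref <- config$reference_taxon
        if (!is.null(ref) && ref %in% rownames(aln) &&
            ref %in% names(canon))
          reg <- annotateRegions(reg, canon[[ref]]$genome, aln, ref)
        params <- list(window = config$window, step = config$step,
                       pi_quantile = config$pi_quantile,
                       snp_min = config$snp_min)
        emit(win, "windows.tsv", params)
        emit(reg, "hypervariable_regions.tsv", params)
        list(windows = win, regions = reg)
      })
      if (!is.null(res)) results$diversity <- res
    }
  }

  if ("kaks" %in% config$stages && length(genomes) >= 2) {
    res <- runStage("kaks", {
      shared <- sharedPCGs(unname(genomes), config$genetic_code)
      recs <- kaksPairwise(shared, config$genetic_code)
      mat <- omegaMatrix(recs)
      params <- list(genetic_code = config$genetic_code,
                     estimator = "NG86")
      emit(recs, "kaks_pairwise.tsv", params)
      writeKaKs(mat, file.path(config$out_dir, "omega_matrix.tsv"))
      list(shared = shared, records = recs, omega = mat)
    })
    if (!is.null(res)) results$kaks <- res
  }

  results$errors <- errors
  if (length(errors)) logmsg(length(errors), " stage(s) failed")
  invisible(results)
}
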