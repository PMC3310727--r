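#' Default pipeline run configuration
#'
#' A nested list describing a full run: either a `simulation` block (the
#' synthetic generator's parameters, see [sim_config()]) or an `inputs`
#' block of file paths, plus per-stage parameters. Presets default to the
#' published caller values; all randomness flows from the single `seed`
#' via per-stage derived seeds.
#'
#' @param seed master seed for the run.
#' @param outdir output directory for stage artifacts.
#' @return A `run_config` list (already validated).
#' @export
default_run_config <- function(seed = 1, outdir = "polytile_run") {
  cfg <- list(
    seed = as.integer(seed),
    outdir = outdir,
    simulation = list(),
    inputs = NULL,
    caller = list(emf1 = list(preset = "emf1"),
                  k27 = list(preset = "k27")),
    annotation = list(upstream = 200),
    metagene = list(anchor = "TSS", flank = 3000, bin = 100),
    classification = list(mode = "peak_loss", delta = 0.5,
                          repressor_mutant = "emf1"),
    expression = list(sd_multiple = 1.5),
    enrichment = list(annotation_path = NULL,
                      small_category_threshold = 5)
  )
  validate_config(cfg)
}

#' Validate a pipeline run configuration
#'
#' Accepts a config list or the path of a YAML file, fills in defaults and
#' checks every invariant, reporting all violations at once rather than
#' failing on the first.
#'
#' @param x a config list or a YAML file path.
#' @param action `"error"` (default): stop listing all problems, or return
#'   the completed `run_config`; `"list"`: return the character vector of
#'   problems (empty when valid).
#' @return A validated `run_config`, or a character vector of problems
#'   when `action = "list"`.
#' @export
validate_config <- function(x, action = c("error", "list")) {
  action <- match.arg(action)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("config file not found: ", x)
    x <- yaml::read_yaml(x)
  }
  stopifnot(is.list(x))
  base <- list(
    seed = 1L, outdir = "polytile_run", simulation = NULL, inputs = NULL,
    caller = list(emf1 = list(preset = "emf1"),
                  k27 = list(preset = "k27")),
    annotation = list(upstream = 200),
    metagene = list(anchor = "TSS", flank = 3000, bin = 100),
    classification = list(mode = "peak_loss", delta = 0.5,
                          repressor_mutant = "emf1"),
    expression = list(sd_multiple = 1.5),
    enrichment = list(annotation_path = NULL,
                      small_category_threshold = 5)
  )
  cfg <- utils::modifyList(base, x, keep.null = TRUE)
  errs <- character()
  say <- function(...) errs <<- c(errs, paste0(...))

  has_sim <- !is.null(cfg$simulation)
  has_inp <- !is.null(cfg$inputs)
  if (has_sim == has_inp) {
    say("exactly one of 'simulation' or 'inputs' must be set (found ",
        sum(c(has_sim, has_inp)), ")")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L) {
    say("seed must be a single integer")
  }
  if (!is.null(cfg$annotation$upstream) &&
      (!is.numeric(cfg$annotation$upstream) || cfg$annotation$upstream < 0)) {
    say("annotation$upstream must be a non-negative number")
  }
  mg <- cfg$metagene
  if (!is.numeric(mg$flank) || mg$flank <= 0) say("metagene$flank must be > 0")
  if (!is.numeric(mg$bin) || mg$bin <= 0) {
    say("metagene$bin must be > 0")
  } else if (is.numeric(mg$flank) && mg$flank > 0 &&
             (2 * mg$flank) %% mg$bin != 0) {
    say("2*metagene$flank must be a multiple of metagene$bin")
  }
  if (!mg$anchor %in% c("TSS", "TES")) say("metagene$anchor must be TSS or TES")
  if (!cfg$classification$mode %in% c("peak_loss", "signal_drop")) {
    say("classification$mode must be peak_loss or signal_drop")
  }
  if (!is.numeric(cfg$expression$sd_multiple) ||
      cfg$expression$sd_multiple <= 0) {
    say("expression$sd_multiple must be > 0")
  }
  for (nm in names(cfg$caller)) {
    ok <- tryCatch({
      do.call(caller_params, cfg$caller[[nm]])
      TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) say("caller$", nm, ": ", ok)
  }
  if (has_sim) {
    ok <- tryCatch({
      do.call(sim_config, cfg$simulation)
      TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) say("simulation: ", ok)
  }
  if (has_inp) {
    for (nm in c("genes", "emf1", "k27_wt")) {
      if (is.null(cfg$inputs[[nm]])) say("inputs$", nm, " is required")
    }
  }
  if (action == "list") return(errs)
  if (length(errs)) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  }
  class(cfg) <- "run_config"
  cfg
}

# ---- pipeline ------------------------------------------------------------

load_pipeline_data <- function(cfg) {
  if (!is.null(cfg$simulation)) {
    sim_args <- cfg$simulation
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    scfg <- do.call(sim_config, sim_args)
    genome <- simulate_genome(scfg)
    chip <- simulate_chip_tracks(genome, scfg)
    expr <- simulate_expression(genome, scfg)
    mutants <- names(scfg$mutant_loss)
    list(genes = genome$genes, chrom_sizes = genome$chrom_sizes,
         emf1_track = chip$tracks$emf1,
         k27_tracks = c(list(WT = chip$tracks$k27_WT),
                        stats::setNames(
                          lapply(mutants, function(m)
                            chip$tracks[[paste0("k27_", m)]]), mutants)),
         expr_tracks = expr$tracks,
         truth = merge(chip$truth, expr$truth, by = "gene_id", sort = FALSE),
         mutants = mutants, sim_config = scfg)
  } else {
    inp <- cfg$inputs
    genes <- read_gene_models(inp$genes)
    k27_mut <- lapply(inp$k27_mutants %||% list(), read_track)
    expr <- lapply(inp$expression %||% list(), read_track)
    list(genes = genes, chrom_sizes = NULL,
         emf1_track = read_track(inp$emf1),
         k27_tracks = c(list(WT = read_track(inp$k27_wt)), k27_mut),
         expr_tracks = expr, truth = NULL,
         mutants = names(k27_mut), sim_config = NULL)
  }
}

#' Run the full tiling-array analysis pipeline
#'
#' Executes, in dependency order: data simulation (or ingest), peak
#' calling for the binding and K27 tracks, peak-to-gene assignment and
#' chromosomal densities, the TSS-aligned metagene matrix with High/Low
#' k-means clustering, co-occupancy classification (Group I/II), per-gene
#' transcription scores with differential calls per mutant, and (when an
#' annotation map is configured) category enrichment for the EMF1_K27
#' set. Every stage writes its artifacts under `outdir`; identical config
#' and seed reproduce identical artifacts. On a stage failure, completed
#' outputs and a report marking the failed stage are left behind and the
#' error is propagated.
#'
#' @param config a `run_config` (see [validate_config()]), a plain list,
#'   or a YAML file path.
#' @param outdir overrides `config$outdir` when given.
#' @return The run report, invisibly: per-stage parameters, headline
#'   counts and timings (`report.json` on disk carries everything except
#'   the wall-clock, which varies between runs).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  outdir <- outdir %||% cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  report <- list(seed = cfg$seed, stages = list(), failed_stage = NULL)
  env <- new.env(parent = emptyenv())

  finish <- function(report) {
    on_disk <- report
    on_disk$wall_clock <- NULL
    jsonlite::write_json(on_disk, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    report
  }
  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      report$failed_stage <<- list(stage = name,
                                   error = conditionMessage(res))
      finish(report)
      stop("stage '", name, "' failed: ", conditionMessage(res),
           call. = FALSE)
    }
    report$stages[[name]] <<- res
  }

  stage("data", function() {
    d <- load_pipeline_data(cfg)
    list2env(d, env)
    write_gene_models(env$genes, file.path(outdir, "genes.bed"))
    write_track(env$emf1_track, file.path(outdir, "emf1.bedGraph"))
    for (nm in names(env$k27_tracks)) {
      write_track(env$k27_tracks[[nm]],
                  file.path(outdir, paste0("k27_", nm, ".bedGraph")))
    }
    for (nm in names(env$expr_tracks)) {
      write_track(env$expr_tracks[[nm]],
                  file.path(outdir, paste0("expr_", nm, ".bedGraph")))
    }
    if (!is.null(env$truth)) {
      write_gene_table(env$truth, file.path(outdir, "truth.tsv"))
    }
    list(n_genes = nrow(env$genes),
         n_probes = nrow(env$emf1_track),
         mutants = env$mutants,
         simulated = !is.null(cfg$simulation))
  })

  stage("peakcall", function() {
    p_emf1 <- do.call(caller_params, cfg$caller$emf1)
    p_k27 <- do.call(caller_params, cfg$caller$k27)
    env$emf1_peaks <- call_peaks(env$emf1_track, p_emf1, env$chrom_sizes)
    write_peaks(env$emf1_peaks, file.path(outdir, "peaks_emf1.bed"))
    env$k27_peaks <- lapply(env$k27_tracks, function(trk)
      call_peaks(trk, p_k27, env$chrom_sizes))
    for (nm in names(env$k27_peaks)) {
      write_peaks(env$k27_peaks[[nm]],
                  file.path(outdir, paste0("peaks_k27_", nm, ".bed")))
    }
    counts <- c(list(emf1 = nrow(env$emf1_peaks)),
                stats::setNames(lapply(env$k27_peaks, nrow),
                                paste0("k27_", names(env$k27_peaks))))
    list(params = list(emf1 = unclass(p_emf1)[c("window_size", "step_size",
                                                "p_cutoff",
                                                "min_peak_length")],
                       k27 = unclass(p_k27)[c("window_size", "step_size",
                                              "p_cutoff",
                                              "min_peak_length")]),
         sigma = c(list(emf1 = attr(env$emf1_peaks, "sigma")),
                   stats::setNames(lapply(env$k27_peaks, attr, "sigma"),
                                   paste0("k27_", names(env$k27_peaks)))),
         n_peaks = counts,
         degenerate = names(counts)[unlist(counts) == 0])
  })

  stage("annotate", function() {
    up <- cfg$annotation$upstream
    emf1_asgn <- assign_peaks_to_genes(env$emf1_peaks, env$genes, up,
                                       env$chrom_sizes)
    env$emf1_bound <- emf1_asgn$bound_genes
    env$k27_genes <- lapply(env$k27_peaks, function(p)
      assign_peaks_to_genes(p, env$genes, up, env$chrom_sizes)$bound_genes)
    write_density(chromosomal_density(env$emf1_peaks,
                                      chrom_sizes = env$chrom_sizes),
                  file.path(outdir, "density_emf1.bedGraph"))
    write_density(chromosomal_density(env$k27_peaks$WT,
                                      chrom_sizes = env$chrom_sizes),
                  file.path(outdir, "density_k27_WT.bedGraph"))
    list(upstream = up,
         n_emf1_bound = length(env$emf1_bound),
         n_emf1_genic_peaks = nrow(emf1_asgn$genic),
         n_emf1_intergenic_peaks = nrow(emf1_asgn$intergenic),
         n_k27_genes = lapply(env$k27_genes, length))
  })

  stage("metagene", function() {
    mg <- cfg$metagene
    m_k27 <- build_metagene_matrix(env$k27_tracks$WT, env$genes,
                                   anchor = mg$anchor, flank = mg$flank,
                                   bin = mg$bin)
    m_k27 <- kmeans_high_low(m_k27, seed = stage_seed(cfg$seed, "kmeans"))
    env$metagene_k27 <- m_k27
    write_metagene_matrix(m_k27, file.path(outdir, "metagene_k27_WT.tsv"),
                          file.path(outdir, "clusters_k27_WT.tsv"))
    m_emf1 <- build_metagene_matrix(env$emf1_track, env$genes,
                                    anchor = mg$anchor, flank = mg$flank,
                                    bin = mg$bin)
    m_emf1 <- align_by_order(m_emf1, m_k27$sort_order)
    write_metagene_matrix(m_emf1, file.path(outdir, "metagene_emf1.tsv"))
    tab <- table(m_k27$cluster_labels)
    list(anchor = mg$anchor, flank = mg$flank, bin = mg$bin,
         n_high = as.integer(tab["High"] %||% 0L),
         n_low = as.integer(tab["Low"] %||% 0L))
  })

  stage("classify", function() {
    universe <- env$genes$gene_id
    k27_wt <- env$k27_genes$WT
    up <- cfg$annotation$upstream
    mode <- cfg$classification$mode
    env$reduced <- list()
    for (m in env$mutants) {
      env$reduced[[m]] <- reduced_methylation(
        env$k27_peaks$WT, env$k27_peaks[[m]], env$genes, mode = mode,
        upstream = up, chrom_sizes = env$chrom_sizes,
        wt_track = env$k27_tracks$WT, mutant_track = env$k27_tracks[[m]],
        delta = cfg$classification$delta)
    }
    rm_mut <- cfg$classification$repressor_mutant
    reduced_emf1 <- if (rm_mut %in% names(env$reduced)) {
      names(env$reduced[[rm_mut]])[env$reduced[[rm_mut]]]
    } else {
      character()
    }
    env$status <- classify_genes(env$emf1_bound, k27_wt, reduced_emf1,
                                 universe)
    for (m in env$mutants) {
      env$status[[paste0("k27_in_", m)]] <-
        universe %in% env$k27_genes[[m]]
    }
    grp <- table(env$status$group)
    venn <- NULL
    if (length(env$mutants) >= 3L) {
      sets <- lapply(env$reduced[env$mutants[1:3]],
                     function(r) names(r)[r])
      venn <- venn_counts(sets)
      venn$regions <- as.list(venn$regions)
      venn$sizes <- as.list(venn$sizes)
      venn$conditional_triple <- as.list(venn$conditional_triple)
    }
    ov <- if (length(env$emf1_bound) && length(k27_wt)) {
      fisher_overlap(env$emf1_bound, k27_wt, universe)
    } else {
      NULL
    }
    list(mode = mode,
         n_emf1_bound = sum(env$status$emf1_bound),
         n_k27_wt = sum(env$status$k27_wt),
         group_sizes = as.list(grp),
         reduced_fractions = lapply(env$reduced, mean),
         emf1_k27_overlap = ov, venn = venn,
         degenerate = if (length(env$emf1_bound) == 0L) "no EMF1-bound genes"
                      else NULL)
  })

  stage("expression", function() {
    if (length(env$expr_tracks) == 0L) {
      return(list(skipped = "no expression tracks"))
    }
    norm <- lapply(env$expr_tracks, normalize_expression)
    env$scores <- lapply(norm, transcription_score, genes = env$genes)
    for (nm in names(env$scores)) {
      env$status[[paste0("tx_", nm)]] <-
        env$scores[[nm]]$score[match(env$status$gene_id,
                                     env$scores[[nm]]$gene_id)]
    }
    de <- list()
    if ("WT" %in% names(env$scores)) {
      for (m in intersect(env$mutants, names(env$scores))) {
        d <- differential_genes(env$scores$WT, env$scores[[m]],
                                sd_multiple = cfg$expression$sd_multiple)
        de[[m]] <- list(sd_ref = d$sd_ref, n_up = length(d$up),
                        n_down = length(d$down))
        env$status[[paste0("de_", m)]] <-
          d$calls$call[match(env$status$gene_id, d$calls$gene_id)]
      }
    }
    groups <- list(
      K27 = env$status$gene_id[env$status$k27_wt],
      EMF1_K27 = env$status$gene_id[env$status$group %in%
                                    c("EMF1_K27_groupI", "EMF1_K27_groupII")],
      GroupI = env$status$gene_id[env$status$group == "EMF1_K27_groupI"],
      GroupII = env$status$gene_id[env$status$group == "EMF1_K27_groupII"],
      EMF1_no_K27 = env$status$gene_id[env$status$group == "EMF1_no_K27"])
    avg <- lapply(groups, function(gs) {
      if (length(gs) == 0L) return(NULL)
      lapply(env$scores, function(sc)
        tryCatch(category_average_score(sc, gs), error = function(e) NULL))
    })
    list(sd_multiple = cfg$expression$sd_multiple, de = de,
         category_averages = avg)
  })

  stage("gene_table", function() {
    write_gene_table(env$status, file.path(outdir, "gene_status.tsv"))
    list(n_rows = nrow(env$status), columns = names(env$status))
  })

  stage("enrichment", function() {
    path <- cfg$enrichment$annotation_path
    if (is.null(path)) return(list(skipped = "no annotation map configured"))
    ann <- read_annotation_map(path)
    grp <- env$status$gene_id[env$status$group %in%
                              c("EMF1_K27_groupI", "EMF1_K27_groupII")]
    if (length(grp) == 0L) return(list(skipped = "empty EMF1_K27 set"))
    tab <- enrichment_table(grp, ann, env$genes$gene_id,
                            cfg$enrichment$small_category_threshold)
    utils::write.table(tab, file.path(outdir, "enrichment_emf1_k27.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(n_categories = nrow(tab),
         top_category = tab$category[1],
         top_log10_p = tab$log10_p[1])
  })

  report$wall_clock <- proc.time()[["elapsed"]] - t0
  invisible(finish(report))
}
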