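#' Assemble a pipeline configuration
#'
#' @param outdir output directory.
#' @param seed global seed; per-stage seeds are derived from it by stable
#'   hashing of the stage name, so toggling one stage does not shift
#'   another's random stream.
#' @param stages character vector of enabled stages, a subset of
#'   `c("simulate", "decontam", "ordination", "permanova", "trajectory",
#'   "mantel", "gwas", "core", "te", "indval", "network")`.
#' @param input optional list of paths (`counts`, `metadata`, `otu_meta`,
#'   `genotypes`) used instead of simulation.
#' @param sim a [sim_config()] (its seed is overridden by the derived stage
#'   seed).
#' @param params per-stage parameter overrides, e.g.
#'   `list(permanova = list(n_perm = 199))`.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1,
                            stages = c("simulate", "decontam", "ordination",
                                       "permanova", "trajectory", "mantel",
                                       "gwas", "core", "te", "indval",
                                       "network"),
                            input = NULL, sim = sim_config(seed = seed),
                            params = list()) {
  all_stages <- c("simulate", "decontam", "ordination", "permanova",
                  "trajectory", "mantel", "gwas", "core", "te", "indval",
                  "network")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop_input("unknown stage(s): %s", paste(bad, collapse = ", "))
  deps <- list(decontam = "simulate", ordination = "decontam",
               permanova = "ordination", trajectory = "ordination",
               mantel = "decontam", gwas = "ordination", core = "decontam",
               te = "decontam", indval = "decontam", network = "decontam")
  for (s in stages) {
    need <- deps[[s]]
    if (!is.null(need) && !need %in% stages &&
        !(need == "simulate" && !is.null(input)))
      stop_input("stage '%s' requires stage '%s'", s, need)
  }
  structure(list(outdir = outdir, seed = seed, stages = stages,
                 input = input, sim = sim, params = params),
            class = "pipeline_config")
}

#' Run the succession-analysis pipeline
#'
#' Executes the enabled stages in dependency order on simulated or loaded
#' data, writes per-stage TSV/JSON outputs under `config$outdir`, and
#' returns (and writes) a machine-readable run report.
#'
#' @param config a [pipeline_config()].
#' @return the run report (list), invisibly written to
#'   `outdir/run_report.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  par_of <- function(stage, defaults) {
    modifyList(defaults, config$params[[stage]] %||% list())
  }
  report <- list(package = "mycodyn",
                 version = as.character(utils::packageVersion("mycodyn")),
                 r_version = paste(R.version$major, R.version$minor,
                                   sep = "."),
                 seed = config$seed, stages = list())
  genotypes <- NULL; truth <- NULL

  if ("simulate" %in% stages) {
    sim <- config$sim
    sim$seed <- stage_seed(config$seed, "simulate")
    genotypes <- simulate_genotypes(sim)
    ss <- simulate_succession(sim, genotypes)
    tab <- ss$table; truth <- ss$truth
    write_table(tab, file.path(config$outdir, "counts.tsv"),
                file.path(config$outdir, "metadata.tsv"),
                file.path(config$outdir, "otu_meta.tsv"))
    write_genotypes(genotypes, file.path(config$outdir, "genotypes.tsv"),
                    file.path(config$outdir, "genotypes.vcf"))
    truth_report(truth, file.path(config$outdir, "truth.json"))
    report$stages$simulate <- list(
      n_samples = nrow(tab$counts), n_otus = ncol(tab$counts),
      n_snps = ncol(genotypes$dosages), seed = sim$seed)
  } else {
    if (is.null(config$input)) stop_input("no input and simulate disabled")
    tab <- load_table(config$input$counts, config$input$metadata,
                      config$input$otu_meta)
    if (!is.null(config$input$genotypes))
      genotypes <- read_genotypes(config$input$genotypes)
  }

  if ("decontam" %in% stages) {
    pp <- par_of("decontam", list(threshold = 0.1))
    rep_c <- flag_contaminants(tab, pp$threshold)
    write.table(as.data.frame(rep_c),
                file.path(config$outdir, "contaminants.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    tab <- decontaminate(tab, pp$threshold)
    report$stages$decontam <- list(n_flagged = sum(rep_c$flagged),
                                   n_samples = nrow(tab$counts))
  }

  norm <- hellinger_transform(css_normalize(tab))
  d <- bray_curtis(norm)
  meta <- tab$sample_meta
  sym <- !meta$infected
  d_sym <- comm_dist(unclass(d)[sym, sym], "bray")
  meta_sym <- meta[sym, , drop = FALSE]

  ord <- NULL
  if ("ordination" %in% stages) {
    pp <- par_of("ordination", list(k = 2, n_restarts = 5))
    ord <- pcoa(d_sym, k = pp$k)
    nm <- nmds(d_sym, k = pp$k, n_restarts = pp$n_restarts,
               seed = stage_seed(config$seed, "nmds"))
    write.table(data.frame(sample_id = rownames(ord$points), ord$points),
                file.path(config$outdir, "pcoa.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(sample_id = rownames(nm$points), nm$points),
                file.path(config$outdir, "nmds.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    report$stages$ordination <- list(nmds_stress = nm$stress,
                                     pcoa_var1 = ord$var_explained[1])
  }

  if ("permanova" %in% stages) {
    pp <- par_of("permanova", list(n_perm = 999))
    pa <- permanova(d_sym ~ timepoint + subpopulation, data = meta_sym,
                    n_perm = pp$n_perm,
                    seed = stage_seed(config$seed, "permanova"))
    write_permanova(pa, file.path(config$outdir, "permanova.tsv"))
    disp <- dispersion_homogeneity(d_sym, meta_sym$timepoint,
                                   n_perm = pp$n_perm,
                                   seed = stage_seed(config$seed, "disp"))
    report$stages$permanova <- list(
      timepoint_r2 = pa$R2[1], subpopulation_r2 = pa$R2[2],
      dispersion_p = disp$p)
  }

  if ("trajectory" %in% stages && !is.null(ord)) {
    ts <- build_trajectories(ord$points, meta_sym, "genotype", "timepoint",
                             "subpopulation")
    tm <- trajectory_metrics(ts)
    write.table(as.data.frame(tm),
                file.path(config$outdir, "trajectory_metrics.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    tests <- trajectory_group_tests(tm, ts = ts)
    report$stages$trajectory <- list(
      mean_directionality = mean(tm$directionality, na.rm = TRUE),
      length_p = tests$length_anova$table$p,
      direction_p = tests$direction_anova$table$p)
  }

  if ("mantel" %in% stages && !is.null(genotypes)) {
    pp <- par_of("mantel", list(n_perm = 999))
    gd <- nei_pi_distance(genotypes)
    rs <- lapply(sort(unique(meta_sym$timepoint)), function(tp) {
      ids <- meta_sym$sample_id[meta_sym$timepoint == tp]
      genos <- meta_sym$genotype[match(ids, meta_sym$sample_id)]
      keep <- genos %in% rownames(unclass(gd))
      dd <- comm_dist(unclass(d_sym)[ids[keep], ids[keep]], "bray")
      gg <- unclass(gd)[genos[keep], genos[keep]]
      dimnames(gg) <- list(ids[keep], ids[keep])
      m <- mantel(dd, comm_dist(gg, "nei_pi"), n_perm = pp$n_perm,
                  seed = stage_seed(config$seed, paste0("mantel", tp)))
      c(timepoint = tp, r = m$r, p = m$p)
    })
    mt <- as.data.frame(do.call(rbind, rs))
    write.table(mt, file.path(config$outdir, "mantel.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    report$stages$mantel <- list(r_by_timepoint = mt$r)
  }

  if ("gwas" %in% stages && !is.null(genotypes) && !is.null(ord)) {
    pp <- par_of("gwas", list(n_pc = 10, timepoint = max(meta_sym$timepoint),
                              axis = 2))
    ids <- meta_sym$sample_id[meta_sym$timepoint == pp$timepoint]
    genos <- meta_sym$genotype[match(ids, meta_sym$sample_id)]
    keep <- genos %in% rownames(genotypes$dosages)
    y <- ord$points[ids[keep], min(pp$axis, ncol(ord$points))]
    gsub <- genotypes
    gsub$dosages <- genotypes$dosages[genos[keep], , drop = FALSE]
    kin <- kinship_matrix(gsub)
    h2 <- pseudo_heritability(y, kin)
    sv <- svd_covariates(gsub, n_pc = min(pp$n_pc,
                                          nrow(gsub$dosages) - 2))
    gw <- gwas_scan(y, gsub, sv$covariates)
    write.table(as.data.frame(gw), file.path(config$outdir, "gwas.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$gwas <- list(h2 = h2$h2, h2_se = h2$se,
                               lambda_gc = attr(gw, "lambda_gc"),
                               top_snp = gw$snp[which.min(gw$p)])
  }

  if ("core" %in% stages) {
    pp <- par_of("core", list(increment = 0.02))
    core_sub <- select_core(tab, "subpopulation", pp$increment)
    core_time <- select_core(tab, "timepoint", pp$increment)
    core <- core_intersection(core_sub, core_time)
    writeLines(core, file.path(config$outdir, "core_otus.txt"))
    report$stages$core <- list(n_subpop = sum(core_sub$included),
                               n_time = sum(core_time$included),
                               n_core = length(core))
  }

  if ("te" %in% stages) {
    te <- time_explainability(tab)
    write.table(as.data.frame(te), file.path(config$outdir, "te.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$te <- list(n_tested = attr(te, "n_tested"),
                             n_significant = sum(te$significant))
  }

  if ("indval" %in% stages) {
    pp <- par_of("indval", list(n_perm = 199))
    iv <- indval(tab, "subpopulation", n_perm = pp$n_perm,
                 seed = stage_seed(config$seed, "indval"))
    write.table(as.data.frame(iv), file.path(config$outdir, "indval.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$indval <- list(n_indicators = sum(iv$p <= 0.05))
  }

  if ("network" %in% stages) {
    pp <- par_of("network", list(r_thresh = 0.35, n_subsamples = 50))
    net <- infer_network(clr_transform(tab),
                         r_thresh = pp$r_thresh,
                         n_subsamples = pp$n_subsamples,
                         seed = stage_seed(config$seed, "network"))
    mods <- detect_modules(net)
    roles <- zi_pi(net, mods)
    write_network(net, file.path(config$outdir, "network_edges.tsv"),
                  file.path(config$outdir, "network.graphml"))
    write.table(as.data.frame(roles), file.path(config$outdir, "roles.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$network <- list(n_edges = nrow(net$edges),
                                  modularity = mods$modularity,
                                  n_hubs = sum(roles$role != "peripheral"))
  }

  jsonlite::write_json(report, file.path(config$outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}

#' Structural validation of a pipeline run report
#'
#' Checks a run report (list or JSON path) against the bundled schema:
#' required top-level fields and per-stage summary types.
#'
#' @param report a report list from [run_pipeline()] or a JSON path.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  if (is.character(report))
    report <- jsonlite::read_json(report, simplifyVector = TRUE)
  schema <- jsonlite::read_json(system.file("schema", "run_report.json",
                                            package = "mycodyn"),
                                simplifyVector = TRUE)
  for (f in schema$required)
    if (is.null(report[[f]])) stop_input("report missing field '%s'", f)
  if (!is.numeric(report$seed)) stop_input("seed must be numeric")
  if (!is.list(report$stages)) stop_input("stages must be an object")
  invisible(TRUE)
}

cli_usage <- function() {
  paste(
    "usage: mycodyn <subcommand> [options]",
    "subcommands: simulate | analyze | gwas | network | report",
    "options: --config FILE (key=value lines)  --seed INT",
    "         --outdir DIR  --counts FILE --metadata FILE",
    "         --genotypes FILE  --verbose", sep = "\n")
}

parse_cli_config <- function(path) {
  out <- list()
  for (line in readLines(path)) {
    line <- sub("#.*", "", line)
    if (!nzchar(trimws(line))) next
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) next
    val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[trimws(kv[1])]] <- if (!is.na(num)) num else val
  }
  out
}

#' Command-line entry point
#'
#' Thin argv-level wrapper over [run_pipeline()]; used by the
#' `inst/cli/mycodyn` Rscript. Returns an exit code instead of calling
#' `quit()` so it can be tested in-process.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit code: 0 on success, 2 on input/usage error.
#' @export
mycodyn_cli <- function(argv) {
  if (!length(argv)) { message(cli_usage()); return(2L) }
  sub <- argv[1]
  if (!sub %in% c("simulate", "analyze", "gwas", "network", "report")) {
    message("unknown subcommand: ", sub, "\n", cli_usage())
    return(2L)
  }
  opts <- list(seed = 1, outdir = "mycodyn_out", verbose = FALSE)
  i <- 2
  while (i <= length(argv)) {
    a <- argv[i]
    if (a == "--verbose") { opts$verbose <- TRUE; i <- i + 1; next }
    if (!grepl("^--", a)) { message("unexpected argument: ", a); return(2L) }
    key <- sub("^--", "", a)
    if (!key %in% c("config", "seed", "outdir", "counts", "metadata",
                    "otu_meta", "genotypes")) {
      message("unknown flag: ", a, "\n", cli_usage())
      return(2L)
    }
    if (i + 1 > length(argv)) { message("missing value for ", a); return(2L) }
    opts[[key]] <- argv[i + 1]
    i <- i + 2
  }
  if (!is.null(opts$config)) {
    if (!file.exists(opts$config)) { message("no such config: ", opts$config); return(2L) }
    opts <- modifyList(opts, parse_cli_config(opts$config))
  }
  opts$seed <- as.integer(opts$seed)
  input <- NULL
  if (!is.null(opts$counts)) {
    for (f in c(opts$counts, opts$metadata))
      if (is.null(f) || !file.exists(f)) {
        message("missing input file: ", f %||% "(metadata not given)")
        return(2L)
      }
    input <- list(counts = opts$counts, metadata = opts$metadata,
                  otu_meta = opts$otu_meta, genotypes = opts$genotypes)
  }
  stages <- switch(sub,
    simulate = "simulate",
    analyze = c("simulate", "decontam", "ordination", "permanova",
                "trajectory", "mantel"),
    gwas = c("simulate", "decontam", "ordination", "gwas"),
    network = c("simulate", "decontam", "core", "network"),
    report = c("simulate", "decontam", "ordination"))
  if (!is.null(input)) stages <- setdiff(stages, "simulate")
  code <- tryCatch({
    cfg <- pipeline_config(opts$outdir, seed = opts$seed, stages = stages,
                           input = input)
    rep <- run_pipeline(cfg)
    if (sub == "report") validate_report(rep)
    if (opts$verbose) message("stages run: ", paste(names(rep$stages),
                                                   collapse = ", "))
    0L
  }, mycodyn_input_error = function(e) { message(conditionMessage(e)); 2L },
     error = function(e) { message(conditionMessage(e)); 1L })
  code
}
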