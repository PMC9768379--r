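# Pipeline commands tying the stages together, driven by one config list.

#' Default pipeline configuration
#'
#' Returns the configuration list consumed by the `cmd_*` commands. Every
#' stochastic stage has an explicit seed; reruns with an identical config
#' are byte-identical.
#'
#' @param out_dir output directory.
#' @param seed base seed from which all per-library seeds are derived.
#' @param depth reads per library.
#' @param n_replicates libraries per strain.
#' @param n_genes Miller-spread genes per strain.
#' @return nested configuration list.
#' @export
default_config <- function(out_dir = "poliseq_results", seed = 1L,
                           depth = 50000L, n_replicates = 3L,
                           n_genes = 200L) {
  list(
    out_dir = out_dir,
    template = list(seed = 101L, fasta = NULL, regions = NULL),
    libraries = list(n_replicates = as.integer(n_replicates),
                     depth = as.integer(depth), read_len = 40L,
                     umi_len = 8L, adaptor = DEFAULT_ADAPTOR,
                     contamination = 0.1, base_seed = as.integer(seed)),
    processing = list(min_overlap = 5L, min_match = 18L),
    analysis = list(alpha = 0.05, q = 2.5, window = c(-10L, 5L),
                    ks_cap = 10000L, n_perm = 999L,
                    perm_seed = as.integer(seed) + 7L),
    spreads = list(n_genes = as.integer(n_genes), density = 50,
                   footprint = 40, seed = as.integer(seed) + 11L),
    gaps = list(threshold = 0.25, n_bins = 10L)
  )
}

#' Load a pipeline configuration from YAML
#'
#' Values present in the file override [default_config()] defaults.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  modifyList(cfg, user)
}

cfg_meta <- function(cfg, extra = character()) {
  c(package = "poliseq",
    config_md5 = unname(tools::md5sum(cfg_file_of(cfg))),
    base_seed = as.character(cfg$libraries$base_seed),
    extra)
}

# The config is hashed from its canonical YAML rendering.
cfg_file_of <- function(cfg) {
  f <- file.path(cfg$out_dir, "config.yaml")
  if (!file.exists(f)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(cfg, f)
  }
  f
}

cfg_template <- function(cfg) {
  if (!is.null(cfg$template$fasta)) {
    load_template(cfg$template$fasta, cfg$template$regions)
  } else {
    make_default_template(seed = cfg$template$seed)
  }
}

lib_name <- function(strain, rep) sprintf("%s_rep%d", strain, rep)

#' Pipeline commands
#'
#' `cmd_simulate` writes FASTQ libraries for both strains of the
#' NET-Seq scenario, Miller-spread TSVs for both strains of the spread
#' scenario, the template (FASTA + regions), and truth tables (per-read
#' true 3' ends and the per-position model dwell). `cmd_process` runs
#' dedup/trim/map/normalize on every library and writes profile TSVs,
#' bedGraphs and accounting reports. `cmd_stats` writes the position-wise
#' t-test table, spacer-region KS table, Spearman matrix and PCA variance
#' fractions. `cmd_logo` writes the pause-site lists, PWMs and the
#' differential-logo table. `cmd_gaps` writes per-gap tables and gap
#' summaries. All outputs carry `# config_md5=` and seed headers.
#'
#' @param cfg configuration list (see [default_config()]).
#' @return invisibly, a named vector/list of output paths (and for the
#'   analysis commands, the result objects).
#' @export
cmd_simulate <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  tpl <- cfg_template(cfg)
  write_template(tpl, file.path(cfg$out_dir, "template.fa"),
                 file.path(cfg$out_dir, "template_regions.tsv"))
  scen <- make_strain_pair_scenario(tpl, seed = cfg$libraries$base_seed)
  lc <- cfg$libraries
  paths <- character()
  for (strain in c("wt", "mutant")) {
    model <- scen[[if (strain == "wt") "wt" else "mutant"]]
    dwell_path <- file.path(cfg$out_dir, sprintf("truth_dwell_%s.tsv", strain))
    write_tsv_meta(data.frame(position = seq_len(tpl$length),
                              dwell = model$dwell),
                   dwell_path, cfg_meta(cfg, c(strain = strain)))
    paths <- c(paths, dwell_path)
    for (r in seq_len(lc$n_replicates)) {
      id <- lib_name(strain, r)
      seed_r <- lc$base_seed + 100L * match(strain, c("wt", "mutant")) + r
      sim <- simulate_netseq_library(model, depth = lc$depth,
                                     read_len = lc$read_len,
                                     umi_len = lc$umi_len,
                                     adaptor = lc$adaptor,
                                     contamination_frac = lc$contamination,
                                     seed = seed_r, library_id = id,
                                     strain = strain)
      fq <- file.path(cfg$out_dir, paste0(id, ".fastq"))
      write_netseq_fastq(sim, fq)
      write_tsv_meta(sim$truth,
                     file.path(cfg$out_dir, paste0("truth_", id, ".tsv")),
                     cfg_meta(cfg, c(library_id = id,
                                     seed = as.character(seed_r))))
      paths <- c(paths, fq)
    }
  }
  sp <- cfg$spreads
  spread_scen <- make_spread_scenario(tpl)
  for (strain in c("wt", "mutant")) {
    model <- spread_scen[[if (strain == "wt") "wt" else "mutant"]]
    spreads <- simulate_miller_spreads(model, n_genes = sp$n_genes,
                                       target_density = sp$density,
                                       footprint = sp$footprint,
                                       seed = sp$seed +
                                         match(strain, c("wt", "mutant")))
    p <- file.path(cfg$out_dir, sprintf("spreads_%s.tsv", strain))
    write_spreads_tsv(spreads, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname cmd_simulate
#' @export
cmd_process <- function(cfg) {
  tpl <- cfg_template(cfg)
  lc <- cfg$libraries
  profiles <- list()
  for (strain in c("wt", "mutant")) {
    for (r in seq_len(lc$n_replicates)) {
      id <- lib_name(strain, r)
      fq <- file.path(cfg$out_dir, paste0(id, ".fastq"))
      if (!file.exists(fq)) stop("missing library (run cmd_simulate): ", fq)
      reads <- read_fastq(fq)
      if (!nrow(reads)) stop("empty FASTQ: ", fq)
      prof <- tryCatch(
        process_library(reads, tpl, umi_len = lc$umi_len,
                        adaptor = lc$adaptor,
                        min_overlap = cfg$processing$min_overlap,
                        min_match = cfg$processing$min_match,
                        library_id = id, strain = strain),
        error = function(e) stop("library ", id, ": ", conditionMessage(e),
                                 call. = FALSE))
      write_profile_tsv(prof, tpl,
                        file.path(cfg$out_dir, paste0("profile_", id, ".tsv")),
                        cfg_meta(cfg))
      write_profile_bedgraph(prof, tpl,
                             file.path(cfg$out_dir,
                                       paste0("profile_", id, ".bedgraph")),
                             cfg_meta(cfg))
      write_stats_report(prof,
                         file.path(cfg$out_dir, paste0("stats_", id, ".txt")),
                         cfg_meta(cfg))
      profiles[[id]] <- prof
    }
  }
  invisible(profiles)
}

load_profiles <- function(cfg, strain) {
  lapply(seq_len(cfg$libraries$n_replicates), function(r) {
    read_profile_tsv(file.path(cfg$out_dir,
                               paste0("profile_", lib_name(strain, r),
                                      ".tsv")))
  })
}

#' @rdname cmd_simulate
#' @export
cmd_stats <- function(cfg) {
  tpl <- cfg_template(cfg)
  wt <- load_profiles(cfg, "wt")
  mut <- load_profiles(cfg, "mutant")
  if (length(wt) < 2L) stop("need >= 2 replicates per strain")
  tt <- positionwise_ttest(wt, mut, alpha = cfg$analysis$alpha)
  write_tsv_meta(tt, file.path(cfg$out_dir, "ttest_positions.tsv"),
                 cfg_meta(cfg))
  spacers <- tpl$regions$name[tpl$regions$cls == "spacer"]
  med_wt <- median_occupancy(wt)
  med_mut <- median_occupancy(mut)
  ks <- do.call(rbind, lapply(spacers, function(rg) {
    r <- region_ks_test(
      normalize_profile(occupancy_profile(
        round(apply(profile_matrix(wt, "counts"), 1, stats::median)),
        "wt_median", "wt")),
      normalize_profile(occupancy_profile(
        round(apply(profile_matrix(mut, "counts"), 1, stats::median)),
        "mutant_median", "mutant")),
      tpl, rg, cap = cfg$analysis$ks_cap)
    data.frame(region = rg, D = r$D, p = r$p)
  }))
  write_tsv_meta(ks, file.path(cfg$out_dir, "ks_regions.tsv"), cfg_meta(cfg))
  rho <- spearman_matrix(c(wt, mut))
  write_tsv_meta(as.data.frame(cbind(library = rownames(rho), rho)),
                 file.path(cfg$out_dir, "spearman_matrix.tsv"),
                 cfg_meta(cfg))
  pca <- pca_variance(c(wt, mut))
  write_tsv_meta(data.frame(component = seq_along(pca$variance_fractions),
                            variance_fraction = pca$variance_fractions),
                 file.path(cfg$out_dir, "pca_variance.tsv"), cfg_meta(cfg))
  invisible(list(ttest = tt, ks = ks, spearman = rho, pca = pca,
                 median_wt = med_wt, median_mutant = med_mut))
}

#' @rdname cmd_simulate
#' @export
cmd_logo <- function(cfg) {
  tpl <- cfg_template(cfg)
  wt <- load_profiles(cfg, "wt")
  mut <- load_profiles(cfg, "mutant")
  an <- cfg$analysis
  res <- pause_logo_compare(median_occupancy(wt), median_occupancy(mut),
                            tpl, q = an$q,
                            window = an$window[1]:an$window[2],
                            n_perm = an$n_perm, seed = an$perm_seed,
                            alpha = an$alpha)
  write_tsv_meta(res$table, file.path(cfg$out_dir, "difflogo.tsv"),
                 cfg_meta(cfg))
  deltas <- as.data.frame(t(res$letter_deltas))
  deltas <- cbind(offset = res$table$offset, deltas)
  write_tsv_meta(deltas, file.path(cfg$out_dir, "difflogo_deltas.tsv"),
                 cfg_meta(cfg))
  sites <- rbind(data.frame(strain = "wt", position = res$sites_a),
                 data.frame(strain = "mutant", position = res$sites_b))
  write_tsv_meta(sites, file.path(cfg$out_dir, "pause_sites.tsv"),
                 cfg_meta(cfg))
  # BED export of pause sites (0-based half-open).
  bed <- data.frame(chrom = tpl$name, start = sites$position - 1L,
                    end = sites$position, name = sites$strain)
  utils::write.table(bed, file.path(cfg$out_dir, "pause_sites.bed"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(res)
}

#' @rdname cmd_simulate
#' @export
cmd_gaps <- function(cfg) {
  out <- list()
  for (strain in c("wt", "mutant")) {
    p <- file.path(cfg$out_dir, sprintf("spreads_%s.tsv", strain))
    if (!file.exists(p)) stop("missing spreads (run cmd_simulate): ", p)
    spreads <- read_spreads_tsv(p)
    summ <- summarize_gap_frequency(spreads,
                                    threshold_fraction = cfg$gaps$threshold,
                                    n_bins = cfg$gaps$n_bins)
    write_tsv_meta(summ$gaps,
                   file.path(cfg$out_dir, sprintf("gaps_%s.tsv", strain)),
                   cfg_meta(cfg))
    write_tsv_meta(summ$bins,
                   file.path(cfg$out_dir, sprintf("gap_bins_%s.tsv", strain)),
                   cfg_meta(cfg))
    write_tsv_meta(data.frame(n_genes = summ$n_genes,
                              n_genes_with_large_gap =
                                summ$n_genes_with_large_gap,
                              fraction = summ$fraction),
                   file.path(cfg$out_dir,
                             sprintf("gap_summary_%s.tsv", strain)),
                   cfg_meta(cfg))
    out[[strain]] <- summ
  }
  invisible(out)
}

#' Run the full synthetic WT-vs-mutant demo
#'
#' Simulation, processing, occupancy statistics, differential logo and gap
#' analysis in one call.
#'
#' @param out_dir output directory.
#' @param seed base seed.
#' @param depth reads per library.
#' @param n_genes Miller-spread genes per strain.
#' @return invisibly, list with the `stats`, `logo` and `gaps` results and
#'   the `config` used.
#' @export
run_demo <- function(out_dir = "poliseq_demo", seed = 1L, depth = 20000L,
                     n_genes = 200L) {
  cfg <- default_config(out_dir = out_dir, seed = seed, depth = depth,
                        n_genes = n_genes)
  cfg_file_of(cfg)
  cmd_simulate(cfg)
  cmd_process(cfg)
  stats <- cmd_stats(cfg)
  logo <- cmd_logo(cfg)
  gaps <- cmd_gaps(cfg)
  invisible(list(config = cfg, stats = stats, logo = logo, gaps = gaps))
}

#' Command-line entry point
#'
#' Dispatches `simulate` / `process` / `stats` / `logo` / `gaps` / `demo`
#' with `--config <yaml>`, `--out-dir <dir>` and `--seed <int>` flags. Used
#' by the `inst/scripts/poliseq` launcher.
#'
#' @param args character vector of command-line arguments.
#' @return invisibly, the command's result.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: poliseq <simulate|process|stats|logo|gaps|demo>",
    "[--config file.yaml] [--out-dir dir] [--seed n] [--depth n]")
  if (!length(args)) stop(usage, call. = FALSE)
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1L] else default
  }
  cfg <- if (!is.null(opt("--config"))) load_config(opt("--config"))
         else default_config()
  if (!is.null(opt("--out-dir"))) cfg$out_dir <- opt("--out-dir")
  if (!is.null(opt("--seed"))) {
    cfg$libraries$base_seed <- as.integer(opt("--seed"))
  }
  if (!is.null(opt("--depth"))) {
    cfg$libraries$depth <- as.integer(opt("--depth"))
  }
  switch(cmd,
         simulate = cmd_simulate(cfg),
         process = cmd_process(cfg),
         stats = cmd_stats(cfg),
         logo = cmd_logo(cfg),
         gaps = cmd_gaps(cfg),
         demo = run_demo(cfg$out_dir, seed = cfg$libraries$base_seed,
                         depth = cfg$libraries$depth),
         stop(usage, call. = FALSE))
}
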