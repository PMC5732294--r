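# End-to-end orchestration: build graph -> harmonics -> (synthetic) study ->
# decomposition -> spectra / cross-frequency / criticality analyses, driven
# by one JSON config, with per-stage error context and a checksum manifest
# for provenance.

#' @keywords internal
default_config <- function() {
  list(
    out_dir = "connharm-out",
    graph = list(source = "synthetic", order = 2, n_long_edges = 200,
                 distance_decay = 30, seed = 1, frac_interhemi = 0.1),
    harmonics = list(m = "all", dense_threshold = 2000),
    study = list(n_subjects = 12, T = 210, noise_sd = 0.01, seed = 1),
    analyses = list(levels = 15, bins = 100, partitions = 10,
                    bands = list(c(0, 0.01), c(0.01, 0.1), c(0.1, 0.2), c(0.2, 1)),
                    n_perm = 10000, alpha = 0.01, seed = 1)
  )
}

#' @keywords internal
merge_config <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
                      !is.null(names(user[[nm]])))
      merge_config(base[[nm]], user[[nm]]) else user[[nm]]
  }
  base
}

#' @keywords internal
stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Builds (or loads) the connectome graph, computes the harmonic basis,
#' generates a paired two-condition synthetic study, decomposes every scan,
#' and runs the binned-spectrum contrast, repertoire distributions,
#' cross-frequency band contrasts and partition means, and the power-law
#' (criticality) comparison. All outputs are plain TSV/JSON plus the basis
#' container, listed with md5 checksums in `manifest.json`. A re-run under
#' an identical config reproduces identical checksums for the deterministic
#' stages.
#'
#' @param config a config list, or path to a JSON file; missing entries take
#'   the documented defaults (see the vignette).
#' @return invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) chd_input_error("config file not found: %s", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- merge_config(default_config(), config)
  # validate declared input files before any computation
  for (p in c(cfg$graph$path, cfg$graph$mesh, cfg$graph$long_edges))
    if (!is.null(p) && !file.exists(p)) chd_input_error("input file not found: %s", p)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  graph <- stage("build-graph", switch(cfg$graph$source,
    synthetic = synth_connectome(order = cfg$graph$order,
                                 n_long_edges = cfg$graph$n_long_edges,
                                 distance_decay = cfg$graph$distance_decay,
                                 seed = cfg$graph$seed,
                                 frac_interhemi = cfg$graph$frac_interhemi),
    mtx = read_graph_mtx(cfg$graph$path),
    mesh = {
      meshes <- lapply(cfg$graph$mesh, read_off)
      mesh <- if (length(meshes) == 2)
        combine_hemispheres(meshes[[1]], meshes[[2]]) else meshes[[1]]
      le <- if (!is.null(cfg$graph$long_edges))
        read_long_edges(cfg$graph$long_edges)$pairs else NULL
      build_adjacency(mesh, le)
    },
    chd_input_error("unknown graph source '%s'", cfg$graph$source)))
  graph <- stage("prune", prune_isolated(graph))
  write_graph_mtx(graph, file.path(out, "graph.mtx"))

  basis <- stage("harmonics", compute_harmonics(
    graph, m = cfg$harmonics$m, dense_threshold = cfg$harmonics$dense_threshold))
  save_basis(basis, file.path(out, "basis.rds"))

  design <- stage("study", study_design(
    n_subjects = cfg$study$n_subjects, T = cfg$study$T,
    noise_sd = cfg$study$noise_sd, seed = cfg$study$seed))
  study <- stage("study", generate_study(basis, design))

  coeffs <- stage("decompose", lapply(study$scans, function(sc)
    decompose(sc$series, basis)))

  an <- cfg$analyses
  is_a <- study$index$condition == "A"
  subj <- study$index$subject

  # spectra: subject x bin energy tables per condition, paired contrast
  binned <- stage("spectra", lapply(coeffs, function(co)
    quantize_spectrum(harmonic_energy(co), n_levels = an$levels)$values))
  tabulate_cond <- function(sel) t(vapply(
    order(subj[sel]), function(i) binned[which(sel)[i]][[1]],
    numeric(an$levels)))
  bins_a <- tabulate_cond(is_a); bins_b <- tabulate_cond(!is_a)
  contrast <- stage("spectra", condition_energy_contrast(
    bins_a, bins_b, n_perm = an$n_perm, seed = an$seed, alpha = an$alpha))

  repertoire <- stage("repertoire", repertoire_distribution(
    list(A = coeffs[is_a], B = coeffs[!is_a]), baseline = "A"))

  xf <- stage("crossfreq", lapply(coeffs, crossfreq_matrix))
  bands <- an$bands
  if (is.matrix(bands)) bands <- asplit(bands, 1)   # JSON round-trip shape
  bands <- lapply(bands, as.numeric)
  band_res <- stage("crossfreq", lapply(bands, function(b)
    band_contrast(xf[is_a], xf[!is_a], band = b)))
  part_a <- Reduce(`+`, lapply(xf[is_a], partition_means, p = an$partitions)) / sum(is_a)
  part_b <- Reduce(`+`, lapply(xf[!is_a], partition_means, p = an$partitions)) / sum(!is_a)

  fits <- stage("criticality", do.call(rbind, lapply(seq_along(coeffs), function(i)
    cbind(subject = subj[i], condition = study$index$condition[i],
          power_law_fits(coeffs[[i]], n_bins = an$bins)))))
  crit <- stage("criticality", compare_fits(fits, c("A", "B")))

  # ---- write artifacts ----
  wtsv <- function(df, name) {
    utils::write.table(df, file.path(out, name), sep = "\t", row.names = FALSE,
                       quote = FALSE)
    name
  }
  spectra_tab <- data.frame(
    subject = rep(subj, each = an$levels),
    condition = rep(study$index$condition, each = an$levels),
    bin = rep(seq_len(an$levels), length(binned)),
    value = unlist(binned))
  files <- c(
    "graph.mtx", "basis.rds",
    wtsv(spectra_tab, "spectra_bins.tsv"),
    wtsv(contrast, "spectra_contrast.tsv"),
    wtsv(fits, "criticality_fits.tsv"),
    wtsv(crit, "criticality_compare.tsv"),
    wtsv(as.data.frame(part_a), "partition_means_A.tsv"),
    wtsv(as.data.frame(part_b), "partition_means_B.tsv"))
  jsonlite::write_json(
    list(conditions = lapply(repertoire, function(f)
      list(mu = f$mu, sigma = f$sigma, height = f$height))),
    file.path(out, "repertoire.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    lapply(seq_along(bands), function(i)
      list(band = bands[[i]], d = band_res[[i]]$d,
           significant = band_res[[i]]$significant)),
    file.path(out, "crossfreq_bands.json"), auto_unbox = TRUE, digits = NA)
  files <- c(files, "repertoire.json", "crossfreq_bands.json")

  manifest <- list(
    config = cfg,
    basis_fingerprint = basis$fingerprint,
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out, files))), files)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(graph = graph, basis = basis, study = study,
                 contrast = contrast, repertoire = repertoire,
                 band_contrasts = band_res, partition_means = list(A = part_a, B = part_b),
                 criticality = crit, fits = fits, manifest = manifest))
}

#' Command-line entry point
#'
#' Subcommand dispatcher used by the `chd` script in `inst/cli/`:
#' `chd synth-graph`, `chd build-graph`, `chd harmonics`, `chd decompose`,
#' `chd run`, `chd --version`.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status (0 on success), invisibly.
#' @export
chd_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: chd <synth-graph|build-graph|harmonics|decompose|run> [options] | chd --version"
  if (length(args) == 0) { message(usage); return(invisible(1L)) }
  cmd <- args[1]; rest <- args[-1]
  opt <- function(spec) optparse::parse_args(
    optparse::OptionParser(option_list = spec), args = rest)
  status <- tryCatch({
    switch(cmd,
      "--version" = {
        cat(sprintf("connharm %s\n", as.character(utils::packageVersion("connharm"))))
      },
      "synth-graph" = {
        o <- opt(list(
          optparse::make_option("--order", type = "integer", default = 2),
          optparse::make_option("--long", type = "integer", default = 200),
          optparse::make_option("--decay", type = "double", default = 30),
          optparse::make_option("--seed", type = "integer", default = 1),
          optparse::make_option("--out", type = "character")))
        g <- synth_connectome(order = o$order, n_long_edges = o$long,
                              distance_decay = o$decay, seed = o$seed)
        write_graph_mtx(g, o$out)
        message(sprintf("wrote %s (%d vertices)", o$out, g$n))
      },
      "build-graph" = {
        o <- opt(list(
          optparse::make_option("--mesh", type = "character",
                                action = "append", default = NULL),
          optparse::make_option("--long-edges", type = "character",
                                dest = "long_edges", default = NULL),
          optparse::make_option("--out", type = "character")))
        meshes <- lapply(o$mesh, read_off)
        mesh <- if (length(meshes) == 2)
          combine_hemispheres(meshes[[1]], meshes[[2]]) else meshes[[1]]
        le <- if (!is.null(o$long_edges)) read_long_edges(o$long_edges)$pairs else NULL
        write_graph_mtx(build_adjacency(mesh, le), o$out)
        message(sprintf("wrote %s", o$out))
      },
      "harmonics" = {
        o <- opt(list(
          optparse::make_option("--graph", type = "character"),
          optparse::make_option("--modes", type = "character", default = "all"),
          optparse::make_option("--out", type = "character")))
        g <- prune_isolated(read_graph_mtx(o$graph))
        m <- if (o$modes == "all") "all" else as.integer(o$modes)
        save_basis(compute_harmonics(g, m = m), o$out)
        message(sprintf("wrote %s", o$out))
      },
      "decompose" = {
        o <- opt(list(
          optparse::make_option("--basis", type = "character"),
          optparse::make_option("--func", type = "character"),
          optparse::make_option("--out", type = "character"),
          optparse::make_option("--zscore", action = "store_true", default = FALSE)))
        basis <- load_basis(o$basis)
        series <- read_series_tsv(o$func)
        if (o$zscore) series <- zscore_vertices(series)
        co <- decompose(series, basis)
        utils::write.table(co$alpha, o$out, sep = "\t", row.names = FALSE,
                           col.names = FALSE)
        message(sprintf("wrote %s (%d x %d)", o$out, nrow(co$alpha), ncol(co$alpha)))
      },
      "run" = {
        o <- opt(list(optparse::make_option("--config", type = "character")))
        run_pipeline(o$config)
        message("pipeline complete")
      },
      { message(usage); return(invisible(1L)) })
    0L
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}
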