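# Pipeline orchestration: one config file in, four report tables out.
# Stages: orthology selection -> network build -> GWAS +1 interactome ->
# per-gene Monte Carlo overlap tests -> list-level significance ->
# connectivity binning and slope comparison.

#' Read a pipeline run configuration
#'
#' Plain YAML key/value file. Recognised keys (all optional unless a stage
#' needs them): paths `network_file`, `screen_list`, `gwas_list`,
#' `orthology_table`, `universe_list`, `output_dir`; Monte Carlo settings
#' `n_sim`, `n_lists`, `list_size`, `alpha`, `rng_seed`; connectivity
#' settings `n_bins`, `boundary` (`upper`/`lower`), `tails` (`two`/`one`);
#' filters `taxid`, `category`, `min_identity`; `k_observed` for the
#' list-level stage (defaults to the number of significant screen genes).
#'
#' @param path Path to the config file.
#' @return A named list of class `run_config` with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  defaults <- list(n_sim = 1000L, n_lists = 100L, list_size = 60L,
                   alpha = 0.05, rng_seed = 1L, n_bins = 10L,
                   boundary = "upper", tails = "two", taxid = 9606L,
                   category = "physical", min_identity = 25,
                   output_dir = "netoverlap_out", k_observed = NULL)
  cfg <- utils::modifyList(defaults, raw)
  for (k in c("network_file", "screen_list", "gwas_list"))
    if (is.null(cfg[[k]]))
      stop("config is missing required key '", k, "'")
  structure(cfg, class = "run_config")
}

.stage <- function(name, log, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e)
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  secs <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
  cat(sprintf("[%s] %gs\n", name, secs), file = log, append = TRUE)
  out
}

#' Run the full overlap-analysis pipeline
#'
#' Executes every stage on the inputs named in the configuration and writes
#' four tab-separated reports plus a run log to `output_dir`:
#' `overlap_results.tsv` (per-gene Monte Carlo overlap tests),
#' `list_level.tsv` (random-list calibration and list-level p),
#' `binning.tsv` (connectivity bins with the experimental profile) and
#' `slope_comparison.tsv` (experimental vs Monte Carlo slopes). The run log
#' records the seed, package version, input checksums and per-stage wall
#' time. If an `orthology_table` is configured the screen list is treated
#' as worm genes and mapped through [select_orthologues()] first; otherwise
#' it is used as-is.
#'
#' @param config A [read_run_config()] result, or a path to a config file.
#' @return Invisibly, a named list of the report paths.
#' @export
full_run <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(config$output_dir, "run_log.txt")
  inputs <- unlist(config[c("network_file", "screen_list", "gwas_list",
                            "orthology_table", "universe_list")])
  cat("netoverlap ", as.character(utils::packageVersion("netoverlap")),
      " run, rng_seed=", config$rng_seed, "\n",
      paste0("md5 ", basename(inputs), " = ", tools::md5sum(inputs),
             collapse = "\n"), "\n", sep = "", file = log)
  cfg <- mc_config(config$n_sim, config$n_lists, config$list_size,
                   config$alpha, config$rng_seed)

  screen <- .stage("read_inputs", log, {
    sl <- read_gene_list(config$screen_list, "screen")
    if (!is.null(config$orthology_table)) {
      omap <- select_orthologues(read_orthology(config$orthology_table),
                                 config$min_identity)
      mapped <- unique(unname(omap$mapping[sl$genes]))
      mapped <- mapped[!is.na(mapped)]
      if (length(mapped) == 0L)
        stop("no screen gene maps to an orthologue")
      gene_list(mapped, "screen_orthologues", config$orthology_table)
    } else sl
  })
  gwas <- read_gene_list(config$gwas_list, "gwas")
  network <- .stage("build_network", log,
    build_network(read_biogrid(config$network_file, config$taxid,
                               config$category)))
  universe <- if (!is.null(config$universe_list))
    read_gene_list(config$universe_list, "universe")
  else gene_list(network$genes, "universe", "all network genes")

  scr <- .stage("overlap_tests", log,
    screen_overlap_tests(network, screen, gwas, universe, cfg))
  paths <- list(overlap = file.path(config$output_dir,
                                    "overlap_results.tsv"))
  write_results_table(scr, paths$overlap)

  smry <- summary(scr)
  k_obs <- if (is.null(config$k_observed)) smry$n_significant
           else config$k_observed
  gwas_p1 <- plus_one(network, gwas)
  lls <- .stage("list_level", log,
    null_list_significance(network, universe, gwas_p1, cfg, k_obs))
  paths$list_level <- file.path(config$output_dir, "list_level.tsv")
  write.table(
    data.frame(statistic = c("mean_significant_per_list", "ci95_halfwidth",
                             "k_observed", "p_ge_k"),
               value = c(lls$mean, lls$ci95_halfwidth, lls$k_observed,
                         lls$p_ge_k)),
    paths$list_level, sep = "\t", quote = FALSE, row.names = FALSE)

  conn <- .stage("connectivity", log, {
    ranking <- rank_by_degree(network)
    scheme <- make_bins(ranking, universe, config$n_bins)
    sc <- slope_comparison(network, universe, scheme, screen, cfg,
                           tails = config$tails,
                           boundary = config$boundary)
    list(scheme = scheme, sc = sc)
  })
  paths$binning <- file.path(config$output_dir, "binning.tsv")
  bin_tab <- cbind(as.data.frame(conn$scheme),
                   count = conn$sc$experimental_profile$count,
                   fraction = conn$sc$experimental_profile$fraction)
  write.table(bin_tab, paths$binning, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths$slope <- file.path(config$output_dir, "slope_comparison.tsv")
  write.table(
    data.frame(statistic = c("experimental_slope", "mc_slope_mean",
                             "mc_slope_sd", "t_statistic", "df", "p",
                             "tails"),
               value = c(conn$sc$experimental_slope,
                         mean(conn$sc$mc_slopes), sd(conn$sc$mc_slopes),
                         conn$sc$t_statistic, conn$sc$df, conn$sc$p,
                         conn$sc$tails)),
    paths$slope, sep = "\t", quote = FALSE, row.names = FALSE)

  cat("done: ", length(paths), " report(s) written\n", sep = "",
      file = log, append = TRUE)
  invisible(paths)
}
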