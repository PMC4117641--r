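# Size-matched Monte Carlo overlap testing.
#
# Screen hits are biased toward network hubs, so the overlap between a hit's
# +1 interactome and the GWAS +1 interactome cannot be referred to a naive
# null. Instead, for each tested gene, random +1 interactomes of exactly the
# same size are assembled from the orthologue universe, and the observed
# overlap is located within the Monte Carlo distribution of random overlaps.
# The empirical p is min(n_right, n_left) / n_sim, where n_right counts
# simulations with overlap >= observed and n_left counts overlap <= observed;
# ties are counted in both tails, giving a one-tailed (and slightly
# conservative) test.

#' Monte Carlo configuration
#'
#' @param n_sim Random interactomes per tested gene (default 1000).
#' @param n_lists Random gene lists for list-level significance and slope
#'   comparison (default 100).
#' @param list_size Genes per random list (default 60).
#' @param alpha Per-gene significance threshold (default 0.05).
#' @param rng_seed Integer seed; when non-`NULL` every stage derives its own
#'   deterministic substream from it (per-gene for [overlap_test()]), so
#'   results are reproducible and adding a stage never perturbs another
#'   stage's draws. When `NULL` the ambient RNG state is used.
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(n_sim = 1000L, n_lists = 100L, list_size = 60L,
                      alpha = 0.05, rng_seed = NULL) {
  n_sim <- as.integer(n_sim); n_lists <- as.integer(n_lists)
  list_size <- as.integer(list_size)
  stopifnot(n_sim >= 1L, n_lists >= 1L, list_size >= 1L,
            alpha > 0, alpha < 1)
  structure(list(n_sim = n_sim, n_lists = n_lists, list_size = list_size,
                 alpha = alpha, rng_seed = rng_seed),
            class = "mc_config")
}

.as_universe_idx <- function(network, universe) {
  if (inherits(universe, "gene_list")) universe <- universe$genes
  idx <- match(unique(.norm_symbol(universe)), network$genes)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) stop("no universe gene is present in the network")
  idx
}

# One random +1 interactome, as gene indices. Universe genes are drawn
# uniformly without replacement; each drawn gene's closed neighbourhood is
# unioned into the accumulator (already-present genes skipped); the final
# gene's contribution is truncated, in rng-shuffled order, so the result has
# exactly `target` genes.
.random_p1_idx <- function(adj, uni_idx, target, mem) {
  ord <- uni_idx[sample.int(length(uni_idx))]
  acc <- integer(0)
  count <- 0L
  for (g in ord) {
    add <- c(g, adj[[g]])
    add <- add[!mem[add]]
    nn <- length(add)
    if (nn == 0L) next
    if (count + nn > target) {
      add <- add[sample.int(nn)[seq_len(target - count)]]
      nn <- target - count
    }
    mem[add] <- TRUE
    acc <- c(acc, add)
    count <- count + nn
    if (count == target) break
  }
  if (count < target) {
    mem[acc] <- FALSE
    stop("universe exhausted: random +1 interactome reached size ", count,
         " of requested ", target)
  }
  acc
}

#' Generate one size-matched random +1 interactome
#'
#' Assembles a random gene set of exactly `target_size` genes by repeatedly
#' drawing a universe gene uniformly without replacement and adding its +1
#' interactome members (already-present genes skipped); the last drawn
#' gene's contribution is truncated in random order to land exactly on the
#' target size.
#'
#' @param network An `interaction_network`.
#' @param universe [gene_list()] or character vector of genes the seeds are
#'   drawn from; genes absent from the network are ignored.
#' @param target_size Required size of the result, `>= 1`.
#' @return Character vector of exactly `target_size` distinct gene symbols.
#' @export
random_plus_one <- function(network, universe, target_size) {
  stopifnot(inherits(network, "interaction_network"), target_size >= 1L)
  uni_idx <- .as_universe_idx(network, universe)
  mem <- logical(length(network$genes))
  network$genes[.random_p1_idx(network$adj, uni_idx, as.integer(target_size),
                               mem)]
}

# Core empirical-p computation for one gene index; RNG state is the caller's.
.overlap_test_core <- function(network, gi, gwas_mask, uni_idx, n_sim) {
  adj <- network$adj
  p1 <- .p1_members_idx(adj, gi)
  target <- length(p1)
  observed <- sum(gwas_mask[p1])
  mem <- logical(length(adj))
  n_right <- 0L; n_left <- 0L; n_tie <- 0L
  for (s in seq_len(n_sim)) {
    acc <- .random_p1_idx(adj, uni_idx, target, mem)
    ov <- sum(gwas_mask[acc])
    mem[acc] <- FALSE
    if (ov >= observed) n_right <- n_right + 1L
    if (ov <= observed) n_left <- n_left + 1L
    if (ov == observed) n_tie <- n_tie + 1L
  }
  list(observed = observed, size = target,
       n_right = n_right, n_left = n_left, n_tie = n_tie)
}

#' Size-matched Monte Carlo overlap test for one gene
#'
#' Computes the observed overlap between the gene's +1 interactome and a
#' fixed GWAS +1 interactome, generates `cfg$n_sim` random +1 interactomes
#' of the same size from the universe, and reports the one-tailed empirical
#' p-value `min(n_right, n_left) / n_sim`. Equality with the observed
#' overlap is counted in both tails, so the test is conservative; an
#' optional mid-p value (half weight on ties) is reported when
#' `mid_p = TRUE` but the headline `p` is never altered.
#'
#' @param network An `interaction_network`.
#' @param gene Gene symbol to test. If absent from the network the test is
#'   skipped: `NULL` is returned with a warning.
#' @param gwas_p1 The fixed GWAS-side [plus_one()] interactome.
#' @param universe Universe the random seeds are drawn from (orthologue
#'   universe; genes absent from the network are ignored).
#' @param cfg An [mc_config()].
#' @param mid_p Also report the mid-p variant (default `FALSE`).
#' @return An object of class `overlap_test` (or `NULL` if skipped): gene,
#'   observed overlap, interactome size, `n_right`, `n_left`, `p`,
#'   `direction` (`"larger"` iff `n_right <= n_left`; the exact tie
#'   `n_right == n_left` is assigned `"larger"` and flagged in `tie`).
#' @export
overlap_test <- function(network, gene, gwas_p1, universe, cfg = mc_config(),
                         mid_p = FALSE) {
  stopifnot(inherits(network, "interaction_network"),
            inherits(cfg, "mc_config"))
  gene <- .norm_symbol(gene)
  gi <- match(gene, network$genes)
  if (is.na(gi)) {
    warning("gene '", gene, "' not in network; test skipped")
    return(NULL)
  }
  uni_idx <- .as_universe_idx(network, universe)
  gwas_mask <- logical(length(network$genes))
  gwas_mask[match(gwas_p1$members, network$genes)] <- TRUE
  if (!is.null(cfg$rng_seed))
    set.seed(derive_seed(cfg$rng_seed, paste0("overlap_test:", gene)))
  core <- .overlap_test_core(network, gi, gwas_mask, uni_idx, cfg$n_sim)
  .finish_overlap_test(gene, core, cfg$n_sim, mid_p)
}

.finish_overlap_test <- function(gene, core, n_sim, mid_p = FALSE) {
  res <- list(gene = gene, observed = core$observed, size = core$size,
              n_right = core$n_right, n_left = core$n_left,
              p = min(core$n_right, core$n_left) / n_sim,
              direction = if (core$n_right <= core$n_left) "larger"
                          else "smaller",
              tie = core$n_right == core$n_left, n_sim = n_sim)
  if (mid_p)
    res$p_mid <- (min(core$n_right, core$n_left) - core$n_tie / 2) / n_sim
  structure(res, class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat("overlap_test: ", x$gene, " (+1 size ", x$size, ")\n", sep = "")
  cat("  observed overlap ", x$observed, "; n_right ", x$n_right,
      ", n_left ", x$n_left, " of ", x$n_sim, " simulations\n", sep = "")
  cat("  p = ", format(x$p), ", direction ", x$direction,
      if (isTRUE(x$tie)) " (tie between tails)", "\n", sep = "")
  if (!is.null(x$p_mid)) cat("  mid-p = ", format(x$p_mid), "\n", sep = "")
  invisible(x)
}

#' Monte Carlo overlap tests for a whole screen list
#'
#' Runs [overlap_test()] for every gene in the (orthologue-mapped) screen
#' list, flags genes whose products interact directly with any GWAS-list
#' gene, and returns the results sorted by ascending p-value (ties by gene
#' symbol). Genes absent from the network are skipped with a warning.
#'
#' @param network An `interaction_network`.
#' @param screen_list [gene_list()] or character vector of screen genes
#'   (human orthologue symbols).
#' @param gwas_list [gene_list()] or character vector of GWAS candidate
#'   genes; their +1 interactome is computed once and held fixed.
#' @param universe Universe for the random interactome seeds.
#' @param cfg An [mc_config()].
#' @return An object of class `overlap_screen`: a data frame with columns
#'   `gene`, `observed`, `size`, `n_right`, `n_left`, `p`, `direction`,
#'   `direct_interactor`, with the configuration, the GWAS interactome size
#'   and any skipped genes as attributes.
#' @seealso [summary.overlap_screen()], [null_list_significance()]
#' @export
screen_overlap_tests <- function(network, screen_list, gwas_list, universe,
                                 cfg = mc_config()) {
  if (inherits(screen_list, "gene_list")) screen_list <- screen_list$genes
  screen_list <- unique(.norm_symbol(screen_list))
  gwas_p1 <- plus_one(network, gwas_list)
  uni_idx <- .as_universe_idx(network, universe)
  gwas_mask <- logical(length(network$genes))
  gwas_mask[match(gwas_p1$members, network$genes)] <- TRUE
  gwas_seed_idx <- match(gwas_p1$seeds, network$genes)

  gi_all <- match(screen_list, network$genes)
  skipped <- screen_list[is.na(gi_all)]
  if (length(skipped))
    warning(length(skipped), " screen gene(s) not in network, skipped: ",
            paste(skipped, collapse = ", "))
  keep <- !is.na(gi_all)
  genes <- screen_list[keep]; gi_all <- gi_all[keep]
  if (length(genes) == 0L) stop("no screen gene is present in the network")

  rows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    if (!is.null(cfg$rng_seed))
      set.seed(derive_seed(cfg$rng_seed, paste0("overlap_test:", genes[[i]])))
    core <- .overlap_test_core(network, gi_all[[i]], gwas_mask, uni_idx,
                               cfg$n_sim)
    rows[[i]] <- data.frame(
      gene = genes[[i]], observed = core$observed, size = core$size,
      n_right = core$n_right, n_left = core$n_left,
      p = min(core$n_right, core$n_left) / cfg$n_sim,
      direction = if (core$n_right <= core$n_left) "larger" else "smaller",
      direct_interactor = any(network$adj[[gi_all[[i]]]] %in% gwas_seed_idx),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("overlap_screen", "data.frame"),
            cfg = cfg, gwas_size = gwas_p1$size,
            gwas_dropped = gwas_p1$dropped_seeds, skipped = skipped)
}

#' @export
print.overlap_screen <- function(x, ...) {
  cfg <- attr(x, "cfg")
  cat("overlap_screen: ", nrow(x), " gene(s) tested against a GWAS +1 ",
      "interactome of ", attr(x, "gwas_size"), " genes (n_sim = ",
      cfg$n_sim, ")\n", sep = "")
  print.data.frame(head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("  ... ", nrow(x) - 10L, " more row(s)\n", sep = "")
  invisible(x)
}

#' Summarise a screen's overlap tests
#'
#' @param object An `overlap_screen` object.
#' @param alpha Significance threshold (defaults to the configuration's).
#' @param ... Unused.
#' @return A list with the number of genes tested, the number significant at
#'   `alpha` split by direction, and the number of direct GWAS interactors.
#' @export
summary.overlap_screen <- function(object, alpha = NULL, ...) {
  if (is.null(alpha)) alpha <- attr(object, "cfg")$alpha
  sig <- object$p < alpha
  out <- list(n_tested = nrow(object),
              alpha = alpha,
              n_significant = sum(sig),
              n_larger = sum(sig & object$direction == "larger"),
              n_smaller = sum(sig & object$direction == "smaller"),
              n_direct = sum(object$direct_interactor),
              significant_genes = object$gene[sig])
  class(out) <- "summary.overlap_screen"
  out
}

#' @export
print.summary.overlap_screen <- function(x, ...) {
  cat(x$n_tested, " gene(s) tested; ", x$n_significant,
      " significant at p < ", x$alpha, " (", x$n_larger, " larger, ",
      x$n_smaller, " smaller than the Monte Carlo null)\n", sep = "")
  cat(x$n_direct, " gene(s) interact directly with a GWAS-list gene\n",
      sep = "")
  if (x$n_significant)
    cat("significant: ", paste(x$significant_genes, collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' List-level significance from random screen lists
#'
#' Draws `cfg$n_lists` random gene lists of `cfg$list_size` genes from the
#' universe, runs the per-gene Monte Carlo overlap test on every member, and
#' counts how many genes per list are significant at `cfg$alpha`. The
#' distribution of those counts calibrates how many significant genes a
#' random screen of this size produces, and `p_ge_k` is the fraction of
#' random lists with at least `k_observed` significant genes — the
#' list-level empirical p for an observed screen.
#'
#' @param network An `interaction_network`.
#' @param universe Universe gene list (orthologue universe).
#' @param gwas_p1 The fixed GWAS-side [plus_one()] interactome.
#' @param cfg An [mc_config()].
#' @param k_observed Observed number of significant genes in the real
#'   screen (default 0 reports only the null distribution summaries).
#' @return An object of class `list_level_result`: `counts_per_list`,
#'   `mean`, `ci95_halfwidth` (normal approximation, 1.96 sd/sqrt(n_lists)),
#'   `p_ge_k`, `k_observed`, and the configuration used.
#' @export
null_list_significance <- function(network, universe, gwas_p1,
                                   cfg = mc_config(), k_observed = 0L) {
  stopifnot(inherits(cfg, "mc_config"), k_observed >= 0L)
  uni_idx <- .as_universe_idx(network, universe)
  if (length(uni_idx) < cfg$list_size)
    stop("universe smaller than list_size")
  gwas_mask <- logical(length(network$genes))
  gwas_mask[match(gwas_p1$members, network$genes)] <- TRUE
  if (!is.null(cfg$rng_seed))
    set.seed(derive_seed(cfg$rng_seed, "null_list_significance"))

  counts <- integer(cfg$n_lists)
  for (l in seq_len(cfg$n_lists)) {
    members <- uni_idx[sample.int(length(uni_idx), cfg$list_size)]
    nsig <- 0L
    for (gi in members) {
      core <- .overlap_test_core(network, gi, gwas_mask, uni_idx, cfg$n_sim)
      if (min(core$n_right, core$n_left) / cfg$n_sim < cfg$alpha)
        nsig <- nsig + 1L
    }
    counts[[l]] <- nsig
  }
  structure(list(counts_per_list = counts,
                 mean = mean(counts),
                 ci95_halfwidth = 1.96 * stats::sd(counts) /
                   sqrt(cfg$n_lists),
                 p_ge_k = mean(counts >= k_observed),
                 k_observed = as.integer(k_observed),
                 cfg = cfg),
            class = "list_level_result")
}

#' @export
print.list_level_result <- function(x, ...) {
  cat("list_level_result: ", x$cfg$n_lists, " random list(s) of ",
      x$cfg$list_size, " genes\n", sep = "")
  cat("  significant genes per list: mean ", round(x$mean, 2), " (95% CI +/- ",
      round(x$ci95_halfwidth, 2), ")\n", sep = "")
  cat("  fraction of lists with >= ", x$k_observed, " significant: ",
      format(x$p_ge_k), "\n", sep = "")
  invisible(x)
}
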