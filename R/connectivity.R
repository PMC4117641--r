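# Connectivity-bias analysis. Genes are ranked by interactor count, the
# ranking is cut into bins each holding the same number of orthologue-
# universe genes, and a gene list's per-bin occupancy fractions are fitted
# on a log-log scale. A hub-biased list gives a negative slope; random
# lists drawn from the universe segregate evenly across bins and give slope
# ~0. The experimental slope is compared against Monte Carlo random-list
# slopes with a one-sample Student's t-test.

#' Rank network genes by degree
#'
#' @param network An `interaction_network`.
#' @return An object of class `degree_ranking`: data frame with columns
#'   `gene`, `degree`, `rank` (1 = most interactors), sorted by decreasing
#'   degree with ties broken by gene symbol so the order is deterministic.
#' @export
rank_by_degree <- function(network) {
  stopifnot(inherits(network, "interaction_network"),
            length(network$genes) > 0L)
  ord <- order(-network$degree, network$genes)
  out <- data.frame(gene = network$genes[ord],
                    degree = as.integer(network$degree[ord]),
                    rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  structure(out, class = c("degree_ranking", "data.frame"))
}

#' Cut a degree ranking into equal-universe bins
#'
#' Walks the ranking from rank 1 and closes a bin once it has accumulated
#' its quota of universe genes; the last bin absorbs the remaining tail of
#' the ranking. When the universe size is not divisible by `n_bins` the
#' remainder is distributed one-per-bin to the earliest bins. Bin widths in
#' ranks differ (hubs are sparse in the universe too), but universe
#' occupancy per bin is uniform — which is what makes a uniform random draw
#' from the universe land evenly across bins.
#'
#' @param ranking A [rank_by_degree()] result.
#' @param universe [gene_list()] or character vector; the orthologue
#'   universe.
#' @param n_bins Number of bins (default 10).
#' @return An object of class `binning_scheme`: data frame with columns
#'   `bin`, `lo`, `hi` (rank interval, inclusive), `n_universe`;
#'   `universe_per_bin` (the base quota) as an attribute.
#' @export
make_bins <- function(ranking, universe, n_bins = 10L) {
  stopifnot(inherits(ranking, "degree_ranking"), n_bins >= 1L)
  if (inherits(universe, "gene_list")) universe <- universe$genes
  universe <- unique(.norm_symbol(universe))
  in_uni <- ranking$gene %in% universe
  n_u <- sum(in_uni)
  if (n_u < n_bins)
    stop("universe has only ", n_u, " gene(s) in the ranking; need at least ",
         n_bins)
  base <- n_u %/% n_bins
  rem <- n_u %% n_bins
  quota <- rep.int(base, n_bins) + c(rep.int(1L, rem),
                                     rep.int(0L, n_bins - rem))
  cum_u <- cumsum(in_uni)
  hi <- integer(n_bins); lo <- integer(n_bins); nun <- integer(n_bins)
  lo[[1L]] <- 1L
  cq <- cumsum(quota)
  for (b in seq_len(n_bins)) {
    hi[[b]] <- if (b == n_bins) nrow(ranking)
               else match(cq[[b]], cum_u)  # rank completing this bin's quota
    if (b > 1L) lo[[b]] <- hi[[b - 1L]] + 1L
    nun[[b]] <- cum_u[[hi[[b]]]] - if (b > 1L) cum_u[[hi[[b - 1L]]]] else 0L
  }
  out <- data.frame(bin = seq_len(n_bins), lo = lo, hi = hi,
                    n_universe = nun)
  structure(out, class = c("binning_scheme", "data.frame"),
            universe_per_bin = base, n_universe_total = n_u)
}

#' Per-bin occupancy profile of a gene list
#'
#' @param scheme A [make_bins()] scheme.
#' @param ranking The [rank_by_degree()] ranking the scheme was built from.
#' @param genes [gene_list()] or character vector.
#' @return An object of class `bin_profile`: data frame with columns `bin`,
#'   `count`, `fraction` (count over the full input list size, so genes
#'   absent from the ranking — reported in the `absent` attribute — make
#'   the fractions sum to less than 1).
#' @export
bin_profile <- function(scheme, ranking, genes) {
  stopifnot(inherits(scheme, "binning_scheme"),
            inherits(ranking, "degree_ranking"))
  if (inherits(genes, "gene_list")) genes <- genes$genes
  genes <- unique(.norm_symbol(genes))
  ranks <- ranking$rank[match(genes, ranking$gene)]
  absent <- genes[is.na(ranks)]
  ranks <- ranks[!is.na(ranks)]
  counts <- vapply(seq_len(nrow(scheme)), function(b)
    sum(ranks >= scheme$lo[[b]] & ranks <= scheme$hi[[b]]), integer(1L))
  out <- data.frame(bin = scheme$bin, count = counts,
                    fraction = counts / length(genes))
  structure(out, class = c("bin_profile", "data.frame"),
            list_size = length(genes), absent = absent)
}

#' Log-log slope of a bin profile
#'
#' Ordinary least squares of log10(fraction) on log10(bin rank boundary).
#' Zero-count bins have no defined log fraction; they are excluded from the
#' fit and listed in the result.
#'
#' @param profile A [bin_profile()].
#' @param scheme The matching [make_bins()] scheme.
#' @param boundary Which rank boundary of each bin supplies the x
#'   coordinate: `"upper"` (default) or `"lower"`.
#' @return An object of class `slope_fit`: list with `slope`, `intercept`,
#'   `n_points`, `excluded_bins`, `boundary` and the `lm` fit.
#' @export
loglog_slope <- function(profile, scheme, boundary = c("upper", "lower")) {
  stopifnot(inherits(profile, "bin_profile"),
            inherits(scheme, "binning_scheme"))
  boundary <- match.arg(boundary)
  x_all <- if (boundary == "upper") scheme$hi else scheme$lo
  usable <- profile$count > 0L
  if (sum(usable) < 2L)
    stop("fewer than 2 bins with nonzero counts; cannot fit a slope")
  x <- log10(x_all[usable])
  y <- log10(profile$fraction[usable])
  fit <- stats::lm(y ~ x)
  structure(list(slope = unname(coef(fit)[[2L]]),
                 intercept = unname(coef(fit)[[1L]]),
                 n_points = sum(usable),
                 excluded_bins = profile$bin[!usable],
                 boundary = boundary, fit = fit),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat("slope_fit: gradient ", round(x$slope, 3), " (intercept ",
      round(x$intercept, 3), ", ", x$n_points, " bins",
      if (length(x$excluded_bins)) paste0(", ", length(x$excluded_bins),
                                          " zero-count bin(s) excluded"),
      ", x = log10 ", x$boundary, " boundary)\n", sep = "")
  invisible(x)
}

#' @export
coef.slope_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Compare an experimental list's slope against Monte Carlo random lists
#'
#' Draws `cfg$n_lists` random lists of the same size as the experimental
#' list from the universe, fits each log-log slope, and performs a
#' one-sample Student's t-test of the Monte Carlo slope sample against the
#' experimental slope as the reference value. With `tails = "one"` the
#' alternative is that the Monte Carlo slopes exceed the experimental one,
#' i.e. that the experimental list is more hub-biased (more negative slope)
#' than random.
#'
#' @param network An `interaction_network`.
#' @param universe Universe gene list the random lists are drawn from.
#' @param scheme A [make_bins()] scheme built on this network's ranking.
#' @param experimental_list [gene_list()] or character vector.
#' @param cfg An [mc_config()] (uses `n_lists` and `rng_seed`).
#' @param tails `"two"` (default) or `"one"`.
#' @param boundary Passed to [loglog_slope()].
#' @return An object of class `slope_comparison`: `experimental_slope`,
#'   `mc_slopes`, `t_statistic`, `df`, `p`, `tails`, plus the experimental
#'   profile and fit.
#' @export
slope_comparison <- function(network, universe, scheme, experimental_list,
                             cfg = mc_config(), tails = c("two", "one"),
                             boundary = c("upper", "lower")) {
  tails <- match.arg(tails)
  boundary <- match.arg(boundary)
  stopifnot(inherits(cfg, "mc_config"))
  ranking <- rank_by_degree(network)
  if (inherits(experimental_list, "gene_list"))
    experimental_list <- experimental_list$genes
  experimental_list <- unique(.norm_symbol(experimental_list))

  exp_profile <- bin_profile(scheme, ranking, experimental_list)
  exp_fit <- loglog_slope(exp_profile, scheme, boundary)

  uni_idx <- .as_universe_idx(network, universe)
  lsize <- length(experimental_list)
  if (length(uni_idx) < lsize) stop("universe smaller than the list size")
  if (!is.null(cfg$rng_seed))
    set.seed(derive_seed(cfg$rng_seed, "slope_comparison"))
  mc_slopes <- rep(NA_real_, cfg$n_lists)
  for (l in seq_len(cfg$n_lists)) {
    rnd <- network$genes[uni_idx[sample.int(length(uni_idx), lsize)]]
    sl <- tryCatch(
      loglog_slope(bin_profile(scheme, ranking, rnd), scheme, boundary)$slope,
      error = function(e) NA_real_)
    mc_slopes[[l]] <- sl
  }
  if (anyNA(mc_slopes)) {
    warning(sum(is.na(mc_slopes)), " Monte Carlo replicate(s) dropped ",
            "(slope fit failed)")
    mc_slopes <- mc_slopes[!is.na(mc_slopes)]
  }
  if (length(mc_slopes) < 10L)
    stop("fewer than 10 surviving Monte Carlo slope replicates")

  tt <- .slope_t(mc_slopes, exp_fit$slope, tails)
  structure(list(experimental_slope = exp_fit$slope,
                 mc_slopes = mc_slopes,
                 t_statistic = tt$t,
                 df = tt$df,
                 p = tt$p,
                 tails = tails,
                 experimental_profile = exp_profile,
                 experimental_fit = exp_fit,
                 scheme = scheme),
            class = "slope_comparison")
}

# One-sample Student's t of the Monte Carlo slope sample against the
# experimental slope as the reference value. tails = "one" tests whether the
# MC slopes exceed the experimental one (experimental more hub-biased).
.slope_t <- function(mc_slopes, experimental_slope, tails = "two") {
  tt <- stats::t.test(mc_slopes, mu = experimental_slope,
                      alternative = if (tails == "two") "two.sided"
                                    else "greater")
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat("slope_comparison: experimental gradient ",
      round(x$experimental_slope, 3), " vs ", length(x$mc_slopes),
      " Monte Carlo random lists (mean ", round(mean(x$mc_slopes), 3),
      ")\n", sep = "")
  cat("  one-sample t = ", round(x$t_statistic, 3), ", df = ", x$df,
      ", ", x$tails, "-tailed p = ", format(x$p), "\n", sep = "")
  invisible(x)
}

#' Plot a slope comparison (bin occupancies on a log-log scale)
#'
#' Experimental per-bin fractions as filled diamonds with the fitted
#' regression line; the mean Monte Carlo random-list fraction per bin as
#' open triangles.
#'
#' @param x A [slope_comparison()] result.
#' @param ... Passed to [plot()].
#' @export
plot.slope_comparison <- function(x, ...) {
  sch <- x$scheme
  bx <- if (x$experimental_fit$boundary == "upper") sch$hi else sch$lo
  pf <- x$experimental_profile
  usable <- pf$count > 0L
  plot(log10(bx[usable]), log10(pf$fraction[usable]), pch = 18, cex = 1.4,
       xlab = "log10 gene-rank bin boundary",
       ylab = "log10 fraction of list in bin", ...)
  graphics::abline(a = x$experimental_fit$intercept,
                   b = x$experimental_fit$slope, lty = 2)
  graphics::points(log10(bx),
                   rep(log10(1 / nrow(sch)), nrow(sch)), pch = 2)
  invisible(x)
}
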