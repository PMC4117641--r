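# Synthetic data with known ground truth: a heavy-tailed interaction
# network (preferential-attachment growth), an orthologue-universe subset,
# a GWAS-like candidate list, and a screen-hit list with a controllable
# planted degree of +1 interactome overlap. Every pipeline stage can be
# exercised against this generator without external downloads.
#
# Defaults are scaled-down stand-ins for the real substrate: 2000 genes
# (vs ~14000 in a BioGrid human snapshot), a 40% orthologue universe
# (800 genes vs 7970), attachment degree 3 (mean degree ~6, leaf-heavy like
# curated physical-interaction networks), a 15-gene GWAS-like list (keeps
# the GWAS +1 footprint near 4-5% of the network, the proportion seen in
# the real data) and 40 screen hits.

#' Specification for a synthetic study
#'
#' @param n_genes Number of genes in the network (default 2000).
#' @param m Edges each newly attached gene brings (default 3).
#' @param universe_fraction Fraction of genes in the orthologue universe
#'   (default 0.4).
#' @param gwas_size GWAS-like candidate list size (default 15; scaled so
#'   the GWAS +1 interactome covers a few percent of the network).
#' @param hit_size Screen-hit list size (default 40).
#' @param enrichment Probability that a hit is planted from the pool of
#'   genes whose +1 interactomes genuinely overlap the GWAS +1 interactome
#'   (default 0.5; 0 = pure null, 1 = all hits carry signal).
#' @param rng_seed Integer seed (default 1).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 2000L, m = 3L, universe_fraction = 0.4,
                           gwas_size = 15L, hit_size = 40L,
                           enrichment = 0.5, rng_seed = 1L) {
  n_genes <- as.integer(n_genes); m <- as.integer(m)
  gwas_size <- as.integer(gwas_size); hit_size <- as.integer(hit_size)
  stopifnot(m >= 1L, n_genes >= m + 1L,
            universe_fraction > 0, universe_fraction <= 1,
            gwas_size + hit_size <= n_genes,
            enrichment >= 0, enrichment <= 1)
  structure(list(n_genes = n_genes, m = m,
                 universe_fraction = universe_fraction,
                 gwas_size = gwas_size, hit_size = hit_size,
                 enrichment = enrichment, rng_seed = as.integer(rng_seed)),
            class = "synthetic_spec")
}

#' Generate a heavy-tailed synthetic interaction network
#'
#' Growth process: a fully connected nucleus of `m + 1` genes, then each
#' subsequent gene attaches to `m` distinct existing genes chosen with
#' probability proportional to their current degree. The resulting degree
#' distribution is heavy-tailed, reproducing the hub structure that makes
#' screen-hit lists connectivity-biased. Gene symbols are `G000001`,
#' `G000002`, ...
#'
#' @param spec A [synthetic_spec()].
#' @return An `interaction_network` with exactly
#'   `m * (n_genes - m - 1) + m * (m + 1) / 2` edges.
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(derive_seed(spec$rng_seed, "generate_network"))
  n <- spec$n_genes; m <- spec$m
  n_edges <- m * (n - m - 1L) + (m * (m + 1L)) %/% 2L
  from <- integer(n_edges); to <- integer(n_edges)
  deg <- integer(n)
  # nucleus: complete graph on genes 1..m+1
  k <- 0L
  for (i in seq_len(m)) for (j in seq.int(i + 1L, m + 1L)) {
    k <- k + 1L; from[[k]] <- i; to[[k]] <- j
  }
  deg[seq_len(m + 1L)] <- m
  for (v in if (n >= m + 2L) seq.int(m + 2L, n) else integer(0)) {
    existing <- seq_len(v - 1L)
    targets <- existing[sample.int(v - 1L, m, prob = deg[existing])]
    from[k + seq_len(m)] <- v
    to[k + seq_len(m)] <- targets
    k <- k + m
    deg[targets] <- deg[targets] + 1L
    deg[[v]] <- m
  }
  syms <- sprintf("G%06d", seq_len(n))
  .network_from_edges(cbind(syms[from], syms[to]))
}

#' Plant GWAS, hit and universe lists on a synthetic network
#'
#' The universe is a uniform random subset of the genes; the GWAS-like list
#' is a uniform random draw from the genes. Each screen hit is, with
#' probability `spec$enrichment`, drawn from the "enriched pool" — the top
#' decile of universe genes ranked by their +1 interactome overlap with the
#' GWAS +1 interactome normalised by their own +1 size (size-normalisation
#' avoids trivially planting hubs, so recovering the plant demonstrates the
#' overlap signal rather than the connectivity bias) — and otherwise drawn
#' uniformly from the remaining universe. GWAS genes are excluded from the
#' hit pools, mirroring screens whose hits share no identity with the GWAS
#' list.
#'
#' @param network An `interaction_network` from [generate_network()].
#' @param spec The matching [synthetic_spec()].
#' @return A list with elements `gwas`, `hits`, `universe` (each a
#'   [gene_list()]) and `truth` (class `planted_truth`: character vectors
#'   `enriched_hits` and `null_hits`, disjoint, union = hit list).
#' @export
plant_lists <- function(network, spec) {
  stopifnot(inherits(network, "interaction_network"),
            inherits(spec, "synthetic_spec"))
  set.seed(derive_seed(spec$rng_seed, "plant_lists"))
  genes <- network$genes
  n <- length(genes)
  uni <- sort(sample(genes, max(1L, floor(spec$universe_fraction * n))))
  gwas <- sort(sample(genes, spec$gwas_size))
  gwas_p1 <- plus_one(network, gwas)
  gwas_mask <- logical(n)
  gwas_mask[match(gwas_p1$members, genes)] <- TRUE

  cand <- setdiff(uni, gwas)
  ci <- match(cand, genes)
  score <- vapply(ci, function(gi) {
    p1 <- .p1_members_idx(network$adj, gi)
    sum(gwas_mask[p1]) / length(p1)
  }, numeric(1L))
  ord <- order(-score, cand)  # deterministic tie-break by symbol
  pool_n <- max(1L, floor(length(cand) / 10))
  pool <- cand[ord[seq_len(pool_n)]]
  rest <- cand[ord[-seq_len(pool_n)]]

  enriched_flag <- stats::rbinom(spec$hit_size, 1L, spec$enrichment) == 1L
  n_enr <- sum(enriched_flag)
  if (n_enr > length(pool))
    stop("enriched pool (", length(pool), ") smaller than required draws (",
         n_enr, ")")
  if (spec$hit_size - n_enr > length(rest))
    stop("null pool too small for ", spec$hit_size - n_enr, " draws")
  enriched <- if (n_enr) pool[sample.int(length(pool), n_enr)] else character()
  nulls <- if (spec$hit_size - n_enr)
    rest[sample.int(length(rest), spec$hit_size - n_enr)] else character()
  hits <- character(spec$hit_size)
  hits[enriched_flag] <- enriched
  hits[!enriched_flag] <- nulls

  list(gwas = gene_list(gwas, "synthetic_gwas", "plant_lists"),
       hits = gene_list(hits, "synthetic_hits", "plant_lists"),
       universe = gene_list(uni, "synthetic_universe", "plant_lists"),
       truth = structure(list(enriched_hits = enriched, null_hits = nulls),
                         class = "planted_truth"))
}

#' Write a synthetic fixture bundle to disk
#'
#' Emits a BioGrid-TAB3-compatible interaction file, one-symbol-per-line
#' gene lists, an orthology table (identity 100, consistency 1 for every
#' universe gene, worm symbols prefixed `CEL-`), a planted-truth table and
#' a `manifest.txt` of key=value pairs including the rng seed. Re-reading
#' the bundle through the package's readers reconstructs identical objects.
#'
#' @param network An `interaction_network`.
#' @param lists The list returned by [plant_lists()].
#' @param dir Output directory (created if needed).
#' @param spec The [synthetic_spec()] used (recorded in the manifest).
#' @return `dir`, invisibly.
#' @seealso [read_fixture_bundle()]
#' @export
write_fixture_bundle <- function(network, lists, dir, spec = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create fixture directory: ", dir)
  el <- network$edges
  tab <- data.frame(
    id = seq_len(nrow(el)),
    a = network$genes[el[, 1L]],
    b = network$genes[el[, 2L]],
    oa = 9606L, ob = 9606L,
    type = "physical",
    src = "synthetic",
    stringsAsFactors = FALSE
  )
  names(tab) <- c("#BioGRID Interaction ID",
                  "Official Symbol Interactor A",
                  "Official Symbol Interactor B",
                  "Organism ID Interactor A", "Organism ID Interactor B",
                  "Experimental System Type", "Source Database")
  utils::write.table(tab, file.path(dir, "interactions.tab3.txt"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in c("gwas", "hits", "universe"))
    writeLines(lists[[nm]]$genes, file.path(dir, paste0(nm, ".txt")))
  uni <- lists$universe$genes
  orth <- data.frame(worm_gene = paste0("CEL-", uni), human_gene = uni,
                     percent_identity = 100, consistency_score = 1)
  utils::write.table(orth, file.path(dir, "orthology.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- data.frame(
    gene = c(lists$truth$enriched_hits, lists$truth$null_hits),
    planted = rep(c("enriched", "null"),
                  c(length(lists$truth$enriched_hits),
                    length(lists$truth$null_hits))))
  utils::write.table(truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- c(
    if (!is.null(spec)) paste0(names(unclass(spec)), "=", unlist(spec)),
    paste0("n_network_genes=", length(network$genes)),
    paste0("n_network_edges=", nrow(el)))
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Read a fixture bundle written by [write_fixture_bundle()]
#'
#' @param dir Bundle directory.
#' @return A list with `network`, `gwas`, `hits`, `universe`, `truth`,
#'   `orthology` and `manifest` (named character vector).
#' @export
read_fixture_bundle <- function(dir) {
  net <- build_network(read_biogrid(file.path(dir, "interactions.tab3.txt")))
  manifest_lines <- readLines(file.path(dir, "manifest.txt"), warn = FALSE)
  kv <- strsplit(manifest_lines, "=", fixed = TRUE)
  manifest <- vapply(kv, `[[`, "", 2L)
  names(manifest) <- vapply(kv, `[[`, "", 1L)
  truth_tab <- read.delim(file.path(dir, "truth.tsv"),
                          stringsAsFactors = FALSE)
  list(network = net,
       gwas = read_gene_list(file.path(dir, "gwas.txt"), "synthetic_gwas"),
       hits = read_gene_list(file.path(dir, "hits.txt"), "synthetic_hits"),
       universe = read_gene_list(file.path(dir, "universe.txt"),
                                 "synthetic_universe"),
       truth = structure(
         list(enriched_hits = truth_tab$gene[truth_tab$planted == "enriched"],
              null_hits = truth_tab$gene[truth_tab$planted == "null"]),
         class = "planted_truth"),
       orthology = read_orthology(file.path(dir, "orthology.tsv")),
       manifest = manifest)
}
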