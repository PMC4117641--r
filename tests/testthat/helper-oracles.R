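# Shared fixtures and independent oracles. Oracles are written from first
# principles (adjacency matrices, exhaustive enumeration) so they share no
# code path with the implementation they check.

records <- function(a, b) {
  data.frame(gene_a = a, gene_b = b, stringsAsFactors = FALSE)
}

# A 12-gene toy network with a hub (H), a triangle, a chain and two
# low-degree satellites; small enough for exhaustive enumeration.
toy_network <- function() {
  build_network(records(
    c("H", "H", "H", "H", "A", "B", "C", "D", "E", "F", "K", "L"),
    c("A", "B", "C", "K", "B", "C", "D", "E", "F", "G", "L", "M")))
}

# Degree oracle: dense adjacency matrix built independently of igraph.
degree_oracle <- function(rec) {
  a <- toupper(trimws(rec$gene_a)); b <- toupper(trimws(rec$gene_b))
  genes <- sort(unique(c(a, b)))
  M <- matrix(0L, length(genes), length(genes),
              dimnames = list(genes, genes))
  for (i in seq_along(a)) {
    if (a[i] != b[i]) M[a[i], b[i]] <- M[b[i], a[i]] <- 1L
  }
  rowSums(M)
}

# Exact distribution of the overlap between a random size-matched +1
# interactome and a fixed gene set, by exhaustive enumeration of every
# achievable draw sequence. Universe genes are drawn uniformly without
# replacement; a drawn gene's new members enter en bloc, except the final
# contribution, which is a uniform random subset of the needed size (its
# overlap count is therefore hypergeometric). Returns P(overlap = k) as a
# vector indexed 0..max.
exact_overlap_dist <- function(network, universe, target, gwas_members) {
  adj <- network$adj
  uni <- match(toupper(universe), network$genes)
  stopifnot(!anyNA(uni))
  gmask <- network$genes %in% toupper(gwas_members)
  probs <- numeric(target + 1L)  # index k+1 = P(overlap == k)

  recurse <- function(mem, count, ov, remaining, pr) {
    p_draw <- pr / length(remaining)
    for (g in remaining) {
      add <- setdiff(c(g, adj[[g]]), mem)
      nn <- length(add)
      rest <- setdiff(remaining, g)
      if (count + nn > target) {
        need <- target - count
        gA <- sum(gmask[add])
        for (x in 0:min(gA, need)) {
          px <- stats::dhyper(x, gA, nn - gA, need)
          if (px > 0) probs[ov + x + 1L] <<- probs[ov + x + 1L] + p_draw * px
        }
      } else if (count + nn == target) {
        k <- ov + sum(gmask[add])
        probs[k + 1L] <<- probs[k + 1L] + p_draw
      } else {
        if (length(rest) == 0L) stop("oracle: universe exhausted")
        recurse(c(mem, add), count + nn, ov + sum(gmask[add]), rest, p_draw)
      }
    }
  }
  recurse(integer(0), 0L, 0L, uni, 1)
  stopifnot(abs(sum(probs) - 1) < 1e-9)
  probs
}

# Small synthetic study shared by several tests (cheap to regenerate).
small_study <- function(seed = 42L, enrichment = 0.5) {
  spec <- synthetic_spec(n_genes = 300L, m = 2L, universe_fraction = 0.5,
                         gwas_size = 8L, hit_size = 12L,
                         enrichment = enrichment, rng_seed = seed)
  net <- generate_network(spec)
  lists <- plant_lists(net, spec)
  list(spec = spec, net = net, lists = lists)
}
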