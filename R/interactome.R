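# +1 interactomes: a seed gene set together with every gene whose product
# physically interacts with a seed's product. Seeds are always members of
# their own +1 interactome; overlap between two interactomes counts genes,
# not interactions.

# Index-level neighbourhood closure; the workhorse for the Monte Carlo loops.
.p1_members_idx <- function(adj, seed_idx) {
  unique(c(seed_idx, unlist(adj[seed_idx], use.names = FALSE)))
}

#' Build a +1 interactome
#'
#' @param network An `interaction_network` from [build_network()].
#' @param seeds A [gene_list()] or character vector of seed gene symbols.
#'   Seeds absent from the network are excluded and reported in
#'   `dropped_seeds`; it is an error for no seed to be present.
#' @return An object of class `plus_one_interactome`: list with `seeds`
#'   (seeds present in the network), `members` (seeds plus all their
#'   distinct neighbours, sorted), `size` (`length(members)`) and
#'   `dropped_seeds`.
#' @examples
#' net <- build_network(data.frame(gene_a = c("A", "B"), gene_b = c("B", "C")))
#' plus_one(net, c("A", "C"))$members  # A B C
#' @export
plus_one <- function(network, seeds) {
  stopifnot(inherits(network, "interaction_network"))
  if (inherits(seeds, "gene_list")) seeds <- seeds$genes
  seeds <- unique(.norm_symbol(seeds))
  idx <- match(seeds, network$genes)
  dropped <- seeds[is.na(idx)]
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L)
    stop("none of the ", length(seeds), " seed gene(s) is in the network; ",
         "an empty +1 interactome is undefined")
  members <- sort(network$genes[.p1_members_idx(network$adj, idx)])
  structure(list(seeds = network$genes[idx], members = members,
                 size = length(members), dropped_seeds = dropped),
            class = "plus_one_interactome")
}

#' @export
print.plus_one_interactome <- function(x, ...) {
  cat("plus_one_interactome: ", length(x$seeds), " seed(s), size ",
      x$size, " (members incl. seeds)",
      if (length(x$dropped_seeds)) paste0("; ", length(x$dropped_seeds),
                                          " seed(s) not in network"),
      "\n", sep = "")
  invisible(x)
}

#' Gene-level overlap between two +1 interactomes
#'
#' @param a,b `plus_one_interactome` objects (or anything with a `members`
#'   character element).
#' @return Integer count of shared member genes.
#' @export
overlap <- function(a, b) {
  length(intersect(a$members, b$members))
}
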