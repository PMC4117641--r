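# Orthologue selection and enrichment. A screen performed in the worm is
# mapped onto human genes: each worm gene may have several candidate human
# orthologues, each with a percent amino-acid identity and a consistency
# score in [0,1] (1 = the orthology call is supported by every source
# database). One human gene is selected per worm gene.

#' Read an orthology candidate table
#'
#' Tab-separated columns: `worm_gene`, `human_gene`, `percent_identity`
#' (0-100), `consistency_score` (0-1).
#'
#' @param path Path to the TSV file.
#' @return A data frame of orthology candidates, symbols uppercased.
#' @export
read_orthology <- function(path) {
  if (!file.exists(path)) stop("orthology table not found: ", path)
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("worm_gene", "human_gene", "percent_identity", "consistency_score")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("orthology table missing column(s): ", paste(miss, collapse = ", "))
  tab$worm_gene <- .norm_symbol(tab$worm_gene)
  tab$human_gene <- .norm_symbol(tab$human_gene)
  .validate_orthology(tab)
}

.validate_orthology <- function(tab) {
  if (any(tab$percent_identity < 0 | tab$percent_identity > 100))
    stop("percent_identity outside [0, 100]")
  if (any(tab$consistency_score < 0 | tab$consistency_score > 1))
    stop("consistency_score outside [0, 1]")
  tab
}

#' Select one human orthologue per worm gene
#'
#' Candidates below the identity threshold are discarded; among the
#' survivors the candidate with the highest percent identity wins, identity
#' ties are broken by the highest consistency score, and any residual tie is
#' broken by the lexicographically smallest human symbol (so selection is
#' deterministic; residual ties are reported via a message).
#'
#' @param candidates Data frame of candidates as from [read_orthology()].
#' @param min_identity Minimum percent amino-acid identity (default 25).
#' @return An object of class `orthology_map`: list with `mapping` (named
#'   character vector, worm gene -> chosen human gene) and `unmapped`
#'   (character vector of worm genes with no surviving candidate).
#' @examples
#' cand <- data.frame(worm_gene = c("W1", "W1", "W2"),
#'                    human_gene = c("H1", "H2", "H3"),
#'                    percent_identity = c(40, 55, 20),
#'                    consistency_score = c(1, 0.5, 1))
#' select_orthologues(cand)  # W1 -> H2, W2 unmapped
#' @export
select_orthologues <- function(candidates, min_identity = 25) {
  candidates <- .validate_orthology(candidates)
  worm_genes <- unique(.norm_symbol(candidates$worm_gene))
  ok <- candidates$percent_identity >= min_identity
  surv <- candidates[ok, , drop = FALSE]

  mapping <- character(0)
  residual_ties <- character(0)
  for (w in intersect(worm_genes, surv$worm_gene)) {
    cc <- surv[surv$worm_gene == w, , drop = FALSE]
    cc <- cc[cc$percent_identity == max(cc$percent_identity), , drop = FALSE]
    cc <- cc[cc$consistency_score == max(cc$consistency_score), , drop = FALSE]
    hs <- sort(unique(cc$human_gene))
    if (length(hs) > 1L) residual_ties <- c(residual_ties, w)
    mapping[[w]] <- hs[[1L]]
  }
  if (length(residual_ties))
    message("residual orthology ties broken lexicographically for: ",
            paste(residual_ties, collapse = ", "))
  structure(list(mapping = mapping,
                 unmapped = setdiff(worm_genes, names(mapping))),
            class = "orthology_map")
}

#' @export
print.orthology_map <- function(x, ...) {
  cat("orthology_map: ", length(x$mapping), " worm gene(s) mapped, ",
      length(x$unmapped), " unmapped\n", sep = "")
  invisible(x)
}

#' Binomial orthologue enrichment test
#'
#' Tests whether a screen's hits are enriched for genes with orthologues in
#' the other species. With `k` of `n` hits having an orthologue, and a
#' genome-wide orthologue fraction `p0` (for the human/worm comparison,
#' 7970 of ~20000 protein-coding genes), the exact one-sided upper-tail
#' binomial probability \eqn{P(X \ge k)} for \eqn{X \sim Bin(n, p0)} is
#' returned. The tail is an exact summation of binomial terms; no normal
#' approximation is used.
#'
#' @param k Number of successes (hits with an orthologue), `0 <= k <= n`.
#' @param n Number of trials (hits).
#' @param p0 Genome-wide success probability, in (0, 1).
#' @return The upper-tail p-value, in (0, 1].
#' @examples
#' orthologue_enrichment(61, 78, 7970 / 20000)  # ~6e-12
#' @export
orthologue_enrichment <- function(k, n, p0) {
  stopifnot(length(k) == 1L, length(n) == 1L, length(p0) == 1L)
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1)
    stop("success probability p0 must lie strictly inside (0, 1)")
  k <- as.integer(k); n <- as.integer(n)
  if (k < 0L || n < 0L || k > n) stop("require 0 <= k <= n")
  if (k == 0L) return(1)
  # pbinom's upper tail sums the individual binomial terms exactly
  stats::pbinom(k - 1L, size = n, prob = p0, lower.tail = FALSE)
}
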