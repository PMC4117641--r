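# Ingest: BioGrid tab-delimited releases, generic edge lists, gene lists.
# Gene identity is case-insensitive throughout; symbols are uppercased at
# ingest so that mixed-case sources agree.

# Column names accepted for each required field, covering the TAB2 and TAB3
# dialects. Resolution is by header name, never by position.
.biogrid_cols <- list(
  gene_a     = c("Official Symbol Interactor A", "OFFICIAL_SYMBOL_A"),
  gene_b     = c("Official Symbol Interactor B", "OFFICIAL_SYMBOL_B"),
  organism_a = c("Organism ID Interactor A", "Organism Interactor A",
                 "ORGANISM_A_ID"),
  organism_b = c("Organism ID Interactor B", "Organism Interactor B",
                 "ORGANISM_B_ID"),
  category   = c("Experimental System Type", "EXPERIMENTAL_SYSTEM_TYPE")
)

.norm_symbol <- function(x) toupper(trimws(x))

#' Read an interaction database file
#'
#' Reads a BioGrid tab-delimited release (TAB2 or TAB3 dialect, recognised by
#' header names) or a headerless two-column edge list, and returns interaction
#' records filtered to one organism and one interaction category.
#'
#' @param path Path to a tab-delimited interaction file.
#' @param taxid NCBI taxonomy id both interactors must have (default 9606,
#'   human). Ignored for two-column edge lists, which carry no organism.
#' @param category Interaction category to keep: `"physical"` (default) or
#'   `"genetic"`. Two-column edge lists default to physical.
#' @return A data frame of interaction records with columns `gene_a`,
#'   `gene_b`, `organism_a`, `organism_b`, `interaction_category` and
#'   `source_version`. Duplicate rows are retained; deduplication is the job
#'   of [build_network()].
#' @examples
#' tf <- tempfile()
#' writeLines(c("A\tB", "B\tC"), tf)
#' read_biogrid(tf)
#' @seealso [build_network()]
#' @export
read_biogrid <- function(path, taxid = 9606,
                         category = c("physical", "genetic")) {
  category <- match.arg(category)
  if (!file.exists(path)) stop("interaction file not found: ", path)

  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty interaction file: ", path)
    return(.empty_records())
  }
  header <- strsplit(sub("^#", "", lines[[1L]]), "\t", fixed = TRUE)[[1L]]

  is_biogrid <- any(.biogrid_cols$gene_a %in% header)
  if (!is_biogrid) {
    nfield <- length(strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]])
    if (nfield != 2L) {
      missing_col <- .biogrid_cols$gene_a[[1L]]
      for (f in names(.biogrid_cols)) {
        if (!any(.biogrid_cols[[f]] %in% header)) {
          missing_col <- .biogrid_cols[[f]][[1L]]
          break
        }
      }
      stop("unrecognised interaction file header: missing column '",
           missing_col, "' and not a 2-column edge list")
    }
    # Generic edge list: no header, no organism columns.
    parts <- strsplit(lines, "\t", fixed = TRUE)
    rec <- data.frame(
      gene_a = .norm_symbol(vapply(parts, `[[`, "", 1L)),
      gene_b = .norm_symbol(vapply(parts, `[[`, "", 2L)),
      organism_a = as.integer(taxid), organism_b = as.integer(taxid),
      interaction_category = "physical",
      source_version = "edge-list",
      stringsAsFactors = FALSE
    )
    return(.validate_records(rec, path))
  }

  tab <- read.delim(text = c(paste(header, collapse = "\t"), lines[-1L]),
                    header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE)
  col_of <- function(field) {
    hit <- intersect(.biogrid_cols[[field]], names(tab))
    if (length(hit) == 0L)
      stop("unrecognised interaction file header: missing column '",
           .biogrid_cols[[field]][[1L]], "'")
    tab[[hit[[1L]]]]
  }
  rec <- data.frame(
    gene_a = .norm_symbol(col_of("gene_a")),
    gene_b = .norm_symbol(col_of("gene_b")),
    organism_a = suppressWarnings(as.integer(col_of("organism_a"))),
    organism_b = suppressWarnings(as.integer(col_of("organism_b"))),
    interaction_category = tolower(trimws(col_of("category"))),
    source_version = if ("Source Database" %in% names(tab))
      as.character(tab[["Source Database"]]) else basename(path),
    stringsAsFactors = FALSE
  )
  keep <- !is.na(rec$organism_a) & !is.na(rec$organism_b) &
    rec$organism_a == taxid & rec$organism_b == taxid &
    rec$interaction_category == category
  rec <- rec[keep, , drop = FALSE]
  if (nrow(rec) == 0L)
    warning("no interactions left after filtering (taxid = ", taxid,
            ", category = ", category, ")")
  .validate_records(rec, path)
}

.empty_records <- function() {
  data.frame(gene_a = character(), gene_b = character(),
             organism_a = integer(), organism_b = integer(),
             interaction_category = character(),
             source_version = character(), stringsAsFactors = FALSE)
}

.validate_records <- function(rec, path) {
  bad <- !nzchar(rec$gene_a) | !nzchar(rec$gene_b) |
    rec$gene_a == "-" | rec$gene_b == "-"
  if (any(bad)) {
    warning(sum(bad), " record(s) with missing gene symbols dropped")
    rec <- rec[!bad, , drop = FALSE]
  }
  stopifnot(all(rec$interaction_category %in% c("physical", "genetic")))
  rownames(rec) <- NULL
  rec
}

#' Build an interaction network from interaction records
#'
#' Assembles an undirected simple graph: duplicate records and reversed
#' duplicates collapse to a single edge, and self-loops are recorded as
#' metadata but never counted as neighbours (a gene is always a member of its
#' own +1 interactome through the seed rule, so counting a self-edge would
#' double-count it).
#'
#' @param records A data frame with character columns `gene_a` and `gene_b`
#'   (as returned by [read_biogrid()]; extra columns are ignored).
#' @return An object of class `interaction_network`: a list with elements
#'   `genes` (character), `degree` (named integer, distinct-neighbour counts),
#'   `adj` (adjacency list of integer gene indices), `edges` (two-column
#'   integer matrix, one row per undirected edge), `self_loops` (character)
#'   and `igraph` (the underlying [igraph::igraph] object, loop-free).
#' @examples
#' net <- build_network(data.frame(gene_a = c("A", "B", "A"),
#'                                 gene_b = c("B", "A", "A")))
#' net$degree
#' net$self_loops
#' @export
build_network <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("gene_a", "gene_b") %in% names(records)))
  a <- .norm_symbol(records$gene_a)
  b <- .norm_symbol(records$gene_b)
  stopifnot(all(nzchar(a)), all(nzchar(b)))
  loops <- sort(unique(a[a == b]))
  keep <- a != b
  .network_from_edges(cbind(a[keep], b[keep]), self_loops = loops)
}

# Internal constructor from a 2-column character (or integer-index) edge
# matrix; igraph does the dedup/simplification, then a plain adjacency list
# is cached for the Monte Carlo inner loops.
.network_from_edges <- function(el, self_loops = character()) {
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  # a gene known only from a self-loop record is still a network member
  # (degree 0): keep it as an isolated vertex
  orphans <- setdiff(self_loops, igraph::V(g)$name)
  if (length(orphans))
    g <- igraph::add_vertices(g, length(orphans), name = orphans)
  genes <- igraph::V(g)$name
  adj <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
  names(adj) <- NULL
  deg <- lengths(adj)
  names(deg) <- genes
  em <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(em) <- "integer"
  structure(list(genes = genes, degree = deg, adj = adj, edges = em,
                 self_loops = sort(unique(self_loops)), igraph = g),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("interaction_network: ", length(x$genes), " genes, ",
      nrow(x$edges), " edges",
      if (length(x$self_loops)) paste0(" (", length(x$self_loops),
                                       " self-loop gene(s) recorded)"),
      "\n", sep = "")
  cat("  mean degree ", round(mean(x$degree), 2),
      ", max degree ", max(x$degree), " (", names(which.max(x$degree)), ")\n",
      sep = "")
  invisible(x)
}

.gene_index <- function(network, genes) {
  idx <- match(.norm_symbol(genes), network$genes)
  names(idx) <- genes
  idx
}

#' Create a gene list
#'
#' @param genes Character vector of gene symbols; uppercased, trimmed, and
#'   deduplicated (first occurrence wins) with a warning.
#' @param name Short label for the list.
#' @param provenance Free-text origin of the list.
#' @return An object of class `gene_list`.
#' @export
gene_list <- function(genes, name = "gene_list", provenance = "") {
  genes <- .norm_symbol(genes)
  genes <- genes[nzchar(genes)]
  if (anyDuplicated(genes)) {
    warning("duplicate gene symbols collapsed in list '", name, "'")
    genes <- genes[!duplicated(genes)]
  }
  if (length(genes) == 0L) stop("gene list '", name, "' is empty")
  structure(list(name = name, genes = genes, provenance = provenance),
            class = "gene_list")
}

#' @export
print.gene_list <- function(x, ...) {
  cat("gene_list '", x$name, "': ", length(x$genes), " genes\n", sep = "")
  cat(" ", paste(head(x$genes, 8L), collapse = ", "),
      if (length(x$genes) > 8L) ", ...", "\n", sep = "")
  invisible(x)
}

#' Read a gene list file
#'
#' One symbol per line; anything after `#` is a comment; blank lines are
#' skipped; duplicates (case-insensitive) are collapsed with a warning.
#'
#' @param path Path to the file.
#' @param name Label for the list (defaults to the file name).
#' @return A [gene_list()].
#' @export
read_gene_list <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("gene list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  gene_list(lines[nzchar(lines)], name = name, provenance = path)
}

#' Write and re-read a per-gene overlap results table
#'
#' The table mirrors the screen-versus-GWAS reporting format: one row per
#' gene with its empirical p-value, the direction of the +1 interactome
#' overlap relative to the Monte Carlo null, and a flag for genes whose
#' products interact directly with a GWAS-list gene. Rows are sorted by
#' ascending p, ties broken by gene symbol.
#'
#' @param results A data frame (or `overlap_screen` object) with columns
#'   `gene`, `observed`, `n_right`, `n_left`, `p`, `direction` and
#'   `direct_interactor` (missing numeric columns are permitted for tables
#'   assembled from published values).
#' @param path Output path; a tab-separated file is written.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  df <- as.data.frame(results)
  stopifnot(all(c("gene", "p", "direction") %in% names(df)))
  df <- df[order(df$p, df$gene), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) stop("results table not found: ", path)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
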