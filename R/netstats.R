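#' Hub genes by centrality in the confidence-filtered PPI subgraph
#'
#' Filters the PPI edge table to combined confidence >= `config$ppi_min`
#' (scores on a 0-1000 scale are auto-detected and rescaled to 0-1),
#' canonicalizes the undirected edges (duplicates and self-loops dropped),
#' induces the subgraph on `query_genes`, and ranks nodes by the chosen
#' centrality, descending, ties broken by ascending id. Every query gene is
#' a vertex; genes untouched by any retained edge are isolated, get
#' degree = betweenness = 0 and closeness 0, and therefore rank last.
#' Betweenness and closeness are computed on the unweighted graph
#' (confidence is a filter, not a weight).
#'
#' @param edges data.frame in the `ppi` schema (`protein_a`, `protein_b`,
#'   `combined_score`).
#' @param query_genes character vector restricting the node set.
#' @param top_n how many hub genes to return (default `config$n_hub`).
#' @param measure `"degree"` (default), `"betweenness"` or `"closeness"`.
#' @param config a [pipeline_config()].
#' @return list with `hubs` (character vector, length `<= top_n`),
#'   `table` (full ranked data.frame with all three centralities),
#'   `n_nodes`, `n_edges` (the induced, filtered graph), and
#'   `n_edges_below_confidence`.
#' @export
hub_genes <- function(edges, query_genes, top_n = config$n_hub,
                      measure = config$hub_measure,
                      config = pipeline_config()) {
  stopifnot(all(c("protein_a", "protein_b", "combined_score") %in%
                  names(edges)))
  measure <- match.arg(measure, c("degree", "betweenness", "closeness"))
  query_genes <- unique(query_genes)
  score <- edges$combined_score
  if (length(score) > 0L && max(score, na.rm = TRUE) > 1) score <- score / 1000
  keep <- !is.na(score) & score >= config$ppi_min
  n_below <- sum(!keep)
  ed <- edges[keep, , drop = FALSE]
  ed <- ed[ed$protein_a != ed$protein_b, , drop = FALSE]
  ed <- ed[ed$protein_a %in% query_genes & ed$protein_b %in% query_genes,
           , drop = FALSE]
  if (nrow(ed) > 0L) {
    a <- pmin(ed$protein_a, ed$protein_b)
    b <- pmax(ed$protein_a, ed$protein_b)
    ed <- unique(data.frame(protein_a = a, protein_b = b,
                            stringsAsFactors = FALSE))
  }

  if (length(query_genes) == 0L) {
    warning("empty PPI graph", call. = FALSE)
    return(list(hubs = character(0),
                table = data.frame(gene = character(0), degree = numeric(0),
                                   betweenness = numeric(0),
                                   closeness = numeric(0)),
                n_nodes = 0L, n_edges = 0L,
                n_edges_below_confidence = n_below))
  }

  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                     vertices = sort(query_genes))
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE)
  ## harmonic-free classical closeness is undefined for isolates and
  ## across components; set those to 0 so they rank last
  cls <- suppressWarnings(igraph::closeness(g, mode = "all"))
  cls[!is.finite(cls) | deg == 0] <- 0

  tab <- data.frame(gene = igraph::V(g)$name, degree = unname(deg),
                    betweenness = unname(btw), closeness = unname(cls),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab[[measure]], tab$gene), ]
  rownames(tab) <- NULL
  tab$rank <- seq_len(nrow(tab))
  list(hubs = utils::head(tab$gene, top_n), table = tab,
       n_nodes = sum(deg > 0), n_edges = nrow(ed),
       n_edges_below_confidence = n_below)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the query hits it more often than
#' expected by drawing `n = |query|` genes from a universe of size `N`
#' without replacement: the upper-tail probability
#' `P(X >= k)` with `k` query hits in a set of `K` universe members,
#' computed with [stats::phyper()]. P-values are BH-adjusted across the
#' tested sets; sets with no universe member are skipped.
#'
#' @param query character vector of genes (must lie within `universe`).
#' @param gene_sets named list of character vectors (e.g. [read_gmt()]).
#' @param universe character vector; the background gene population.
#' @return data.frame sorted by p-value (ties by term id): `term_id`,
#'   `k`, `K`, `n`, `N`, `p_value`, `fdr`.
#' @export
#' @examples
#' enrich(c("a", "b", "c", "d"),
#'        list(s1 = c("a", "b", "c", "d", "e")),
#'        letters[1:10])  # p = 5/210
enrich <- function(query, gene_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0L)
    stop("query gene(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))

  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    members <- intersect(unique(gene_sets[[nm]]), universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(query, members))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = nm, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(res))
    return(data.frame(term_id = character(0), k = integer(0),
                      K = integer(0), n = integer(0), N = integer(0),
                      p_value = numeric(0), fdr = numeric(0)))
  res$fdr <- bh_adjust(res$p_value)
  res <- res[order(res$p_value, res$term_id), ]
  rownames(res) <- NULL
  res
}

#' Top enriched terms
#'
#' Convenience report: the `top` most significant terms at raw `p <
#' p_cutoff` from an [enrich()] result.
#'
#' @param enrichment data.frame from [enrich()].
#' @param top maximum number of terms.
#' @param p_cutoff significance level on the raw p-value.
#' @return subset of `enrichment`.
#' @export
top_terms <- function(enrichment, top = 10L, p_cutoff = 0.05) {
  utils::head(enrichment[enrichment$p_value < p_cutoff, , drop = FALSE],
              top)
}
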