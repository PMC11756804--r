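#' Assemble lncRNA-miRNA-mRNA ceRNA triplets
#'
#' Natural join of the two directed pair sets on the shared miRNA. Each
#' triplet carries the provenance scores of both pairs and must satisfy
#' the ceRNA direction invariant: lncRNA and miRNA opposite, miRNA and
#' mRNA opposite (hence lncRNA and mRNA co-directional) — asserted at
#' construction. miRNAs present in only one pair table are dropped and
#' reported; a miRNA whose recorded direction differs between the two
#' tables is a hard error.
#'
#' @param lnc_mir `pairs` data.frame from [lnc_mir_pairs()].
#' @param mir_mrna `pairs` data.frame from [mir_mrna_pairs()].
#' @return list with `triplets` (data.frame), `network` (a
#'   [network_export()] with the unique lncRNA-miRNA and miRNA-mRNA
#'   edges), `composition` (named counts of unique lncRNAs, miRNAs,
#'   mRNAs in at least one triplet) and `dropped_mirnas`.
#' @export
assemble_cerna <- function(lnc_mir, mir_mrna) {
  stopifnot(all(c("lncrna_id", "mirna_id", "lnc_direction",
                  "mir_direction") %in% names(lnc_mir)),
            all(c("mirna_id", "mrna_id", "mir_direction",
                  "mrna_direction") %in% names(mir_mrna)))

  shared <- intersect(lnc_mir$mirna_id, mir_mrna$mirna_id)
  dropped <- sort(setdiff(union(lnc_mir$mirna_id, mir_mrna$mirna_id),
                          shared))
  for (m in shared) {
    d1 <- unique(lnc_mir$mir_direction[lnc_mir$mirna_id == m])
    d2 <- unique(mir_mrna$mir_direction[mir_mrna$mirna_id == m])
    if (length(unique(c(d1, d2))) != 1L)
      stop("contradictory direction for miRNA '", m,
           "' between the two pair tables", call. = FALSE)
  }

  triplets <- merge(lnc_mir, mir_mrna,
                    by = c("mirna_id", "mir_direction"), sort = TRUE)
  triplets <- triplets[order(triplets$lncrna_id, triplets$mirna_id,
                             triplets$mrna_id), ]
  cols <- c("lncrna_id", "lnc_direction", "mirna_id", "mir_direction",
            "mrna_id", "mrna_direction", "target_score", "conservation",
            "context_score", "miranda_score", "miranda_energy")
  triplets <- triplets[, intersect(cols, names(triplets)), drop = FALSE]
  rownames(triplets) <- NULL

  bad <- triplets$lnc_direction == triplets$mir_direction |
    triplets$mir_direction == triplets$mrna_direction
  if (any(bad))
    stop("direction invariant violated for ", sum(bad), " triplet(s)",
         call. = FALSE)

  composition <- c(lncRNA = length(unique(triplets$lncrna_id)),
                   miRNA = length(unique(triplets$mirna_id)),
                   mRNA = length(unique(triplets$mrna_id)))
  list(triplets = triplets, network = cerna_network(triplets),
       composition = composition, dropped_mirnas = dropped)
}

#' Collapse triplets to a typed ceRNA network
#'
#' @param triplets triplet data.frame from [assemble_cerna()].
#' @return a [network_export()] with unique nodes (role + direction) and
#'   unique lncRNA-miRNA and miRNA-mRNA edges.
#' @export
cerna_network <- function(triplets) {
  if (nrow(triplets) == 0L) {
    return(network_export(
      data.frame(id = character(0), role = character(0),
                 direction = character(0), stringsAsFactors = FALSE),
      data.frame(from = character(0), to = character(0),
                 kind = character(0), stringsAsFactors = FALSE)))
  }
  nodes <- unique(rbind(
    data.frame(id = triplets$lncrna_id, role = "lncRNA",
               direction = triplets$lnc_direction,
               stringsAsFactors = FALSE),
    data.frame(id = triplets$mirna_id, role = "miRNA",
               direction = triplets$mir_direction,
               stringsAsFactors = FALSE),
    data.frame(id = triplets$mrna_id, role = "mRNA",
               direction = triplets$mrna_direction,
               stringsAsFactors = FALSE)))
  nodes <- nodes[order(nodes$role, nodes$id), ]
  edges <- unique(rbind(
    data.frame(from = triplets$lncrna_id, to = triplets$mirna_id,
               kind = "lncRNA-miRNA", stringsAsFactors = FALSE),
    data.frame(from = triplets$mirna_id, to = triplets$mrna_id,
               kind = "miRNA-mRNA", stringsAsFactors = FALSE)))
  edges <- edges[order(edges$kind, edges$from, edges$to), ]
  network_export(nodes, edges)
}

#' Core ceRNA subnetwork induced by hub mRNAs
#'
#' Keeps the triplets whose mRNA is a hub gene and recomputes the
#' composition counts.
#'
#' @param triplets triplet data.frame from [assemble_cerna()].
#' @param hub_mrnas nonempty character vector of hub gene ids.
#' @return list with `triplets`, `network`, `composition`.
#' @export
core_subnetwork <- function(triplets, hub_mrnas) {
  if (length(hub_mrnas) == 0L)
    stop("hub_mrnas must be nonempty", call. = FALSE)
  sub <- triplets[triplets$mrna_id %in% hub_mrnas, , drop = FALSE]
  rownames(sub) <- NULL
  list(triplets = sub, network = cerna_network(sub),
       composition = c(lncRNA = length(unique(sub$lncrna_id)),
                       miRNA = length(unique(sub$mirna_id)),
                       mRNA = length(unique(sub$mrna_id))))
}
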