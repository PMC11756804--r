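## Independent brute-force oracles used across the suite. These stay
## deliberately naive (loops, enumeration, closed forms) so they cannot
## share a defect with the implementation they check.

## step-up FDR from first principles
bf_bh <- function(p) {
  m <- length(p)
  out <- numeric(m)
  for (i in seq_len(m)) {
    cand <- 1
    for (j in seq_len(m)) {
      if (p[j] >= p[i]) {
        rank_j <- sum(p <= p[j])
        cand <- min(cand, m * p[j] / rank_j)
      }
    }
    out[i] <- cand
  }
  out
}

## hypergeometric upper tail by direct combinatorics
bf_hyper_tail <- function(k, K, n, N) {
  tot <- 0
  for (i in k:min(K, n))
    tot <- tot + choose(K, i) * choose(N - K, n - i) / choose(N, n)
  tot
}

## BFS distances over an adjacency list
bf_dists <- function(adj, s) {
  d <- stats::setNames(rep(Inf, length(adj)), names(adj))
  d[s] <- 0
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- character(0)
    for (v in frontier) for (u in adj[[v]]) {
      if (is.infinite(d[u])) {
        d[u] <- d[v] + 1
        nxt <- c(nxt, u)
      }
    }
    frontier <- unique(nxt)
  }
  d
}

bf_adj <- function(ids, from, to) {
  adj <- stats::setNames(lapply(ids, function(i) character(0)), ids)
  for (i in seq_along(from)) {
    adj[[from[i]]] <- union(adj[[from[i]]], to[i])
    adj[[to[i]]] <- union(adj[[to[i]]], from[i])
  }
  adj
}

## enumerate every shortest path between s and t
bf_shortest_paths <- function(adj, d_s, s, t) {
  if (is.infinite(d_s[t])) return(list())
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) return(list(path))
    out <- list()
    for (u in adj[[v]])
      if (d_s[u] == d_s[v] + 1 && d_s[u] <= d_s[t])
        out <- c(out, walk(c(path, u)))
    out
  }
  walk(s)
}

## betweenness and closeness by exhaustive path enumeration (undirected,
## unweighted, connected graphs)
## random connected undirected graph: spanning tree + extra edges
bf_random_connected <- function(ids, n_extra = 4) {
  from <- ids[2:length(ids)]
  to <- vapply(2:length(ids), function(i) ids[sample(i - 1, 1)],
               character(1))
  extra <- t(replicate(n_extra, sort(sample(ids, 2))))
  ed <- unique(rbind(data.frame(a = pmin(from, to), b = pmax(from, to),
                                stringsAsFactors = FALSE),
                     data.frame(a = extra[, 1], b = extra[, 2],
                                stringsAsFactors = FALSE)))
  ed[ed$a != ed$b, ]
}

bf_centralities <- function(ids, from, to) {
  adj <- bf_adj(ids, from, to)
  btw <- stats::setNames(rep(0, length(ids)), ids)
  cls <- stats::setNames(rep(0, length(ids)), ids)
  dmat <- sapply(ids, function(s) bf_dists(adj, s))
  for (v in ids) cls[v] <- 1 / sum(dmat[, v][names(dmat[, v]) != v])
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    s <- ids[i]; t <- ids[j]
    paths <- bf_shortest_paths(adj, dmat[, s], s, t)
    if (length(paths) == 0) next
    for (v in setdiff(ids, c(s, t))) {
      on_path <- sum(vapply(paths, function(p) v %in% p, logical(1)))
      btw[v] <- btw[v] + on_path / length(paths)
    }
  }
  degree <- vapply(adj, length, integer(1))
  data.frame(gene = ids, degree = unname(degree), betweenness = unname(btw),
             closeness = unname(cls), stringsAsFactors = FALSE)
}

## plain-loop re-check of every lncRNA-miRNA filter conjunct
bf_lnc_mir_filter <- function(core_lncs, pred, mir_de, lnc_de, cfg) {
  dir_of <- function(id, de) {
    i <- match(id, de$feature_id)
    if (is.na(i)) "absent" else de$direction[i]
  }
  keep <- logical(nrow(pred))
  for (i in seq_len(nrow(pred))) {
    ld <- dir_of(pred$lncrna_id[i], lnc_de)
    md <- dir_of(pred$mirna_id[i], mir_de)
    keep[i] <- pred$lncrna_id[i] %in% core_lncs &&
      pred$target_score[i] >= cfg$mirdb_score &&
      pred$conservation[i] > cfg$mirdb_conservation &&
      md %in% c("up", "down") && ld %in% c("up", "down") && ld != md
  }
  pred[keep, c("lncrna_id", "mirna_id")]
}

## plain-loop re-check of every miRNA-mRNA filter conjunct
bf_mir_mrna_filter <- function(mirnas, ts, mr, mrna_de, mir_de, cfg) {
  dir_of <- function(id, de) {
    i <- match(id, de$feature_id)
    if (is.na(i)) "absent" else de$direction[i]
  }
  keys <- unique(rbind(ts[, c("mirna_id", "mrna_id")],
                       mr[, c("mirna_id", "mrna_id")]))
  keep <- logical(nrow(keys))
  for (i in seq_len(nrow(keys))) {
    ti <- which(ts$mirna_id == keys$mirna_id[i] &
                  ts$mrna_id == keys$mrna_id[i])
    mi <- which(mr$mirna_id == keys$mirna_id[i] &
                  mr$mrna_id == keys$mrna_id[i])
    if (length(ti) == 0 || length(mi) == 0) next
    ctx <- min(ts$context_score[ti])
    msc <- max(mr$miranda_score[mi])
    men <- min(mr$miranda_energy[mi])
    md <- dir_of(keys$mirna_id[i], mir_de)
    gd <- dir_of(keys$mrna_id[i], mrna_de)
    keep[i] <- keys$mirna_id[i] %in% mirnas &&
      ctx <= cfg$context_max && msc > cfg$miranda_min &&
      men < cfg$energy_max && gd %in% c("up", "down") &&
      md %in% c("up", "down") && md != gd
  }
  keys[keep, ]
}

## exhaustive triple loop over all (L, m, G) combinations
bf_triplets <- function(lnc_mir, mir_mrna) {
  out <- list()
  ls <- unique(lnc_mir$lncrna_id)
  ms <- unique(c(lnc_mir$mirna_id, mir_mrna$mirna_id))
  gs <- unique(mir_mrna$mrna_id)
  for (L in ls) for (m in ms) for (G in gs) {
    has_lm <- any(lnc_mir$lncrna_id == L & lnc_mir$mirna_id == m)
    has_mg <- any(mir_mrna$mirna_id == m & mir_mrna$mrna_id == G)
    if (has_lm && has_mg)
      out[[length(out) + 1L]] <- data.frame(
        lncrna_id = L, mirna_id = m, mrna_id = G,
        stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(lncrna_id = character(0), mirna_id = character(0),
                      mrna_id = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

triplet_key <- function(d) sort(paste(d$lncrna_id, d$mirna_id, d$mrna_id))
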