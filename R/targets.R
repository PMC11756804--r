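de_direction_of <- function(ids, de) {
  d <- de$direction[match(ids, de$feature_id)]
  d[is.na(d)] <- "absent"
  d
}

dedup_best <- function(df, keys, maximize = character(0),
                       minimize = character(0)) {
  ## collapse duplicate prediction rows per key pair, keeping the best
  ## score per column (max for scores, min for context/energy)
  key <- do.call(paste, c(df[keys], sep = "\r"))
  if (!anyDuplicated(key)) return(list(df = df, n_dup = 0L))
  n_dup <- sum(duplicated(key))
  sp <- split(seq_len(nrow(df)), key)
  rows <- lapply(sp, function(ix) {
    row <- df[ix[1L], , drop = FALSE]
    for (cc in maximize) row[[cc]] <- max(df[[cc]][ix], na.rm = TRUE)
    for (cc in minimize) row[[cc]] <- min(df[[cc]][ix], na.rm = TRUE)
    row
  })
  out <- do.call(rbind, rows[unique(key)])  # first-occurrence order
  rownames(out) <- NULL
  list(df = out, n_dup = n_dup)
}

#' Filter lncRNA-miRNA predictions into directed sponge pairs
#'
#' Keeps miRDB-style prediction rows that satisfy, in order: the lncRNA is
#' a core candidate; target score >= `config$mirdb_score` (inclusive);
#' conservation > `config$mirdb_conservation` (strict); the miRNA is
#' differentially expressed; and the lncRNA and miRNA change in opposite
#' directions (the ceRNA sponge rule). The exclusion tally counts each row
#' at the first rule it fails, so tally + retained = input rows (after
#' duplicate collapsing, which keeps the best score per pair and warns).
#'
#' With `config$direction_rule = "per_mirna"`, a miRNA with any same-trend
#' core partner is removed from all its pairs (the stricter global
#' reading); the default `"per_pair"` drops only the offending pairs.
#'
#' @param core_lncs character vector of core lncRNA ids (must be
#'   differentially expressed, i.e. present in `lnc_de` with a direction).
#' @param predictions data.frame in the `mirdb` schema.
#' @param mir_de,lnc_de DE tables (from [nb_test()]) with `feature_id` and
#'   `direction`.
#' @param config a [pipeline_config()].
#' @return list with `pairs` (data.frame: `lncrna_id`, `mirna_id`,
#'   `lnc_direction`, `mir_direction`, `target_score`, `conservation`),
#'   `tally` (named exclusion counts), and `lnc_without_mirna` (core
#'   lncRNAs left with no surviving miRNA).
#' @export
lnc_mir_pairs <- function(core_lncs, predictions, mir_de, lnc_de,
                          config = pipeline_config()) {
  stopifnot(all(c("lncrna_id", "mirna_id", "target_score",
                  "conservation") %in% names(predictions)))
  core_dir <- de_direction_of(core_lncs, lnc_de)
  if (any(!core_dir %in% c("up", "down")))
    stop("core lncRNA(s) not differentially expressed: ",
         paste(core_lncs[!core_dir %in% c("up", "down")], collapse = ", "),
         call. = FALSE)

  dd <- dedup_best(predictions, c("lncrna_id", "mirna_id"),
                   maximize = c("target_score", "conservation"))
  if (dd$n_dup > 0L)
    warning(dd$n_dup, " duplicate prediction row(s) collapsed",
            call. = FALSE)
  pr <- dd$df

  lnc_dir <- de_direction_of(pr$lncrna_id, lnc_de)
  mir_dir <- de_direction_of(pr$mirna_id, mir_de)

  checks <- list(
    not_core = pr$lncrna_id %in% core_lncs,
    low_score = pr$target_score >= config$mirdb_score,
    low_conservation = pr$conservation > config$mirdb_conservation,
    mirna_not_de = mir_dir %in% c("up", "down"),
    same_direction = lnc_dir != mir_dir
  )
  reason <- rep(NA_character_, nrow(pr))
  alive <- rep(TRUE, nrow(pr))
  for (r in names(checks)) {
    fail <- alive & !checks[[r]]
    reason[fail] <- r
    alive <- alive & checks[[r]]
  }

  if (config$direction_rule == "per_mirna") {
    offending <- unique(pr$mirna_id[!is.na(reason) &
                                      reason == "same_direction"])
    glob <- alive & pr$mirna_id %in% offending
    reason[glob] <- "same_direction"
    alive <- alive & !glob
  }

  pairs <- data.frame(
    lncrna_id = pr$lncrna_id[alive],
    mirna_id = pr$mirna_id[alive],
    lnc_direction = lnc_dir[alive],
    mir_direction = mir_dir[alive],
    target_score = pr$target_score[alive],
    conservation = pr$conservation[alive],
    stringsAsFactors = FALSE)
  tally <- vapply(names(checks), function(r)
    sum(reason == r, na.rm = TRUE), integer(1))
  tally <- c(tally, retained = sum(alive))
  list(pairs = pairs, tally = tally,
       lnc_without_mirna = sort(setdiff(core_lncs, pairs$lncrna_id)))
}

#' Filter miRNA-mRNA predictions into directed target pairs
#'
#' Merges TargetScan-style and miRanda-style prediction tables on
#' (miRNA, mRNA) and keeps pairs predicted by BOTH tools with context++
#' score <= `config$context_max` (inclusive), miRanda score >
#' `config$miranda_min` (strict), energy < `config$energy_max` (strict),
#' an mRNA that is differentially expressed, and miRNA/mRNA changing in
#' opposite directions. Pairs whose miRNA is outside `mirnas` are excluded
#' first (`not_in_set`). Duplicate rows per pair keep the best score per
#' tool (max miRanda score, min context score and energy) with a warning.
#'
#' @param mirnas character vector of admissible miRNA ids (the sponged
#'   miRNAs from [lnc_mir_pairs()]).
#' @param targetscan data.frame in the `targetscan` schema.
#' @param miranda data.frame in the `miranda` schema.
#' @param mrna_de,mir_de DE tables with `feature_id` and `direction`.
#' @param config a [pipeline_config()].
#' @return list with `pairs` (data.frame: `mirna_id`, `mrna_id`,
#'   `mir_direction`, `mrna_direction`, `context_score`, `miranda_score`,
#'   `miranda_energy`) and `tally` (exclusion counts; tally + retained =
#'   merged pair count).
#' @export
mir_mrna_pairs <- function(mirnas, targetscan, miranda, mrna_de, mir_de,
                           config = pipeline_config()) {
  stopifnot(all(c("mirna_id", "mrna_id", "context_score") %in%
                  names(targetscan)),
            all(c("mirna_id", "mrna_id", "miranda_score",
                  "miranda_energy") %in% names(miranda)))
  dts <- dedup_best(targetscan, c("mirna_id", "mrna_id"),
                    minimize = "context_score")
  dmr <- dedup_best(miranda, c("mirna_id", "mrna_id"),
                    maximize = "miranda_score",
                    minimize = "miranda_energy")
  if (dts$n_dup + dmr$n_dup > 0L)
    warning(dts$n_dup + dmr$n_dup,
            " duplicate prediction row(s) collapsed", call. = FALSE)

  pr <- merge(dts$df[, c("mirna_id", "mrna_id", "context_score")],
              dmr$df[, c("mirna_id", "mrna_id", "miranda_score",
                         "miranda_energy")],
              by = c("mirna_id", "mrna_id"), all = TRUE, sort = TRUE)

  mir_dir <- de_direction_of(pr$mirna_id, mir_de)
  mrna_dir <- de_direction_of(pr$mrna_id, mrna_de)
  both <- !is.na(pr$context_score) & !is.na(pr$miranda_score)

  checks <- list(
    not_in_set = pr$mirna_id %in% mirnas,
    single_tool = both,
    context = both & pr$context_score <= config$context_max,
    miranda_score = both & pr$miranda_score > config$miranda_min,
    energy = both & pr$miranda_energy < config$energy_max,
    mrna_not_de = mrna_dir %in% c("up", "down"),
    same_direction = mir_dir != mrna_dir
  )
  reason <- rep(NA_character_, nrow(pr))
  alive <- rep(TRUE, nrow(pr))
  for (r in names(checks)) {
    fail <- alive & !checks[[r]]
    reason[fail] <- r
    alive <- alive & checks[[r]]
  }

  pairs <- data.frame(
    mirna_id = pr$mirna_id[alive],
    mrna_id = pr$mrna_id[alive],
    mir_direction = mir_dir[alive],
    mrna_direction = mrna_dir[alive],
    context_score = pr$context_score[alive],
    miranda_score = pr$miranda_score[alive],
    miranda_energy = pr$miranda_energy[alive],
    stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  tally <- vapply(names(checks), function(r)
    sum(reason == r, na.rm = TRUE), integer(1))
  tally <- c(tally, retained = sum(alive))
  list(pairs = pairs, tally = tally)
}
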