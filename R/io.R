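#' @name table_schemas
#' @title Built-in table schemas
#'
#' @description Every table the pipeline reads is validated against a named
#' schema. Tables are one header line plus data rows; lines starting with
#' `#` are comments; the delimiter (tab or comma) is sniffed from the
#' header. Extra columns are tolerated everywhere (journal supplementary
#' exports routinely carry them); missing required columns are an error.
#'
#' Available schemas:
#' \describe{
#'   \item{`de`}{`id, log2fc, pvalue, fdr` — differential-expression table.}
#'   \item{`transcript`}{`transcript_id, class_code, length_nt, exon_count,
#'     cpc_score, cnci_score, cpat_score, pfam_score, chrom, start, end,
#'     strand` plus at least one per-sample `fpkm_*` column.}
#'   \item{`localization`}{`lncrna_id` plus the five compartment scores
#'     `cytoplasm, nucleus, ribosome, cytosol, exosome`.}
#'   \item{`mirdb`}{`lncrna_id, mirna_id, target_score, conservation`.}
#'   \item{`targetscan`}{`mirna_id, mrna_id, context_score`.}
#'   \item{`miranda`}{`mirna_id, mrna_id, miranda_score, miranda_energy`.}
#'   \item{`ppi`}{`protein_a, protein_b, combined_score`.}
#'   \item{`counts`}{`feature_id` plus one numeric column per sample.}
#' }
#'
#' Identifiers are opaque case-sensitive strings; the only normalization
#' applied is whitespace stripping.
NULL

.table_schemas <- list(
  de = list(columns = c(id = "character", log2fc = "numeric",
                        pvalue = "numeric", fdr = "numeric"),
            id = "id"),
  transcript = list(columns = c(transcript_id = "character",
                                class_code = "character",
                                length_nt = "numeric",
                                exon_count = "numeric",
                                cpc_score = "numeric",
                                cnci_score = "numeric",
                                cpat_score = "numeric",
                                pfam_score = "numeric",
                                chrom = "character",
                                start = "numeric", end = "numeric",
                                strand = "character"),
                    id = "transcript_id", prefix_numeric = "fpkm"),
  localization = list(columns = c(lncrna_id = "character",
                                  cytoplasm = "numeric", nucleus = "numeric",
                                  ribosome = "numeric", cytosol = "numeric",
                                  exosome = "numeric"),
                      id = "lncrna_id"),
  mirdb = list(columns = c(lncrna_id = "character", mirna_id = "character",
                           target_score = "numeric",
                           conservation = "numeric"),
               id = NULL),
  targetscan = list(columns = c(mirna_id = "character",
                                mrna_id = "character",
                                context_score = "numeric"),
                    id = NULL),
  miranda = list(columns = c(mirna_id = "character", mrna_id = "character",
                             miranda_score = "numeric",
                             miranda_energy = "numeric"),
                 id = NULL),
  ppi = list(columns = c(protein_a = "character", protein_b = "character",
                         combined_score = "numeric"),
             id = NULL),
  counts = list(columns = c(feature_id = "character"),
                id = "feature_id", rest_numeric = TRUE)
)

resolve_schema <- function(schema) {
  if (is.character(schema) && length(schema) == 1L) {
    if (!schema %in% names(.table_schemas))
      stop("unknown schema '", schema, "'; available: ",
           paste(names(.table_schemas), collapse = ", "), call. = FALSE)
    return(.table_schemas[[schema]])
  }
  stopifnot(is.list(schema), !is.null(schema$columns))
  schema
}

#' Read and validate a delimited table
#'
#' @param path file path to a tab- or comma-separated table (sniffed from
#'   the header line). Lines starting with `#` are skipped.
#' @param schema a schema name (see [table_schemas]) or a list with a
#'   `columns` character vector (`name = "numeric"|"character"`), an
#'   optional `id` column name, optional `prefix_numeric` (columns whose
#'   name starts with this prefix are coerced numeric; at least one must be
#'   present) and optional `rest_numeric` (all non-required columns are
#'   coerced numeric).
#' @return A `data.frame` with columns coerced to the schema types, rows in
#'   file order. Duplicated identifiers (if the schema names an id column)
#'   are reported via a warning and the `"duplicated_ids"` attribute.
#' @export
read_table <- function(path, schema) {
  sch <- resolve_schema(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(keep) < 1L) stop("no header line in ", path, call. = FALSE)
  header <- lines[keep[1L]]
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(text = lines[keep], sep = sep, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "",
                          stringsAsFactors = FALSE)
  line_of_row <- keep[-1L]

  req <- names(sch$columns)
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L)
    stop("schema error: missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)

  types <- sch$columns
  if (isTRUE(sch$rest_numeric)) {
    extra <- setdiff(names(df), req)
    types <- c(types, stats::setNames(rep("numeric", length(extra)), extra))
  }
  if (!is.null(sch$prefix_numeric)) {
    pf <- grep(paste0("^", sch$prefix_numeric), names(df), value = TRUE)
    if (length(pf) == 0L)
      stop("schema error: missing required column(s): ",
           sch$prefix_numeric, "*", call. = FALSE)
    pf <- setdiff(pf, names(types))
    types <- c(types, stats::setNames(rep("numeric", length(pf)), pf))
  }

  for (col in names(types)) {
    raw <- trimws(df[[col]])
    if (types[[col]] == "numeric") {
      val <- suppressWarnings(as.numeric(raw))
      bad <- which(is.na(val) & !is.na(raw) &
                     !(raw %in% c("", "NA", "NaN")))
      if (length(bad) > 0L)
        stop(sprintf(
          "unparseable numeric value '%s' in column '%s' at line %d of %s",
          raw[bad[1L]], col, line_of_row[bad[1L]], path), call. = FALSE)
      df[[col]] <- val
    } else {
      df[[col]] <- raw
    }
  }

  if (!is.null(sch$id) && sch$id %in% names(df)) {
    dup <- unique(df[[sch$id]][duplicated(df[[sch$id]])])
    if (length(dup) > 0L) {
      warning("duplicated identifier(s) in ", path, ": ",
              paste(utils::head(dup, 5L), collapse = ", "),
              if (length(dup) > 5L) ", ..." else "", call. = FALSE)
      attr(df, "duplicated_ids") <- dup
    }
  }
  rownames(df) <- NULL
  df
}

#' Write a delimited table
#'
#' Plain tab-separated (default) writer matching [read_table()]:
#' one header line, no quoting, no row names.
#'
#' @param df data.frame.
#' @param path output path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, sep = "\t") {
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' @param path GMT file path.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @param sets named list of character vectors (gene sets).
#' @param descriptions optional character vector of set descriptions
#'   (defaults to the set names).
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

## ---- typed network container ------------------------------------------

.allowed_edge_roles <- list(
  "lncRNA-miRNA"    = c("lncRNA", "miRNA"),
  "miRNA-mRNA"      = c("miRNA", "mRNA"),
  "protein-protein" = c("protein", "protein")
)

#' Typed network container
#'
#' A validated node + edge list for the pipeline's networks. Node roles are
#' `lncRNA`, `miRNA`, `mRNA` or `protein`; node direction is `up` or
#' `down`; edge kinds are `lncRNA-miRNA`, `miRNA-mRNA` or
#' `protein-protein`, and the roles at an edge's endpoints must match its
#' kind. Self-loops and edges naming unknown nodes are rejected.
#'
#' @param nodes data.frame with columns `id`, `role`, `direction`.
#' @param edges data.frame with columns `from`, `to`, `kind`; any further
#'   columns are carried as edge provenance (scores).
#' @return An object of class `"network_export"`.
#' @export
network_export <- function(nodes, edges) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  need_n <- c("id", "role", "direction")
  if (!all(need_n %in% names(nodes)))
    stop("nodes need columns: ", paste(need_n, collapse = ", "),
         call. = FALSE)
  need_e <- c("from", "to", "kind")
  if (!all(need_e %in% names(edges)))
    stop("edges need columns: ", paste(need_e, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(nodes$id))
    stop("duplicated node ids", call. = FALSE)
  bad_role <- setdiff(unique(nodes$role),
                      c("lncRNA", "miRNA", "mRNA", "protein"))
  if (length(bad_role) > 0L)
    stop("unknown node role(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  if (nrow(edges) > 0L) {
    unknown <- setdiff(c(edges$from, edges$to), nodes$id)
    if (length(unknown) > 0L)
      stop("edge endpoint(s) not in node list: ",
           paste(unique(unknown), collapse = ", "), call. = FALSE)
    if (any(edges$from == edges$to))
      stop("self-loop edge(s) present", call. = FALSE)
    role_of <- stats::setNames(nodes$role, nodes$id)
    for (i in seq_len(nrow(edges))) {
      kind <- edges$kind[i]
      allowed <- .allowed_edge_roles[[kind]]
      if (is.null(allowed))
        stop("unknown edge kind: ", kind, call. = FALSE)
      got <- sort(c(role_of[[edges$from[i]]], role_of[[edges$to[i]]]))
      if (!identical(got, sort(allowed)))
        stop("edge ", edges$from[i], " -> ", edges$to[i],
             " has roles (", paste(got, collapse = ", "),
             ") incompatible with kind '", kind, "'", call. = FALSE)
    }
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "network_export")
}

#' @export
print.network_export <- function(x, ...) {
  cat(sprintf("network_export: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$nodes) > 0L) print(table(x$nodes$role))
  invisible(x)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  gsub("'", "&apos;", x, fixed = TRUE)
}

#' Export a typed network
#'
#' Writes a [network_export()] object so that generic graph viewers (e.g.
#' Cytoscape) can load it. Three dialects:
#' \describe{
#'   \item{`sif`}{simple interaction format (`from  kind  to`); node
#'     attributes go to a companion `<path>.noa.tsv` file.}
#'   \item{`graphml`}{single self-contained XML file with node attributes
#'     `role`/`direction` and all edge columns as edge attributes.}
#'   \item{`tsv`}{edge table with all columns plus the `<path>.noa.tsv`
#'     companion.}
#' }
#' `read_network()` re-reads any dialect to an isomorphic graph with
#' identical node attributes.
#'
#' @param net a [network_export()] object (validated on construction).
#' @param path output file path.
#' @param dialect one of `"sif"`, `"graphml"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, dialect = c("sif", "graphml", "tsv")) {
  stopifnot(inherits(net, "network_export"))
  dialect <- match.arg(dialect)
  nodes <- net$nodes
  edges <- net$edges
  if (dialect == "sif") {
    lines <- if (nrow(edges) > 0L)
      paste(edges$from, edges$kind, edges$to, sep = "\t") else character(0)
    writeLines(lines, path)
    write_table(nodes, paste0(path, ".noa.tsv"))
  } else if (dialect == "tsv") {
    write_table(edges, path)
    write_table(nodes, paste0(path, ".noa.tsv"))
  } else {
    extra <- setdiff(names(edges), c("from", "to", "kind"))
    con <- file(path, "w")
    on.exit(close(con))
    w <- function(...) writeLines(sprintf(...), con)
    w('<?xml version="1.0" encoding="UTF-8"?>')
    w('<graphml xmlns="http://graphml.graphdrawing.org/xmlns">')
    w('  <key id="d_role" for="node" attr.name="role" attr.type="string"/>')
    w(paste0('  <key id="d_direction" for="node" attr.name="direction"',
             ' attr.type="string"/>'))
    w('  <key id="d_kind" for="edge" attr.name="kind" attr.type="string"/>')
    for (i in seq_along(extra)) {
      typ <- if (is.numeric(edges[[extra[i]]])) "double" else "string"
      w('  <key id="d_e%d" for="edge" attr.name="%s" attr.type="%s"/>',
        i, xml_escape(extra[i]), typ)
    }
    w('  <graph id="G" edgedefault="undirected">')
    for (i in seq_len(nrow(nodes))) {
      w('    <node id="%s">', xml_escape(nodes$id[i]))
      w('      <data key="d_role">%s</data>', xml_escape(nodes$role[i]))
      w('      <data key="d_direction">%s</data>',
        xml_escape(as.character(nodes$direction[i])))
      w('    </node>')
    }
    for (i in seq_len(nrow(edges))) {
      w('    <edge source="%s" target="%s">',
        xml_escape(edges$from[i]), xml_escape(edges$to[i]))
      w('      <data key="d_kind">%s</data>', xml_escape(edges$kind[i]))
      for (k in seq_along(extra)) {
        v <- edges[[extra[k]]][i]
        w('      <data key="d_e%d">%s</data>', k,
          xml_escape(format(v, digits = 15)))
      }
      w('    </edge>')
    }
    w('  </graph>')
    w('</graphml>')
  }
  invisible(path)
}

#' @rdname export_network
#' @export
read_network <- function(path, dialect = c("sif", "graphml", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "graphml") {
    doc <- xml2::read_xml(path)
    keys <- xml2::xml_find_all(doc, "//*[local-name()='key']")
    key_name <- stats::setNames(xml2::xml_attr(keys, "attr.name"),
                                xml2::xml_attr(keys, "id"))
    key_type <- stats::setNames(xml2::xml_attr(keys, "attr.type"),
                                xml2::xml_attr(keys, "id"))
    nd <- xml2::xml_find_all(doc, "//*[local-name()='node']")
    get_data <- function(node) {
      d <- xml2::xml_find_all(node, "./*[local-name()='data']")
      stats::setNames(xml2::xml_text(d),
                      key_name[xml2::xml_attr(d, "key")])
    }
    nodes <- data.frame(
      id = xml2::xml_attr(nd, "id"),
      role = vapply(nd, function(n) get_data(n)[["role"]], character(1)),
      direction = vapply(nd, function(n) get_data(n)[["direction"]],
                         character(1)),
      stringsAsFactors = FALSE)
    ed <- xml2::xml_find_all(doc, "//*[local-name()='edge']")
    edges <- data.frame(
      from = xml2::xml_attr(ed, "source"),
      to = xml2::xml_attr(ed, "target"), stringsAsFactors = FALSE)
    attr_names <- unname(key_name[!key_name %in% c("role", "direction")])
    for (an in attr_names) {
      kid <- names(key_name)[key_name == an][1L]
      vals <- vapply(ed, function(e) {
        v <- get_data(e)
        if (an %in% names(v)) v[[an]] else NA_character_
      }, character(1))
      edges[[an]] <- if (identical(key_type[[kid]], "double"))
        as.numeric(vals) else vals
    }
    if (nrow(edges) == 0L) edges$kind <- character(0)
    return(network_export(nodes, edges))
  }
  nodes <- read_table(paste0(path, ".noa.tsv"),
                      list(columns = c(id = "character",
                                       role = "character",
                                       direction = "character"),
                           id = "id"))
  if (dialect == "sif") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) {
      edges <- data.frame(from = character(0), to = character(0),
                          kind = character(0), stringsAsFactors = FALSE)
    } else {
      parts <- strsplit(lines, "\t", fixed = TRUE)
      edges <- data.frame(
        from = vapply(parts, `[[`, character(1), 1L),
        kind = vapply(parts, `[[`, character(1), 2L),
        to = vapply(parts, `[[`, character(1), 3L),
        stringsAsFactors = FALSE)[, c("from", "to", "kind")]
    }
  } else {
    edges <- utils::read.table(path, sep = "\t", header = TRUE,
                               check.names = FALSE,
                               stringsAsFactors = FALSE)
    if (nrow(edges) == 0L)
      edges <- data.frame(from = character(0), to = character(0),
                          kind = character(0), stringsAsFactors = FALSE)
  }
  network_export(nodes, edges)
}
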