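#' Parse a KGML pathway file into a signed directed graph
#'
#' Reads one KEGG KGML XML document and builds a [pathway_graph()]:
#' one node per `entry` of type `gene`, `compound` or `group` (group members
#' are flattened into the union of their gene identifiers), one signed edge
#' per `relation`. Relation subtypes whose name contains `"inhibition"` or
#' `"repression"` are mapped to sign -1; every other subtype (including
#' `"indirect effect"` and unnamed ones) keeps the conservative default +1.
#' Entries of type `map` (pathway cross-links) and any other non-molecular
#' entry types are dropped, together with relations that touch them.
#'
#' @param x Path to a KGML file, or a KGML XML string.
#' @return A `PathwayGraph` with sources and sinks identified by degree.
#' @seealso [break_cycles()] to make the graph acyclic before PSF propagation.
#' @export
parse_kgml <- function(x) {
  doc <- tryCatch(
    xml2::read_xml(x),
    error = function(e) {
      stop("KGML parse error: ", conditionMessage(e), call. = FALSE)
    }
  )
  if (xml2::xml_name(xml2::xml_root(doc)) != "pathway") {
    stop("KGML parse error: root element is not <pathway>")
  }
  pathway_id <- xml2::xml_attr(doc, "name") %|NA|% "unknown_pathway"
  pathway_id <- sub("^path:", "", pathway_id)
  pname <- xml2::xml_attr(doc, "title") %|NA|% pathway_id

  entries <- xml2::xml_find_all(doc, ".//entry")
  ent_id <- xml2::xml_attr(entries, "id")
  ent_type <- xml2::xml_attr(entries, "type")
  ent_name <- xml2::xml_attr(entries, "name")
  keep_kind <- c(gene = "gene", compound = "compound", group = "group")
  keep <- ent_type %in% names(keep_kind)
  dropped_ids <- ent_id[!keep]

  # gene ids from the entry name attribute (whitespace-separated accessions)
  gene_ids_of <- function(i) {
    if (ent_type[i] != "gene") return(character(0))
    ids <- strsplit(trimws(ent_name[i] %|NA|% ""), "\\s+")[[1]]
    ids[nzchar(ids)]
  }

  labels <- vapply(entries, function(e) {
    gr <- xml2::xml_find_first(e, "./graphics")
    lab <- if (!inherits(gr, "xml_missing")) xml2::xml_attr(gr, "name") else NA_character_
    if (is.na(lab)) lab <- xml2::xml_attr(e, "name")
    sub(",.*$", "", lab %|NA|% "")
  }, "")

  by_id <- setNames(seq_along(ent_id), ent_id)

  nodes <- data.frame(node_id = ent_id[keep], node_kind = ent_type[keep],
                      label = labels[keep], stringsAsFactors = FALSE)
  gene_ids <- lapply(which(keep), gene_ids_of)

  # flatten group entries: union of their component entries' gene ids
  for (j in seq_len(nrow(nodes))) {
    if (nodes$node_kind[j] != "group") next
    e <- entries[[by_id[[nodes$node_id[j]]]]]
    comp <- xml2::xml_attr(xml2::xml_find_all(e, "./component"), "id")
    missing <- setdiff(comp, ent_id)
    if (length(missing)) {
      stop("KGML structural error: group entry '", nodes$node_id[j],
           "' references missing entries: ", paste(missing, collapse = ", "))
    }
    gene_ids[[j]] <- sort(unique(unlist(lapply(by_id[comp], gene_ids_of))))
  }
  nodes$gene_ids <- gene_ids

  rels <- xml2::xml_find_all(doc, ".//relation")
  from <- xml2::xml_attr(rels, "entry1")
  to <- xml2::xml_attr(rels, "entry2")
  subtypes <- lapply(rels, function(r) {
    xml2::xml_attr(xml2::xml_find_all(r, "./subtype"), "name")
  })
  subtype_label <- vapply(subtypes, function(s) paste(s, collapse = "; "), "")
  sign <- vapply(subtypes, function(s) {
    if (any(grepl("inhibition|repression", s, ignore.case = TRUE))) -1L else 1L
  }, 0L)

  unknown <- setdiff(unique(c(from, to)), ent_id)
  if (length(unknown)) {
    stop("KGML structural error: relation references missing entry id(s): ",
         paste(unknown, collapse = ", "))
  }
  # relations touching dropped (e.g. map) entries are dropped with them
  keep_rel <- !(from %in% dropped_ids) & !(to %in% dropped_ids)
  edges <- data.frame(from = from[keep_rel], to = to[keep_rel],
                      sign = sign[keep_rel], subtype = subtype_label[keep_rel],
                      stringsAsFactors = FALSE)

  pathway_graph(pathway_id, pname, nodes, edges)
}

`%|NA|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Serialize a pathway graph to KGML XML
#'
#' Emits a minimal valid KGML document (entries with graphics labels,
#' relations with activation/inhibition subtypes) that [parse_kgml()] reads
#' back to the same node and edge multiset. Used by the synthetic-pathway
#' generator so that generated collections exercise the same reader as real
#' KEGG downloads.
#'
#' @param g A `PathwayGraph`.
#' @param path Optional output file; if `NULL` the XML string is returned.
#' @return XML string (invisibly when written to `path`).
#' @export
write_kgml <- function(g, path = NULL) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  lines <- c(
    "<?xml version=\"1.0\"?>",
    sprintf("<pathway name=\"path:%s\" title=\"%s\">",
            esc(g$pathway_id), esc(g$name))
  )
  for (i in seq_len(nrow(g$nodes))) {
    kind <- g$nodes$node_kind[i]
    nm <- if (kind == "gene") paste(g$nodes$gene_ids[[i]], collapse = " ") else g$nodes$label[i]
    lines <- c(lines,
      sprintf("  <entry id=\"%s\" name=\"%s\" type=\"%s\">",
              esc(g$nodes$node_id[i]), esc(nm), esc(kind)),
      sprintf("    <graphics name=\"%s\"/>", esc(g$nodes$label[i])),
      "  </entry>")
  }
  for (i in seq_len(nrow(g$edges))) {
    st <- if (g$edges$sign[i] == -1L) "inhibition" else "activation"
    if (nzchar(g$edges$subtype[i])) st <- g$edges$subtype[i]
    lines <- c(lines,
      sprintf("  <relation entry1=\"%s\" entry2=\"%s\" type=\"PPrel\">",
              esc(g$edges$from[i]), esc(g$edges$to[i])),
      sprintf("    <subtype name=\"%s\" value=\"--&gt;\"/>", esc(st)),
      "  </relation>")
  }
  lines <- c(lines, "</pathway>")
  xml <- paste(lines, collapse = "\n")
  if (is.null(path)) return(xml)
  writeLines(xml, path)
  invisible(xml)
}
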