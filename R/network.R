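#' Greedy covering-set selection
#'
#' Implements the covering rule used to thin a redundant MGE database:
#' candidates are repeatedly re-ranked by the number of not-yet-covered
#' elements they contain, the best one is selected (ties broken by
#' lexicographically smallest candidate id), and covered elements are
#' removed, until the whole universe is covered.  Every selected candidate
#' contributes at least one new element at its selection step.
#'
#' @param universe character vector of element ids to cover.
#' @param candidates named list; each entry is the set of element ids the
#'   candidate covers (must be subsets of \code{universe}, jointly
#'   covering it).
#' @return character vector of selected candidate ids, in selection order.
#' @export
greedy_cover <- function(universe, candidates) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) return(character(0))
  if (length(candidates) == 0L || is.null(names(candidates)))
    stop("candidates must be a non-empty named list", call. = FALSE)
  candidates <- lapply(candidates, function(s) unique(as.character(s)))
  stray <- setdiff(unlist(candidates, use.names = FALSE), universe)
  if (length(stray))
    stop("candidate sets cover elements outside the universe: ",
         paste(utils::head(stray, 10), collapse = ", "), call. = FALSE)
  uncovered <- setdiff(universe, unlist(candidates, use.names = FALSE))
  if (length(uncovered))
    stop("universe not coverable; uncovered elements: ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  # fixed lexicographic candidate order makes which.max the tie-break
  candidates <- candidates[order(names(candidates), method = "radix")]
  todo <- universe
  sel <- character(0)
  while (length(todo)) {
    gain <- vapply(candidates, function(s) sum(s %in% todo), integer(1))
    best <- which.max(gain)
    sel <- c(sel, names(candidates)[best])
    todo <- setdiff(todo, candidates[[best]])
    candidates <- candidates[-best]
  }
  sel
}

#' Select a small set of MGEs explaining all matched spacers
#'
#' Builds a covering instance whose universe is the set of spacer clusters
#' with at least one passing hit, and whose candidates are the MGEs (each
#' covering the clusters it contains protospacers for), then runs
#' [greedy_cover()].
#'
#' @param hits filtered hits data.frame.
#' @return character vector of selected MGE ids, in selection order.
#' @export
select_mges <- function(hits) {
  if (nrow(hits) == 0L) return(character(0))
  greedy_cover(unique(hits$cluster_id),
               lapply(split(hits$cluster_id, hits$mge_id), unique))
}

#' Select a small set of hosts containing all matched spacers
#'
#' Same greedy rule over hosts: the universe is the matched spacer
#' clusters; a host covers every matched cluster that has at least one
#' member spacer from that host.
#'
#' @param hits filtered hits data.frame.
#' @param catalog spacer occurrence table with columns \code{host_id} and
#'   \code{cluster_id} (e.g. [extract_spacers()] output merged with
#'   [spacer_cluster_map()], or \code{read_spacer_fasta()$spacers}).
#' @return character vector of selected host ids, in selection order.
#' @export
select_hosts <- function(hits, catalog) {
  if (nrow(hits) == 0L) return(character(0))
  matched <- unique(hits$cluster_id)
  cat2 <- catalog[catalog$cluster_id %in% matched, , drop = FALSE]
  greedy_cover(matched, lapply(split(cat2$cluster_id, cat2$host_id), unique))
}

collapse_types <- function(types) {
  if (length(types) == 0L) "untyped" else paste(types, collapse = ";")
}

make_network <- function(vdf, edf, kind) {
  g <- igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
  g <- igraph::set_graph_attr(g, "networkkind", kind)
  g
}

#' Build the spacer-MGE interaction network
#'
#' Nodes are matched spacer clusters and selected MGEs; an edge joins a
#' spacer to an MGE when the MGE contains at least one passing protospacer
#' for it.  The edge attribute \code{nmatches} counts the passing hit loci
#' for the pair.  Only MGEs from \code{selected_mges} enter the network,
#' and every node has degree at least one.
#'
#' @param hits filtered hits data.frame.
#' @param selected_mges MGE ids from [select_mges()].
#' @param clusters data.frame from [deduplicate_spacers()] (supplies
#'   CRISPR type labels).
#' @param mge_meta optional data.frame with \code{mge_id},
#'   \code{mge_class}, \code{source_db}, \code{known_host}.
#' @return an \pkg{igraph} undirected bipartite graph; spacer nodes carry
#'   \code{kind = "spacer"} and \code{crisprtype}, MGE nodes
#'   \code{kind = "mge"}, \code{mgeclass}, \code{sourcedb},
#'   \code{knownhost}.
#' @export
build_spacer_mge_network <- function(hits, selected_mges, clusters,
                                     mge_meta = NULL) {
  h <- hits[hits$mge_id %in% selected_mges, , drop = FALSE]
  if (nrow(h) == 0L)
    return(make_network(
      data.frame(name = character(0), kind = character(0),
                 crisprtype = character(0), mgeclass = character(0),
                 sourcedb = character(0), knownhost = character(0),
                 stringsAsFactors = FALSE),
      data.frame(from = character(0), to = character(0),
                 nmatches = numeric(0), stringsAsFactors = FALSE),
      "spacer_mge"))
  key <- paste(h$cluster_id, h$mge_id, sep = "\r")
  tab <- table(key)
  pair <- strsplit(names(tab), "\r", fixed = TRUE)
  edf <- data.frame(from = vapply(pair, `[[`, character(1), 1L),
                    to = vapply(pair, `[[`, character(1), 2L),
                    nmatches = as.numeric(tab), stringsAsFactors = FALSE)
  edf <- edf[order(edf$from, edf$to, method = "radix"), , drop = FALSE]
  sp_ids <- sort(unique(edf$from), method = "radix")
  mge_ids <- sort(unique(edf$to), method = "radix")
  ctype <- vapply(sp_ids, function(id)
    collapse_types(clusters$crispr_types[[match(id, clusters$cluster_id)]]),
    character(1))
  meta_of <- function(ids, col) {
    if (is.null(mge_meta) || !col %in% names(mge_meta))
      return(rep("", length(ids)))
    v <- as.character(mge_meta[[col]][match(ids, mge_meta$mge_id)])
    ifelse(is.na(v), "", v)
  }
  vdf <- data.frame(
    name = c(sp_ids, mge_ids),
    kind = c(rep("spacer", length(sp_ids)), rep("mge", length(mge_ids))),
    crisprtype = c(ctype, rep("", length(mge_ids))),
    mgeclass = c(rep("", length(sp_ids)), meta_of(mge_ids, "mge_class")),
    sourcedb = c(rep("", length(sp_ids)), meta_of(mge_ids, "source_db")),
    knownhost = c(rep("", length(sp_ids)), meta_of(mge_ids, "known_host")),
    stringsAsFactors = FALSE)
  make_network(vdf, edf, "spacer_mge")
}

#' Build the host-MGE interaction network
#'
#' An edge joins a selected host to a selected MGE when some spacer cluster
#' with a member in that host has a passing hit to that MGE.  The edge
#' attribute \code{nmatches} counts distinct (cluster, locus) matched
#' pairs.  Hosts whose spacers match nothing are absent (degree >= 1).
#'
#' @param hits filtered hits data.frame.
#' @param selected_hosts host ids from [select_hosts()].
#' @param selected_mges MGE ids from [select_mges()].
#' @param catalog spacer occurrence table (see [select_hosts()]).
#' @param mge_meta optional MGE metadata (see
#'   [build_spacer_mge_network()]).
#' @param host_meta optional data.frame with \code{host_id}, \code{taxon}.
#' @return an \pkg{igraph} undirected bipartite graph; host nodes carry
#'   \code{kind = "host"} and \code{taxon}.
#' @export
build_host_mge_network <- function(hits, selected_hosts, selected_mges,
                                   catalog, mge_meta = NULL,
                                   host_meta = NULL) {
  empty <- make_network(
    data.frame(name = character(0), kind = character(0),
               taxon = character(0), mgeclass = character(0),
               sourcedb = character(0), knownhost = character(0),
               stringsAsFactors = FALSE),
    data.frame(from = character(0), to = character(0),
               nmatches = numeric(0), stringsAsFactors = FALSE),
    "host_mge")
  h <- hits[hits$mge_id %in% selected_mges, , drop = FALSE]
  if (nrow(h) == 0L) return(empty)
  cl2hosts <- lapply(split(catalog$host_id, catalog$cluster_id), unique)
  pairs <- character(0)
  for (i in seq_len(nrow(h))) {
    hs <- intersect(cl2hosts[[h$cluster_id[i]]], selected_hosts)
    if (length(hs))
      pairs <- c(pairs, paste(hs, h$mge_id[i], sep = "\r"))
  }
  if (!length(pairs)) return(empty)
  tab <- table(pairs)
  pp <- strsplit(names(tab), "\r", fixed = TRUE)
  edf <- data.frame(from = vapply(pp, `[[`, character(1), 1L),
                    to = vapply(pp, `[[`, character(1), 2L),
                    nmatches = as.numeric(tab), stringsAsFactors = FALSE)
  edf <- edf[order(edf$from, edf$to, method = "radix"), , drop = FALSE]
  host_ids <- sort(unique(edf$from), method = "radix")
  mge_ids <- sort(unique(edf$to), method = "radix")
  meta_of <- function(meta, ids, id_col, col, n) {
    if (is.null(meta) || !col %in% names(meta)) return(rep("", n))
    v <- as.character(meta[[col]][match(ids, meta[[id_col]])])
    ifelse(is.na(v), "", v)
  }
  vdf <- data.frame(
    name = c(host_ids, mge_ids),
    kind = c(rep("host", length(host_ids)), rep("mge", length(mge_ids))),
    taxon = c(meta_of(host_meta, host_ids, "host_id", "taxon",
                      length(host_ids)),
              rep("", length(mge_ids))),
    mgeclass = c(rep("", length(host_ids)),
                 meta_of(mge_meta, mge_ids, "mge_id", "mge_class",
                         length(mge_ids))),
    sourcedb = c(rep("", length(host_ids)),
                 meta_of(mge_meta, mge_ids, "mge_id", "source_db",
                         length(mge_ids))),
    knownhost = c(rep("", length(host_ids)),
                  meta_of(mge_meta, mge_ids, "mge_id", "known_host",
                          length(mge_ids))),
    stringsAsFactors = FALSE)
  make_network(vdf, edf, "host_mge")
}

#' Connected components of an interaction network
#'
#' Components are numbered by decreasing node count, ties broken by the
#' lexicographically smallest member node id.
#'
#' @param network an \pkg{igraph} network from the build functions.
#' @return list with \code{membership} (named integer vector: component id
#'   per node) and \code{components} (list; each element has
#'   \code{component_id}, \code{nodes}, and the [module_type_report()]
#'   counts).
#' @export
network_components <- function(network) {
  n <- igraph::vcount(network)
  if (n == 0L) return(list(membership = integer(0), components = list()))
  cmp <- igraph::components(network)
  nodes_by <- split(igraph::V(network)$name, cmp$membership)
  sizes <- lengths(nodes_by)
  first <- vapply(nodes_by, function(x) sort(x, method = "radix")[1],
                  character(1))
  ord <- order(-sizes, first, method = "radix")
  nodes_by <- nodes_by[ord]
  comps <- vector("list", length(nodes_by))
  membership <- integer(n)
  names(membership) <- igraph::V(network)$name
  for (i in seq_along(nodes_by)) {
    nd <- sort(nodes_by[[i]], method = "radix")
    membership[nd] <- i
    comps[[i]] <- c(list(component_id = i, nodes = nd),
                    module_type_report(nd, network))
  }
  list(membership = membership, components = comps)
}

#' Node composition of one network module
#'
#' Counts spacer nodes per CRISPR type, host nodes, and phage/plasmid MGE
#' nodes among the given nodes.  Spacers without a type label are counted
#' under \code{"untyped"}.
#'
#' @param nodes character vector of node ids (one component/module).
#' @param network the \pkg{igraph} network the nodes belong to.
#' @return list with \code{n_nodes}, \code{n_spacers}, \code{n_hosts},
#'   \code{n_mges}, \code{n_phages}, \code{n_plasmids} and
#'   \code{spacer_types} (named integer vector).
#' @export
module_type_report <- function(nodes, network) {
  vi <- match(nodes, igraph::V(network)$name)
  if (anyNA(vi)) stop("unknown node id(s)", call. = FALSE)
  kind <- igraph::V(network)$kind[vi]
  is_sp <- kind == "spacer"
  st <- integer(0)
  if (any(is_sp)) {
    ct <- igraph::V(network)$crisprtype[vi][is_sp]
    ct[is.na(ct) | ct == ""] <- "untyped"
    tt <- table(ct)
    st <- as.integer(tt)
    names(st) <- names(tt)
    st <- st[order(-st, names(st), method = "radix")]
  }
  cls <- if (!is.null(igraph::V(network)$mgeclass))
    igraph::V(network)$mgeclass[vi] else rep("", length(vi))
  list(n_nodes = length(nodes),
       n_spacers = sum(is_sp),
       n_hosts = sum(kind == "host"),
       n_mges = sum(kind == "mge"),
       n_phages = sum(kind == "mge" & cls == "phage"),
       n_plasmids = sum(kind == "mge" & cls == "plasmid"),
       spacer_types = st)
}

#' Write a component summary table
#'
#' @param comps result of [network_components()].
#' @param path output TSV.
#' @export
write_components_tsv <- function(comps, path) {
  rows <- lapply(comps$components, function(cp) {
    st <- cp$spacer_types
    data.frame(component_id = cp$component_id, n_nodes = cp$n_nodes,
               n_spacers = cp$n_spacers, n_hosts = cp$n_hosts,
               n_mges = cp$n_mges, n_phages = cp$n_phages,
               n_plasmids = cp$n_plasmids,
               spacer_types = if (length(st))
                 paste(names(st), st, sep = "=", collapse = ";") else "",
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(component_id = integer(0), n_nodes = integer(0),
               n_spacers = integer(0), n_hosts = integer(0),
               n_mges = integer(0), n_phages = integer(0),
               n_plasmids = integer(0), spacer_types = character(0),
               stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Write a network to file
#'
#' \code{"gml"} writes Graph Modelling Language (readable by Cytoscape,
#' igraph and NetworkX) with node attributes and the \code{nmatches} edge
#' attribute; [read_network()] round-trips it losslessly.  \code{"tsv"}
#' writes \code{<path>_nodes.tsv} and \code{<path>_edges.tsv} for direct
#' Cytoscape table import.
#'
#' @param network an \pkg{igraph} network.
#' @param path output file (for \code{"tsv"}, the path prefix).
#' @param format \code{"gml"} (default) or \code{"tsv"}.
#' @export
write_network <- function(network, path, format = c("gml", "tsv")) {
  format <- match.arg(format)
  if (format == "gml") {
    dir_ok <- dir.exists(dirname(path))
    if (!dir_ok) stop("cannot write network: directory does not exist: ",
                      dirname(path), call. = FALSE)
    igraph::write_graph(network, path, format = "gml")
    # the stock Creator line embeds a timestamp; pin it for reproducibility
    lines <- readLines(path)
    lines[grepl("^Creator ", lines)] <- "Creator \"crisprnet\""
    writeLines(lines, path)
  } else {
    vdf <- as.data.frame(igraph::vertex_attr(network),
                         stringsAsFactors = FALSE)
    edf <- igraph::as_data_frame(network, what = "edges")
    write_tsv(vdf, paste0(path, "_nodes.tsv"))
    write_tsv(edf, paste0(path, "_edges.tsv"))
  }
  invisible(path)
}

#' Read a GML network written by [write_network()]
#'
#' @param path GML file.
#' @return an \pkg{igraph} network.
#' @export
read_network <- function(path) {
  igraph::read_graph(path, format = "gml")
}

## structural + attribute equality of two networks (order-insensitive)
networks_equal <- function(g1, g2) {
  n1 <- sort(igraph::V(g1)$name, method = "radix")
  n2 <- sort(igraph::V(g2)$name, method = "radix")
  if (!identical(n1, n2)) return(FALSE)
  va <- function(g) {
    at <- igraph::vertex_attr(g)
    at <- at[setdiff(names(at), "id")]
    df <- as.data.frame(at, stringsAsFactors = FALSE)
    df[order(df$name, method = "radix"),
       sort(names(df), method = "radix"), drop = FALSE]
  }
  a1 <- va(g1); a2 <- va(g2)
  rownames(a1) <- rownames(a2) <- NULL
  if (!isTRUE(all.equal(a1, a2, check.attributes = FALSE))) return(FALSE)
  ea <- function(g) {
    ed <- igraph::as_data_frame(g, what = "edges")
    u <- pmin(ed$from, ed$to); v <- pmax(ed$from, ed$to)
    ed <- data.frame(u = u, v = v, nmatches = ed$nmatches,
                     stringsAsFactors = FALSE)
    ed[order(ed$u, ed$v, method = "radix"), , drop = FALSE]
  }
  e1 <- ea(g1); e2 <- ea(g2)
  rownames(e1) <- rownames(e2) <- NULL
  isTRUE(all.equal(e1, e2, check.attributes = FALSE))
}

#' Write selected MGE sequences as annotated FASTA
#'
#' @param db MGE database data.frame from [read_mge_db()].
#' @param selected MGE ids to write (selection order preserved).
#' @param path output FASTA.
#' @export
write_selected_mges_fasta <- function(db, selected, path) {
  i <- match(selected, db$mge_id)
  if (anyNA(i))
    stop("selected MGE id(s) absent from database: ",
         paste(selected[is.na(i)], collapse = ", "), call. = FALSE)
  seqs <- db$seq[i]
  names(seqs) <- sprintf("%s class=%s source=%s known_host=%s",
                         db$mge_id[i], db$mge_class[i], db$source_db[i],
                         ifelse(nzchar(db$known_host[i]), db$known_host[i],
                                "NA"))
  write_fasta(seqs, path)
}
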