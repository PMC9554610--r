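#' Pipeline configuration
#'
#' Bundles the input paths and stage parameters for [run_pipeline()].
#'
#' @param genomes host genomes: either one multi-FASTA path (each record
#'   is one host) or a named vector of FASTA paths (one file per host;
#'   records are its contigs; names default to file base names).
#' @param mge_fasta MGE database multi-FASTA.
#' @param mge_metadata optional MGE metadata TSV (see [read_mge_db()]).
#' @param workdir output directory (created if missing).
#' @param mode CRISPR detection mode: \code{"denovo"}, \code{"guided"} or
#'   \code{"both"} (guided arrays take precedence where they overlap a de
#'   novo call).
#' @param repeat_library repeat library FASTA (required for guided modes).
#' @param detection a [detection_params()] list.
#' @param search a [search_params()] list.
#' @param dedup_mode spacer dedup mode (see [deduplicate_spacers()]).
#' @param external_hits optional precomputed 12-column tabular hits; when
#'   given, the built-in search is skipped.
#' @param host_meta optional data.frame with \code{host_id}, \code{taxon}.
#' @return a validated list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(genomes, mge_fasta, mge_metadata = NULL,
                            workdir,
                            mode = c("denovo", "guided", "both"),
                            repeat_library = NULL,
                            detection = detection_params(),
                            search = search_params(),
                            dedup_mode = "exact",
                            external_hits = NULL, host_meta = NULL) {
  mode <- match.arg(mode)
  for (p in c(genomes, mge_fasta, mge_metadata, repeat_library,
              external_hits))
    if (!file.exists(p)) stop("input path does not exist: ", p,
                              call. = FALSE)
  if (mode != "denovo" && is.null(repeat_library))
    stop("mode '", mode, "' needs a repeat_library", call. = FALSE)
  structure(list(genomes = genomes, mge_fasta = mge_fasta,
                 mge_metadata = mge_metadata, workdir = workdir,
                 mode = mode, repeat_library = repeat_library,
                 detection = detection, search = search,
                 dedup_mode = dedup_mode, external_hits = external_hits,
                 host_meta = host_meta),
            class = "pipeline_config")
}

## drop denovo arrays overlapping a guided array on the same contig
merge_mode_arrays <- function(guided, denovo) {
  keep <- vapply(denovo, function(d) {
    !any(vapply(guided, function(g)
      g$contig_id == d$contig_id && g$start <= d$end && g$end >= d$start,
      logical(1)))
  }, logical(1))
  c(guided, denovo[keep])
}

#' Run the full interaction-network inference pipeline
#'
#' Executes detect -> extract/dedup -> search (built-in, or ingest of
#' external tabular hits) -> filter -> greedy MGE and host selection ->
#' spacer-MGE and host-MGE networks -> connected components, writing all
#' artifacts plus a stage-count manifest and a log into the work
#' directory.  Re-running on identical inputs reproduces identical
#' artifacts; empty intermediate results yield empty-but-valid downstream
#' files.
#'
#' @param config a [pipeline_config()] object.
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the manifest counts, the principal
#'   in-memory objects and the artifact paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$workdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  out_path <- function(f) file.path(config$workdir, f)

  # --- detect ---------------------------------------------------------
  res <- stage("detect", {
    contigs <- list()   # list of (record, host_id)
    if (length(config$genomes) == 1L && is.null(names(config$genomes))) {
      for (r in read_fasta_records(config$genomes))
        contigs[[length(contigs) + 1L]] <- list(rec = r, host = r$id)
    } else {
      nm <- names(config$genomes)
      if (is.null(nm)) nm <- rep("", length(config$genomes))
      for (i in seq_along(config$genomes)) {
        host <- if (nzchar(nm[i])) nm[i] else
          sub("\\.(fa|fasta|fna)(\\.gz)?$", "",
              basename(config$genomes[i]))
        for (r in read_fasta_records(config$genomes[i]))
          contigs[[length(contigs) + 1L]] <- list(rec = r, host = host)
      }
    }
    lib <- if (!is.null(config$repeat_library))
      read_repeat_library(config$repeat_library) else NULL
    arrays <- list()
    min_len <- 2L * config$detection$min_repeat_len +
      config$detection$min_spacer_len
    for (ct in contigs) {
      if (ct$rec$length < min_len) next  # cannot hold an array
      a <- switch(config$mode,
        denovo = find_denovo_arrays(ct$rec, config$detection,
                                    host_id = ct$host),
        guided = find_guided_arrays(ct$rec, lib, config$detection,
                                    host_id = ct$host),
        both = merge_mode_arrays(
          find_guided_arrays(ct$rec, lib, config$detection,
                             host_id = ct$host),
          find_denovo_arrays(ct$rec, config$detection,
                             host_id = ct$host)))
      arrays <- c(arrays, a)
    }
    arrays <- filter_artifacts(arrays, config$detection)
    # stable unique ids across contigs and modes
    for (i in seq_along(arrays))
      arrays[[i]]$array_id <- sprintf("%s_arr%03d",
                                      arrays[[i]]$contig_id, i)
    list(arrays = arrays, n_contigs = length(contigs),
         n_hosts = length(unique(vapply(contigs, `[[`, character(1),
                                        "host"))))
  })
  arrays <- res$arrays
  say("detect: ", length(arrays), " arrays in ", res$n_contigs,
      " contigs (", res$n_hosts, " hosts)")
  write_arrays_tsv(arrays, out_path("arrays.tsv"))
  write_arrays_gff(arrays, out_path("arrays.gff"))

  # --- extract & dedup ------------------------------------------------
  spacers <- stage("extract", extract_spacers(arrays))
  clusters <- stage("dedup", deduplicate_spacers(spacers,
                                                 config$dedup_mode))
  catalog <- merge(spacers, spacer_cluster_map(clusters),
                   by = "spacer_id", sort = TRUE)
  say("extract/dedup: ", nrow(spacers), " spacers, ", nrow(clusters),
      " unique clusters")
  write_spacer_fasta(spacers, clusters, out_path("spacers.fasta"))

  # --- search & filter ------------------------------------------------
  db <- stage("read_mge_db",
              read_mge_db(config$mge_fasta, config$mge_metadata))
  hits_all <- stage("search", {
    if (nrow(clusters) == 0L) empty_hits()
    else if (!is.null(config$external_hits))
      read_tabular_hits(config$external_hits,
                        stats::setNames(nchar(clusters$rep_seq),
                                        clusters$cluster_id))
    else search_spacers(clusters, db, config$search)
  })
  hits <- stage("filter", filter_hits(hits_all, config$search))
  say("search: ", nrow(hits_all), " raw hits, ", nrow(hits),
      " pass the retention filters")
  write_hits_tsv(hits, out_path("hits_filtered.tsv"))

  # --- selections -----------------------------------------------------
  sel_mges <- stage("select_mges", select_mges(hits))
  sel_hosts <- stage("select_hosts", select_hosts(hits, catalog))
  sel_class <- db$mge_class[match(sel_mges, db$mge_id)]
  say("greedy selection: ", length(sel_mges), " MGEs (",
      sum(sel_class == "phage"), " phages, ",
      sum(sel_class == "plasmid"), " plasmids), ",
      length(sel_hosts), " hosts")
  writeLines(sel_mges, out_path("selected_mges.txt"))
  writeLines(sel_hosts, out_path("selected_hosts.txt"))
  write_selected_mges_fasta(db, sel_mges, out_path("selected_mges.fasta"))

  # --- networks & components -----------------------------------------
  net_sm <- stage("spacer_mge_network",
                  build_spacer_mge_network(hits, sel_mges, clusters, db))
  net_hm <- stage("host_mge_network",
                  build_host_mge_network(hits, sel_hosts, sel_mges,
                                         catalog, db, config$host_meta))
  write_network(net_sm, out_path("spacer_mge.gml"))
  write_network(net_hm, out_path("host_mge.gml"))
  cmp_sm <- stage("components", network_components(net_sm))
  cmp_hm <- stage("components", network_components(net_hm))
  write_components_tsv(cmp_sm, out_path("components_spacer_mge.tsv"))
  write_components_tsv(cmp_hm, out_path("components_host_mge.tsv"))
  say("networks: spacer-MGE ", igraph::vcount(net_sm), " nodes / ",
      igraph::ecount(net_sm), " edges (",
      length(cmp_sm$components), " components); host-MGE ",
      igraph::vcount(net_hm), " nodes / ", igraph::ecount(net_hm),
      " edges (", length(cmp_hm$components), " components)")

  manifest <- list(
    mode = config$mode,
    n_hosts = res$n_hosts,
    n_contigs = res$n_contigs,
    n_arrays = length(arrays),
    n_spacers = nrow(spacers),
    n_clusters = nrow(clusters),
    n_matched_clusters = length(unique(hits$cluster_id)),
    n_hits_filtered = nrow(hits),
    n_selected_mges = length(sel_mges),
    n_selected_phages = sum(sel_class == "phage"),
    n_selected_plasmids = sum(sel_class == "plasmid"),
    n_selected_hosts = length(sel_hosts),
    n_components_spacer_mge = length(cmp_sm$components),
    n_components_host_mge = length(cmp_hm$components))
  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, out_path("run.log"))

  invisible(list(manifest = manifest, arrays = arrays, spacers = spacers,
                 clusters = clusters, catalog = catalog, hits = hits,
                 selected_mges = sel_mges, selected_hosts = sel_hosts,
                 spacer_mge = net_sm, host_mge = net_hm,
                 components_spacer_mge = cmp_sm,
                 components_host_mge = cmp_hm,
                 workdir = config$workdir))
}
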