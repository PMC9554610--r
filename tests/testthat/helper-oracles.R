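# Independent oracles used to cross-check the implementation.
# They deliberately share no code with the package internals.

# all-offsets full-coverage Hamming scan of spacers against MGEs, with its
# own bisection solve of the Karlin-Altschul lambda; returns the hits that
# clear the identity/coverage/e-value retention thresholds
oracle_hamming_search <- function(clusters, db, min_identity = 0.90,
                                  max_evalue = 1e-3, karlin_k = 0.46) {
  lam_lo <- 0; lam_hi <- 5
  for (i in 1:200) {  # bisection for (1/4)e^l + (3/4)e^(-2l) = 1
    mid <- (lam_lo + lam_hi) / 2
    if (0.25 * exp(mid) + 0.75 * exp(-2 * mid) < 1) lam_lo <- mid
    else lam_hi <- mid
  }
  lam <- (lam_lo + lam_hi) / 2
  n_total <- sum(nchar(db$seq))
  out <- list()
  for (ci in seq_len(nrow(clusters))) {
    q <- clusters$rep_seq[ci]
    qlen <- nchar(q)
    qc <- strsplit(q, "")[[1]]
    rcq <- strsplit(crisprnet::revcomp(q), "")[[1]]
    for (mi in seq_len(nrow(db))) {
      sc <- strsplit(db$seq[mi], "")[[1]]
      slen <- length(sc)
      if (slen < qlen) next
      for (a in seq_len(slen - qlen + 1)) {
        win <- sc[a:(a + qlen - 1)]
        for (strand in c("+", "-")) {
          m <- sum(win == (if (strand == "+") qc else rcq))
          ident <- m / qlen
          score <- m - 2 * (qlen - m)
          ev <- karlin_k * qlen * n_total * exp(-lam * score)
          if (ident > min_identity && ev < max_evalue) {
            ss <- if (strand == "+") a else a + qlen - 1
            se <- if (strand == "+") a + qlen - 1 else a
            out[[length(out) + 1]] <- data.frame(
              cluster_id = clusters$cluster_id[ci],
              mge_id = db$mge_id[mi], strand = strand,
              s_start = ss, s_end = se, identity = ident,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(out)) return(data.frame(cluster_id = character(0),
                                      mge_id = character(0),
                                      strand = character(0),
                                      s_start = integer(0),
                                      s_end = integer(0),
                                      identity = numeric(0)))
  df <- do.call(rbind, out)
  df[order(df$cluster_id, df$mge_id, df$strand, df$s_start,
           method = "radix"), , drop = FALSE]
}

hit_key <- function(h) {
  if (nrow(h) == 0) return(character(0))
  sort(paste(h$cluster_id, h$mge_id, h$strand, h$s_start, h$s_end,
             round(h$identity, 6), sep = "|"), method = "radix")
}

# breadth-first-search connected components from every node; returns the
# partition ordered by decreasing size then smallest member id
oracle_bfs_components <- function(nodes, edges_from, edges_to) {
  adj <- split(c(edges_to, edges_from), c(edges_from, edges_to))
  seen <- setNames(rep(FALSE, length(nodes)), nodes)
  comps <- list()
  for (n in nodes) {
    if (seen[[n]]) next
    queue <- n; seen[[n]] <- TRUE; comp <- character(0)
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, v)
      for (w in adj[[v]]) if (!seen[[w]]) { seen[[w]] <- TRUE
        queue <- c(queue, w) }
    }
    comps[[length(comps) + 1]] <- sort(comp, method = "radix")
  }
  sizes <- lengths(comps)
  first <- vapply(comps, `[`, character(1), 1)
  comps[order(-sizes, first, method = "radix")]
}

# exhaustive minimum set cover via bitmask enumeration (<= 20 elements,
# <= 12 candidates); returns the minimum number of candidates needed
oracle_min_cover_size <- function(universe, candidates) {
  elems <- sort(unique(universe))
  masks <- vapply(candidates, function(s)
    sum(bitwShiftL(1, match(s, elems) - 1)), numeric(1))
  full <- sum(bitwShiftL(1, seq_along(elems) - 1))
  nc <- length(masks)
  nsub <- 2^nc
  or_mask <- integer(nsub)  # subset-DP over the 2^nc candidate subsets
  popc <- integer(nsub)
  for (sub in seq_len(nsub - 1)) {
    low <- bitwAnd(sub, -sub)
    j <- round(log2(low)) + 1
    rest <- sub - low
    or_mask[sub + 1] <- bitwOr(or_mask[rest + 1], masks[j])
    popc[sub + 1] <- popc[rest + 1] + 1
  }
  min(popc[or_mask == full])
}

# random covering instance: returns list(universe, candidates)
random_cover_instance <- function(max_elems = 20, max_cands = 12) {
  ne <- sample(3:max_elems, 1)
  nc <- sample(2:max_cands, 1)
  elems <- sprintf("e%02d", seq_len(ne))
  cands <- lapply(seq_len(nc), function(i)
    sample(elems, sample.int(ne, 1)))
  names(cands) <- sprintf("c%02d", seq_len(nc))
  universe <- sort(unique(unlist(cands)))
  list(universe = universe, candidates = cands)
}

# hand-built clusters table (as deduplicate_spacers would emit)
make_clusters <- function(seqs, ids = sprintf("SC%05d", seq_along(seqs))) {
  data.frame(cluster_id = ids, rep_seq = seqs,
             n_members = 1L,
             members = I(as.list(paste0(ids, "_m"))),
             crispr_types = I(rep(list(character(0)), length(seqs))),
             stringsAsFactors = FALSE)
}

make_db <- function(seqs, ids = sprintf("mge_%03d", seq_along(seqs)),
                    cls = "phage") {
  data.frame(mge_id = ids, seq = seqs,
             mge_class = rep_len(cls, length(seqs)),
             source_db = "test", known_host = "", stringsAsFactors = FALSE)
}
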