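#' Parameters for CRISPR array detection
#'
#' Defaults follow the usual geometry of bacterial CRISPR arrays: repeats of
#' 23-55 bp separated by spacers of 18-72 bp, with at least three repeat
#' units required to call an array.
#'
#' @param min_repeat_len,max_repeat_len allowed repeat length range (bp).
#' @param min_spacer_len,max_spacer_len allowed spacer length range (bp).
#' @param min_repeats minimum number of repeat units per array.
#' @param seed_k exact k-mer length used to seed de novo repeat discovery.
#' @param window maximum distance (bp) between successive seed occurrences
#'   considered part of one candidate array.
#' @param max_repeat_mismatch maximum substitutions between a repeat unit and
#'   the consensus (guided mode: between a genomic window and a library
#'   repeat, on either strand).
#' @param spacer_sim_cutoff artifact filter: arrays whose mean pairwise
#'   spacer identity exceeds this are removed (tandem-repeat mimics).
#' @param repeat_spacer_sim_cutoff artifact filter: arrays whose mean
#'   spacer-to-consensus-repeat identity exceeds this are removed.
#' @return a list of class \code{"detection_params"}.
#' @export
detection_params <- function(min_repeat_len = 23L, max_repeat_len = 55L,
                             min_spacer_len = 18L, max_spacer_len = 72L,
                             min_repeats = 3L, seed_k = 13L, window = 500L,
                             max_repeat_mismatch = 3L,
                             spacer_sim_cutoff = 0.60,
                             repeat_spacer_sim_cutoff = 0.60) {
  stopifnot(min_repeat_len >= seed_k, min_spacer_len > 0,
            min_repeat_len <= max_repeat_len,
            min_spacer_len <= max_spacer_len, min_repeats >= 2L)
  structure(list(min_repeat_len = as.integer(min_repeat_len),
                 max_repeat_len = as.integer(max_repeat_len),
                 min_spacer_len = as.integer(min_spacer_len),
                 max_spacer_len = as.integer(max_spacer_len),
                 min_repeats = as.integer(min_repeats),
                 seed_k = as.integer(seed_k),
                 window = as.integer(window),
                 max_repeat_mismatch = as.integer(max_repeat_mismatch),
                 spacer_sim_cutoff = spacer_sim_cutoff,
                 repeat_spacer_sim_cutoff = repeat_spacer_sim_cutoff),
            class = "detection_params")
}

new_crispr_array <- function(array_id, host_id, contig_id, start, end, strand,
                             repeats, spacers, consensus_repeat,
                             crispr_type = NA_character_, mode) {
  structure(list(array_id = array_id, host_id = host_id,
                 contig_id = contig_id, start = start, end = end,
                 strand = strand, repeats = repeats, spacers = spacers,
                 consensus_repeat = consensus_repeat,
                 crispr_type = crispr_type, mode = mode),
            class = "crispr_array")
}

#' @export
print.crispr_array <- function(x, ...) {
  cat(sprintf("<crispr_array %s> %s:%d-%d (%s) %d repeats, %d spacers, type=%s, mode=%s\n",
              x$array_id, x$contig_id, x$start, x$end, x$strand,
              nrow(x$repeats), nrow(x$spacers),
              ifelse(is.na(x$crispr_type), "untyped", x$crispr_type), x$mode))
  invisible(x)
}

## maximal extension of a seeded repeat run; positions are seed starts of an
## exact seed_k-mer.  Extends left/right while the column is identical across
## all units, subject to repeat-length and minimum-spacer constraints.
extend_seed_run <- function(seq, L, pos, k, params) {
  n <- length(pos)
  diffs <- diff(pos)
  budget <- min(min(diffs) - k - params$min_spacer_len,
                params$max_repeat_len - k)
  if (budget < 0L) budget <- 0L
  col_equal <- function(at) {
    if (any(at < 1L) || any(at > L)) return(FALSE)
    b <- substring(seq, at, at)
    b[1] != "N" && all(b == b[1])
  }
  dl <- 0L
  while (dl < budget && col_equal(pos - dl - 1L)) dl <- dl + 1L
  dr <- 0L
  while (dl + dr < budget && col_equal(pos + k + dr)) dr <- dr + 1L
  list(dl = dl, dr = dr, rep_len = dl + k + dr)
}

## split positions into maximal stretches whose inter-repeat gaps (spacers)
## fall within the allowed spacer length range
split_by_gap <- function(pos, rep_len, params) {
  if (length(pos) < 2L) return(list(pos))
  sp <- diff(pos) - rep_len
  ok <- sp >= params$min_spacer_len & sp <= params$max_spacer_len
  segs <- list(); cur <- pos[1]
  for (i in seq_along(ok)) {
    if (ok[i]) cur <- c(cur, pos[i + 1L])
    else { segs[[length(segs) + 1L]] <- cur; cur <- pos[i + 1L] }
  }
  segs[[length(segs) + 1L]] <- cur
  segs
}

## resolve overlapping candidate intervals, preferring more repeat units,
## then fewer mismatches, then leftmost start
resolve_overlaps <- function(cands) {
  if (length(cands) <= 1L) return(cands)
  n_rep <- vapply(cands, function(x) length(x$pos), integer(1))
  mm <- vapply(cands, function(x) x$mismatches, numeric(1))
  st <- vapply(cands, function(x) x$start, integer(1))
  en <- vapply(cands, function(x) x$end, integer(1))
  ord <- order(-n_rep, mm, st, en)
  kept <- integer(0)
  for (i in ord) {
    if (!any(st[i] <= en[kept] & en[i] >= st[kept]))
      kept <- c(kept, i)
  }
  cands[kept[order(st[kept])]]
}

#' Detect CRISPR arrays de novo from the repeat-spacer structure
#'
#' Finds candidate repeats by exact k-mer seeding (k-mers recurring with a
#' CRISPR-like period), extends each seed maximally while the flanking
#' column is identical across all repeat units, chains units whose gaps
#' (spacers) fall in the allowed length range, and reports non-overlapping
#' arrays left to right.  Repeat/spacer boundaries are placed at the first
#' column where the units disagree, so reported repeat units are exact
#' copies of the consensus.
#'
#' @param contig a [sequence_record()] or a single (optionally named) DNA
#'   string.
#' @param params a [detection_params()] list.
#' @param host_id host identifier attached to resulting arrays; defaults to
#'   the contig id.
#' @return list of \code{crispr_array} objects (possibly empty), ordered by
#'   start coordinate.  Coordinates are 1-based inclusive.
#' @export
find_denovo_arrays <- function(contig, params = detection_params(),
                               host_id = NULL) {
  rec <- as_sequence_record(contig)
  if (is.null(host_id)) host_id <- rec$id
  seq <- rec$seq; L <- rec$length
  if (L < 2L * params$min_repeat_len + params$min_spacer_len)
    stop("contig '", rec$id, "' is too short to contain a CRISPR array",
         call. = FALSE)
  k <- params$seed_k
  starts <- seq_len(L - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  okk <- !grepl("N", kmers, fixed = TRUE)
  pos_by_kmer <- split(starts[okk], kmers[okk])
  pos_by_kmer <- pos_by_kmer[lengths(pos_by_kmer) >= params$min_repeats]
  p_lo <- params$min_repeat_len + params$min_spacer_len
  p_hi <- min(params$max_repeat_len + params$max_spacer_len, params$window)

  cands <- list()
  add_candidate <- function(pos) {
    ext <- extend_seed_run(seq, L, pos, k, params)
    if (ext$rep_len < params$min_repeat_len) return()
    for (seg in split_by_gap(pos, ext$rep_len, params)) {
      if (length(seg) < params$min_repeats) next
      ext2 <- if (length(seg) == length(pos)) ext else
        extend_seed_run(seq, L, seg, k, params)
      if (ext2$rep_len < params$min_repeat_len) next
      seg_ok <- split_by_gap(seg, ext2$rep_len, params)
      for (s2 in seg_ok) {
        if (length(s2) < params$min_repeats) next
        cands[[length(cands) + 1L]] <<- list(
          pos = s2 - ext2$dl, rep_len = ext2$rep_len, mismatches = 0,
          start = s2[1] - ext2$dl,
          end = s2[length(s2)] - ext2$dl + ext2$rep_len - 1L)
      }
    }
  }

  for (pos in pos_by_kmer) {
    pos <- sort(pos)
    # collapse seed occurrences closer than a minimal repeat+spacer period
    # (duplicates within one unit, or sub-CRISPR tandem periodicity)
    kept <- pos[1]
    for (p in pos[-1]) if (p - kept[length(kept)] >= p_lo) kept <- c(kept, p)
    if (length(kept) < params$min_repeats) next
    # chain occurrences with CRISPR-like periods into runs
    run <- kept[1]
    for (i in seq_len(length(kept) - 1L)) {
      d <- kept[i + 1L] - kept[i]
      if (d >= p_lo && d <= p_hi) run <- c(run, kept[i + 1L])
      else {
        if (length(run) >= params$min_repeats) add_candidate(run)
        run <- kept[i + 1L]
      }
    }
    if (length(run) >= params$min_repeats) add_candidate(run)
  }

  # identical arrays arise from every seed k-mer inside the repeat
  if (length(cands)) {
    key <- vapply(cands, function(x)
      paste(x$start, x$end, x$rep_len, sep = ":"), character(1))
    cands <- cands[!duplicated(key)]
  }
  cands <- resolve_overlaps(cands)

  out <- vector("list", length(cands))
  for (i in seq_along(cands)) {
    cc <- cands[[i]]
    rep_starts <- cc$pos
    rep_seqs <- substring(seq, rep_starts, rep_starts + cc$rep_len - 1L)
    sp_starts <- rep_starts[-length(rep_starts)] + cc$rep_len
    sp_ends <- rep_starts[-1] - 1L
    out[[i]] <- new_crispr_array(
      array_id = paste0(rec$id, "_array", i), host_id = host_id,
      contig_id = rec$id, start = cc$start, end = cc$end, strand = "+",
      repeats = data.frame(start = rep_starts, seq = rep_seqs,
                           stringsAsFactors = FALSE),
      spacers = data.frame(start = sp_starts,
                           seq = substring(seq, sp_starts, sp_ends),
                           stringsAsFactors = FALSE),
      consensus_repeat = rep_seqs[1], crispr_type = NA_character_,
      mode = "denovo")
  }
  out
}

#' Read a CRISPR repeat library from FASTA
#'
#' A CRISPR type label is parsed from a \code{type=<label>} token on the
#' description line, if present.
#'
#' @param path FASTA file of repeat sequences (each at least 16 bp).
#' @return data.frame with columns \code{id}, \code{seq}, \code{crispr_type}.
#' @export
read_repeat_library <- function(path) {
  recs <- read_fasta_records(path)
  df <- data.frame(
    id = vapply(recs, `[[`, character(1), "id"),
    seq = vapply(recs, `[[`, character(1), "seq"),
    crispr_type = vapply(recs, function(r) {
      m <- regmatches(r$description,
                      regexpr("type=[^ \t|]+", r$description))
      if (length(m)) sub("^type=", "", m) else NA_character_
    }, character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  validate_repeat_library(df)
  df
}

validate_repeat_library <- function(library) {
  if (!is.data.frame(library) || nrow(library) == 0L)
    stop("repeat library must be a non-empty data.frame", call. = FALSE)
  if (!all(c("id", "seq") %in% names(library)))
    stop("repeat library needs columns 'id' and 'seq'", call. = FALSE)
  short <- nchar(library$seq) < 16L
  if (any(short))
    stop("repeat library entries shorter than 16 bp: ",
         paste(library$id[short], collapse = ", "), call. = FALSE)
  invisible(library)
}

## sliding-window Hamming mismatch counts of `pat` along `seq` (N counts as
## a mismatch); returns one count per start offset
mismatch_profile <- function(seq, pat) {
  sr <- charToRaw(seq); pr <- charToRaw(pat)
  m <- length(pr); L <- length(sr)
  if (L < m) return(integer(0))
  n_off <- L - m + 1L
  mm <- integer(n_off)
  for (j in seq_len(m)) mm <- mm + (sr[j:(j + n_off - 1L)] != pr[j])
  mm
}

#' Detect CRISPR arrays guided by a library of known repeats
#'
#' Scans both strands for windows within a fixed Hamming distance of a
#' library repeat, chains matches whose gaps fall in the allowed spacer
#' length range, and reports arrays inheriting the matched entry's CRISPR
#' type.  Arrays matched on the minus strand are reported with repeat and
#' spacer sequences reverse-complemented and their order reversed, so that
#' spacer order follows the repeat orientation; \code{start} coordinates
#' stay on the forward strand of the contig.
#'
#' @inheritParams find_denovo_arrays
#' @param library data.frame with columns \code{id}, \code{seq} and
#'   optionally \code{crispr_type} (see [read_repeat_library()]).
#' @return list of \code{crispr_array} objects ordered by start coordinate.
#' @export
find_guided_arrays <- function(contig, library, params = detection_params(),
                               host_id = NULL) {
  rec <- as_sequence_record(contig)
  if (is.null(host_id)) host_id <- rec$id
  validate_repeat_library(library)
  if (is.null(library$crispr_type)) library$crispr_type <- NA_character_
  seq <- rec$seq; L <- rec$length

  cands <- list()
  for (e in seq_len(nrow(library))) {
    rseq <- toupper(library$seq[e])
    m <- nchar(rseq)
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") rseq else revcomp(rseq)
      mm <- mismatch_profile(seq, pat)
      hit <- which(mm <= params$max_repeat_mismatch)
      if (length(hit) < params$min_repeats) next
      # drop occurrences overlapping an already accepted one
      keep <- hit[1]
      for (p in hit[-1]) if (p >= keep[length(keep)] + m) keep <- c(keep, p)
      if (length(keep) < params$min_repeats) next
      # chain by spacer-length-compatible gaps
      runs <- list(); run <- keep[1]
      for (i in seq_len(length(keep) - 1L)) {
        g <- keep[i + 1L] - (keep[i] + m)
        if (g >= params$min_spacer_len && g <= params$max_spacer_len)
          run <- c(run, keep[i + 1L])
        else { runs[[length(runs) + 1L]] <- run; run <- keep[i + 1L] }
      }
      runs[[length(runs) + 1L]] <- run
      for (run in runs) {
        if (length(run) < params$min_repeats) next
        cands[[length(cands) + 1L]] <- list(
          pos = run, rep_len = m, entry = e, strand = strand,
          mismatches = sum(mm[run]),
          start = run[1], end = run[length(run)] + m - 1L)
      }
    }
  }
  cands <- resolve_overlaps(cands)

  out <- vector("list", length(cands))
  for (i in seq_along(cands)) {
    cc <- cands[[i]]
    rep_starts <- cc$pos
    rep_seqs <- substring(seq, rep_starts, rep_starts + cc$rep_len - 1L)
    sp_starts <- rep_starts[-length(rep_starts)] + cc$rep_len
    sp_seqs <- substring(seq, sp_starts, rep_starts[-1] - 1L)
    if (cc$strand == "-") {
      rep_seqs <- rev(revcomp(rep_seqs)); rep_starts <- rev(rep_starts)
      sp_seqs <- rev(revcomp(sp_seqs)); sp_starts <- rev(sp_starts)
    }
    out[[i]] <- new_crispr_array(
      array_id = paste0(rec$id, "_array", i), host_id = host_id,
      contig_id = rec$id, start = cc$start, end = cc$end,
      strand = cc$strand,
      repeats = data.frame(start = rep_starts, seq = rep_seqs,
                           stringsAsFactors = FALSE),
      spacers = data.frame(start = sp_starts, seq = sp_seqs,
                           stringsAsFactors = FALSE),
      consensus_repeat = toupper(library$seq[cc$entry]),
      crispr_type = library$crispr_type[cc$entry], mode = "guided")
  }
  out
}

#' Remove CRISPR-like artifacts such as tandem repeats
#'
#' Two similarity rules flag repetitive loci that mimic the repeat-spacer
#' structure: an array is removed when its spacers are too similar to each
#' other (mean pairwise identity above \code{spacer_sim_cutoff}) or too
#' similar to the consensus repeat (mean identity above
#' \code{repeat_spacer_sim_cutoff}).  Genuine spacers are near-random with
#' respect to one another, so both means sit far below the cutoffs.
#' Retained arrays are returned unchanged.
#'
#' @param arrays list of \code{crispr_array} objects.
#' @param params a [detection_params()] list.
#' @return the retained subset of \code{arrays}, order preserved.
#' @export
filter_artifacts <- function(arrays, params = detection_params()) {
  keep <- vapply(arrays, function(a) {
    sp <- a$spacers$seq
    if (length(sp) >= 2L) {
      pr <- utils::combn(length(sp), 2L)
      msp <- mean(vapply(seq_len(ncol(pr)), function(j)
        ungapped_identity(sp[pr[1, j]], sp[pr[2, j]]), numeric(1)))
      if (msp > params$spacer_sim_cutoff) return(FALSE)
    }
    mrs <- mean(vapply(sp, ungapped_identity, numeric(1),
                       b = a$consensus_repeat))
    mrs <= params$repeat_spacer_sim_cutoff
  }, logical(1))
  arrays[keep]
}

#' Extract spacers from detected arrays
#'
#' @param arrays list of \code{crispr_array} objects.
#' @return data.frame with one row per spacer: \code{spacer_id}, \code{seq},
#'   \code{host_id}, \code{array_id}, \code{contig_id},
#'   \code{index_in_array} (1 = first spacer in repeat orientation) and
#'   \code{crispr_type}.
#' @export
extract_spacers <- function(arrays) {
  if (length(arrays) == 0L)
    return(data.frame(spacer_id = character(0), seq = character(0),
                      host_id = character(0), array_id = character(0),
                      contig_id = character(0), index_in_array = integer(0),
                      crispr_type = character(0), stringsAsFactors = FALSE))
  do.call(rbind, lapply(arrays, function(a) {
    n <- nrow(a$spacers)
    data.frame(spacer_id = paste0(a$array_id, "_sp", seq_len(n)),
               seq = a$spacers$seq, host_id = a$host_id,
               array_id = a$array_id, contig_id = a$contig_id,
               index_in_array = seq_len(n), crispr_type = a$crispr_type,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Collapse spacers into 100% non-redundant sequence clusters
#'
#' Exact-duplicate collapse after uppercasing (\code{mode = "exact"}), or
#' additionally merging a sequence with its reverse complement
#' (\code{mode = "exact_rc"}; the representative is the lexicographically
#' smaller orientation).  Clusters partition the input and are returned in
#' deterministic order by representative sequence.
#'
#' @param spacers data.frame from [extract_spacers()].
#' @param mode \code{"exact"} (default) or \code{"exact_rc"}.
#' @return data.frame with columns \code{cluster_id}, \code{rep_seq},
#'   \code{n_members}, and list-columns \code{members} (spacer ids) and
#'   \code{crispr_types}.
#' @export
deduplicate_spacers <- function(spacers, mode = c("exact", "exact_rc")) {
  mode <- match.arg(mode)
  if (nrow(spacers) == 0L)
    return(data.frame(cluster_id = character(0), rep_seq = character(0),
                      n_members = integer(0),
                      members = I(list()), crispr_types = I(list()),
                      stringsAsFactors = FALSE))
  key <- toupper(spacers$seq)
  if (mode == "exact_rc") {
    rc <- revcomp(key)
    swap <- mapply(function(a, b) b < a, key, rc, USE.NAMES = FALSE)
    key[swap] <- rc[swap]
  }
  reps <- sort(unique(key), method = "radix")
  idx <- split(seq_len(nrow(spacers)), factor(key, levels = reps))
  data.frame(
    cluster_id = sprintf("SC%05d", seq_along(reps)),
    rep_seq = reps,
    n_members = lengths(idx),
    members = I(unname(lapply(idx, function(i) spacers$spacer_id[i]))),
    crispr_types = I(unname(lapply(idx, function(i) {
      t <- unique(spacers$crispr_type[i])
      t <- t[!is.na(t)]
      if (length(t)) sort(t, method = "radix") else character(0)
    }))),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Map each spacer occurrence to its cluster
#'
#' @param clusters data.frame from [deduplicate_spacers()].
#' @return data.frame with columns \code{spacer_id}, \code{cluster_id}.
#' @export
spacer_cluster_map <- function(clusters) {
  ids <- unlist(clusters$members, use.names = FALSE)
  data.frame(
    spacer_id = if (is.null(ids)) character(0) else ids,
    cluster_id = rep(clusters$cluster_id, clusters$n_members),
    stringsAsFactors = FALSE)
}

#' Write detected arrays as TSV
#'
#' One row per array with 1-based inclusive coordinates.
#' @param arrays list of \code{crispr_array} objects.
#' @param path output file.
#' @export
write_arrays_tsv <- function(arrays, path) {
  df <- if (length(arrays) == 0L)
    data.frame(array_id = character(0), host = character(0),
               contig = character(0), start = integer(0), end = integer(0),
               strand = character(0), n_repeats = integer(0),
               consensus_repeat = character(0), type = character(0),
               mode = character(0), stringsAsFactors = FALSE)
  else do.call(rbind, lapply(arrays, function(a)
    data.frame(array_id = a$array_id, host = a$host_id, contig = a$contig_id,
               start = a$start, end = a$end, strand = a$strand,
               n_repeats = nrow(a$repeats),
               consensus_repeat = a$consensus_repeat,
               type = ifelse(is.na(a$crispr_type), "untyped", a$crispr_type),
               mode = a$mode, stringsAsFactors = FALSE)))
  write_tsv(df, path)
}

#' Write arrays as GFF3-like features
#'
#' Emits one \code{CRISPR_array} feature per array plus child
#' \code{repeat_unit} and \code{spacer} features (1-based inclusive).
#' @inheritParams write_arrays_tsv
#' @export
write_arrays_gff <- function(arrays, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (a in arrays) {
    attr_a <- sprintf("ID=%s;n_repeats=%d;type=%s;mode=%s", a$array_id,
                      nrow(a$repeats),
                      ifelse(is.na(a$crispr_type), "untyped", a$crispr_type),
                      a$mode)
    writeLines(paste(a$contig_id, "crisprnet", "CRISPR_array", a$start,
                     a$end, ".", a$strand, ".", attr_a, sep = "\t"), con)
    for (i in seq_len(nrow(a$repeats)))
      writeLines(paste(a$contig_id, "crisprnet", "repeat_unit",
                       a$repeats$start[i],
                       a$repeats$start[i] + nchar(a$repeats$seq[i]) - 1L,
                       ".", a$strand, ".",
                       sprintf("ID=%s_rep%d;Parent=%s", a$array_id, i,
                               a$array_id), sep = "\t"), con)
    for (i in seq_len(nrow(a$spacers)))
      writeLines(paste(a$contig_id, "crisprnet", "spacer",
                       a$spacers$start[i],
                       a$spacers$start[i] + nchar(a$spacers$seq[i]) - 1L,
                       ".", a$strand, ".",
                       sprintf("ID=%s_sp%d;Parent=%s", a$array_id, i,
                               a$array_id), sep = "\t"), con)
  }
  invisible(path)
}

#' Write spacer occurrences as FASTA
#'
#' Headers carry the cluster id and occurrence metadata:
#' \code{<cluster_id>|host=<host>|array=<array>|idx=<i>|type=<label>}.
#'
#' @param spacers data.frame from [extract_spacers()].
#' @param clusters data.frame from [deduplicate_spacers()].
#' @param path output file.
#' @export
write_spacer_fasta <- function(spacers, clusters, path) {
  cm <- spacer_cluster_map(clusters)
  cl <- cm$cluster_id[match(spacers$spacer_id, cm$spacer_id)]
  hdr <- sprintf("%s|host=%s|array=%s|idx=%d|type=%s", cl, spacers$host_id,
                 spacers$array_id, spacers$index_in_array,
                 ifelse(is.na(spacers$crispr_type), "untyped",
                        spacers$crispr_type))
  seqs <- spacers$seq
  names(seqs) <- hdr
  write_fasta(seqs, path)
}

#' Read a spacer FASTA written by [write_spacer_fasta()]
#'
#' @param path FASTA file.
#' @return list with \code{spacers} (occurrence table including
#'   \code{cluster_id}) and \code{clusters} (as from
#'   [deduplicate_spacers()], reconstructed).
#' @export
read_spacer_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- names(ss)
  parts <- strsplit(hdr, "|", fixed = TRUE)
  bad <- which(lengths(parts) != 5L)
  if (length(bad))
    stop("malformed spacer header at record ", bad[1], call. = FALSE)
  field <- function(i, tag) {
    v <- vapply(parts, `[[`, character(1), i)
    sub(paste0("^", tag, "="), "", v)
  }
  typ <- field(5L, "type")
  spacers <- data.frame(
    spacer_id = paste0(field(3L, "array"), "_sp", field(4L, "idx")),
    seq = as.character(ss), host_id = field(2L, "host"),
    array_id = field(3L, "array"), contig_id = NA_character_,
    index_in_array = as.integer(field(4L, "idx")),
    crispr_type = ifelse(typ == "untyped", NA_character_, typ),
    cluster_id = vapply(parts, `[[`, character(1), 1L),
    stringsAsFactors = FALSE, row.names = NULL)
  ids <- sort(unique(spacers$cluster_id), method = "radix")
  idx <- split(seq_len(nrow(spacers)),
               factor(spacers$cluster_id, levels = ids))
  clusters <- data.frame(
    cluster_id = ids,
    rep_seq = vapply(idx, function(i) toupper(spacers$seq[i][1]),
                     character(1), USE.NAMES = FALSE),
    n_members = lengths(idx),
    members = I(unname(lapply(idx, function(i) spacers$spacer_id[i]))),
    crispr_types = I(unname(lapply(idx, function(i) {
      t <- unique(spacers$crispr_type[i]); t <- t[!is.na(t)]
      if (length(t)) sort(t, method = "radix") else character(0)
    }))),
    stringsAsFactors = FALSE, row.names = NULL)
  list(spacers = spacers, clusters = clusters)
}
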