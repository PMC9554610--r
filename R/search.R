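#' Parameters for the spacer-vs-MGE search and retention filters
#'
#' Retention thresholds follow the usual spacer-protospacer matching
#' practice: identity above 90%, query coverage per HSP above 80% and
#' e-value below 0.001, all strict inequalities.  The scoring scheme
#' (+1/-2, affine gaps -5/-2) favours short, near-exact matches.  The
#' default word size of 8 guarantees an exact seed exists for any 32-bp
#' spacer carrying up to 3 substitutions (the most a hit can carry and
#' still clear the identity filter); word sizes this small are standard
#' for short nucleotide queries.
#'
#' @param min_identity retained hits need identity strictly greater.
#' @param min_qcov retained hits need query coverage strictly greater.
#' @param max_evalue retained hits need e-value strictly smaller.
#' @param word_size exact seed length (bp).
#' @param match,mismatch,gap_open,gap_extend alignment scores.
#' @param karlin_k Karlin-Altschul K constant for e-value calibration.
#' @param db_length_total total database length (bp); if \code{NULL},
#'   computed as the sum of subject lengths at search time.
#' @param gapped if \code{TRUE}, candidate loci are refined by gapped local
#'   alignment (Smith-Waterman via \pkg{Biostrings}); by default hits are
#'   ungapped full-query-span alignments, which is the natural statistic
#'   for spacer matching (identity is measured over the whole spacer
#'   projection, so terminal mismatches count against it).
#' @return a list of class \code{"search_params"}.
#' @export
search_params <- function(min_identity = 0.90, min_qcov = 0.80,
                          max_evalue = 1e-3, word_size = 8L,
                          match = 1L, mismatch = -2L,
                          gap_open = -5L, gap_extend = -2L,
                          karlin_k = 0.46, db_length_total = NULL,
                          gapped = FALSE) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_qcov > 0, min_qcov <= 1, max_evalue > 0,
            word_size >= 4L, match > 0, mismatch < 0)
  structure(list(min_identity = min_identity, min_qcov = min_qcov,
                 max_evalue = max_evalue, word_size = as.integer(word_size),
                 match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, karlin_k = karlin_k,
                 db_length_total = db_length_total, gapped = isTRUE(gapped)),
            class = "search_params")
}

.lambda_cache <- new.env(parent = emptyenv())

#' Karlin-Altschul lambda for a match/mismatch scoring scheme
#'
#' The unique positive root of
#' \eqn{p\,e^{\lambda\,match} + (1-p)\,e^{\lambda\,mismatch} = 1}
#' under uniform base composition (\eqn{p = 1/4} is the chance that two
#' random bases match).
#'
#' @param match,mismatch scores (match positive, mismatch negative).
#' @param p_match probability two random letters match.
#' @return the positive root, solved numerically.
#' @export
karlin_lambda <- function(match = 1, mismatch = -2, p_match = 0.25) {
  key <- paste(match, mismatch, p_match, sep = ":")
  if (!is.null(.lambda_cache[[key]])) return(.lambda_cache[[key]])
  if (p_match * match + (1 - p_match) * mismatch >= 0)
    stop("expected score must be negative for lambda to exist",
         call. = FALSE)
  f <- function(l) p_match * exp(l * match) + (1 - p_match) *
    exp(l * mismatch) - 1
  upper <- log(1 / p_match) / match + 1
  lam <- stats::uniroot(f, c(1e-9, upper), tol = 1e-14)$root
  .lambda_cache[[key]] <- lam
  lam
}

#' Bit score and e-value from a raw alignment score
#'
#' Karlin-Altschul statistics: \code{bitscore = (lambda*S - ln K)/ln 2} and
#' \code{evalue = K*m*n*exp(-lambda*S)} with \code{m} the query length and
#' \code{n} the total database length.  Vectorised over \code{score_raw}.
#'
#' @param score_raw raw score(s) under the \code{params} scoring scheme.
#' @param query_len query length (bp).
#' @param db_len_total total database length (bp).
#' @param params a [search_params()] list (supplies scores and K).
#' @return data.frame with columns \code{bitscore}, \code{evalue}.
#' @export
compute_evalue <- function(score_raw, query_len, db_len_total,
                           params = search_params()) {
  if (query_len <= 0 || db_len_total <= 0)
    stop("query and database lengths must be positive", call. = FALSE)
  lam <- karlin_lambda(params$match, params$mismatch)
  k <- params$karlin_k
  data.frame(bitscore = (lam * score_raw - log(k)) / log(2),
             evalue = k * query_len * db_len_total * exp(-lam * score_raw))
}

#' Read an MGE database (FASTA plus metadata TSV)
#'
#' The metadata table needs columns \code{mge_id}, \code{mge_class}
#' (\code{phage} or \code{plasmid}), \code{source_db} and optionally
#' \code{known_host}.  Sequences without a metadata row are kept with class
#' \code{"unknown"} (with a warning).
#'
#' @param fasta MGE multi-FASTA.
#' @param metadata path to the metadata TSV, or \code{NULL}.
#' @return data.frame with columns \code{mge_id}, \code{seq},
#'   \code{mge_class}, \code{source_db}, \code{known_host}.
#' @export
read_mge_db <- function(fasta, metadata = NULL) {
  recs <- read_fasta_records(fasta)
  db <- data.frame(mge_id = vapply(recs, `[[`, character(1), "id"),
                   seq = vapply(recs, `[[`, character(1), "seq"),
                   mge_class = "unknown", source_db = "",
                   known_host = "", stringsAsFactors = FALSE,
                   row.names = NULL)
  if (!is.null(metadata)) {
    md <- utils::read.delim(metadata, stringsAsFactors = FALSE)
    if (!"mge_id" %in% names(md))
      stop("MGE metadata needs an 'mge_id' column", call. = FALSE)
    if ("class" %in% names(md) && !"mge_class" %in% names(md))
      names(md)[names(md) == "class"] <- "mge_class"
    i <- match(db$mge_id, md$mge_id)
    if (anyNA(i))
      warning("no metadata for MGE id(s): ",
              paste(db$mge_id[is.na(i)], collapse = ", "), call. = FALSE)
    for (col in intersect(c("mge_class", "source_db", "known_host"),
                          names(md)))
      db[[col]] <- ifelse(is.na(i), db[[col]], as.character(md[[col]][i]))
  }
  db
}

empty_hits <- function() {
  data.frame(cluster_id = character(0), mge_id = character(0),
             identity = numeric(0), aln_len = integer(0),
             mismatches = integer(0), gap_openings = integer(0),
             q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             evalue = numeric(0), bitscore = numeric(0),
             qcov = numeric(0), strand = character(0),
             score_raw = numeric(0), stringsAsFactors = FALSE)
}

count_matches <- function(a, b) sum(charToRaw(a) == charToRaw(b))

## candidate ungapped alignment of query `qq` projected onto subject at
## start offset `a` (may hang off either subject end)
span_alignment <- function(qq, subject, slen, a, qlen) {
  s_from <- max(a, 1L)
  s_to <- min(a + qlen - 1L, slen)
  q_from <- s_from - a + 1L
  q_to <- s_to - a + 1L
  span <- s_to - s_from + 1L
  m <- count_matches(substr(qq, q_from, q_to), substr(subject, s_from, s_to))
  list(s_from = s_from, s_to = s_to, q_from = q_from, q_to = q_to,
       span = span, matches = m)
}

gapped_refine <- function(qq, subject, slen, s_lo, s_hi, params) {
  w_from <- max(1L, s_lo - 15L)
  w_to <- min(slen, s_hi + 15L)
  sm <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match, mismatch = params$mismatch, baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    qq, substr(subject, w_from, w_to), type = "local",
    substitutionMatrix = sm, gapOpening = abs(params$gap_open),
    gapExtension = abs(params$gap_extend))
  qr <- pa@pattern@range
  sr <- pa@subject@range
  aln <- nchar(as.character(Biostrings::alignedPattern(pa)))
  list(score = Biostrings::score(pa),
       matches = Biostrings::nmatch(pa),
       mismatches = Biostrings::nmismatch(pa),
       gap_openings = sum(Biostrings::nindel(pa)@insertion[, 1],
                          Biostrings::nindel(pa)@deletion[, 1]),
       aln_len = aln,
       q_from = qr@start, q_to = qr@start + qr@width - 1L,
       s_from = w_from + sr@start - 1L,
       s_to = w_from + sr@start + sr@width - 2L)
}

#' Search spacer clusters against an MGE database
#'
#' Seeds with exact shared words of \code{word_size} bp on both strands,
#' evaluates the full-query-span ungapped alignment at every seeded
#' diagonal, merges overlapping candidates per (cluster, MGE, strand)
#' keeping the best-scoring locus, and attaches Karlin-Altschul bit scores
#' and e-values.  Results are unfiltered; apply [filter_hits()] for the
#' retention thresholds.  With \code{params$gapped = TRUE} each merged
#' locus is refined by gapped local alignment instead.
#'
#' Coordinates are 1-based; on the minus strand \code{s_start > s_end},
#' following the tabular alignment convention.
#'
#' @param clusters data.frame from [deduplicate_spacers()] (columns
#'   \code{cluster_id}, \code{rep_seq}).
#' @param db data.frame from [read_mge_db()] (columns \code{mge_id},
#'   \code{seq}).
#' @param params a [search_params()] list.
#' @return data.frame of hits (one row per locus), ordered by cluster,
#'   MGE, strand and subject position.
#' @export
search_spacers <- function(clusters, db, params = search_params()) {
  if (nrow(clusters) == 0L) stop("no spacer clusters to search", call. = FALSE)
  if (nrow(db) == 0L) stop("empty MGE database", call. = FALSE)
  k <- params$word_size
  n_total <- params$db_length_total
  if (is.null(n_total)) n_total <- sum(nchar(db$seq))

  short <- nchar(clusters$rep_seq) < k
  if (any(short)) {
    warning("skipping ", sum(short), " spacer cluster(s) shorter than the ",
            "word size (", k, " bp): ",
            paste(clusters$cluster_id[short], collapse = ", "),
            call. = FALSE)
    clusters <- clusters[!short, , drop = FALSE]
  }
  if (nrow(clusters) == 0L) return(empty_hits())

  # per-subject exact word index
  index_subject <- function(s) {
    L <- nchar(s)
    if (L < k) return(NULL)
    st <- seq_len(L - k + 1L)
    km <- substring(s, st, st + k - 1L)
    ok <- !grepl("N", km, fixed = TRUE)
    e <- new.env(parent = emptyenv(), size = length(st))
    if (any(ok)) {
      sp <- split(st[ok], km[ok])
      for (nm in names(sp)) assign(nm, sp[[nm]], envir = e)
    }
    e
  }
  idx <- lapply(db$seq, index_subject)

  rows <- vector("list", 256L); nr <- 0L
  push <- function(r) {
    nr <<- nr + 1L
    if (nr > length(rows)) length(rows) <<- 2L * nr
    rows[[nr]] <<- r
  }

  for (ci in seq_len(nrow(clusters))) {
    q <- toupper(clusters$rep_seq[ci])
    qlen <- nchar(q)
    q_or <- c("+" = q, "-" = revcomp(q))
    for (mi in seq_len(nrow(db))) {
      if (is.null(idx[[mi]])) next
      subject <- db$seq[mi]
      slen <- nchar(subject)
      for (strand in c("+", "-")) {
        qq <- q_or[[strand]]
        qst <- seq_len(qlen - k + 1L)
        qkm <- substring(qq, qst, qst + k - 1L)
        hit_pos <- mget(qkm, envir = idx[[mi]], ifnotfound = list(NULL))
        a_all <- integer(0)
        for (j in seq_along(hit_pos)) {
          sp <- hit_pos[[j]]
          if (!is.null(sp)) a_all <- c(a_all, sp - qst[j] + 1L)
        }
        if (!length(a_all)) next
        a_all <- sort(unique(a_all))
        cand <- lapply(a_all, function(a)
          span_alignment(qq, subject, slen, a, qlen))
        score <- vapply(cand, function(cc)
          cc$matches * params$match +
            (cc$span - cc$matches) * params$mismatch, numeric(1))
        # in gapped mode the local aligner judges each locus; ungapped
        # candidates with non-positive score are unreportable
        keep <- if (params$gapped) rep(TRUE, length(score)) else score > 0
        if (!any(keep)) next
        cand <- cand[keep]; score <- score[keep]
        # merge candidates whose subject spans overlap: keep best score,
        # ties to the leftmost subject start
        s_lo <- vapply(cand, `[[`, integer(1), "s_from")
        s_hi <- vapply(cand, `[[`, integer(1), "s_to")
        grp <- integer(length(cand)); g <- 0L; last_hi <- -1L
        for (j in order(s_lo, s_hi)) {
          if (s_lo[j] > last_hi) g <- g + 1L
          grp[j] <- g
          last_hi <- max(last_hi, s_hi[j])
        }
        for (gi in seq_len(g)) {
          in_g <- which(grp == gi)
          best <- in_g[order(-score[in_g], s_lo[in_g])][1]
          cc <- cand[[best]]; sc <- score[best]
          if (params$gapped) {
            ref <- gapped_refine(qq, subject, slen, min(s_lo[in_g]),
                                 max(s_hi[in_g]), params)
            if (ref$score <= 0) next
            cc <- list(s_from = ref$s_from, s_to = ref$s_to,
                       q_from = ref$q_from, q_to = ref$q_to,
                       span = ref$aln_len, matches = ref$matches)
            sc <- ref$score
            gaps <- ref$gap_openings
            mism <- ref$mismatches
          } else {
            gaps <- 0L
            mism <- cc$span - cc$matches
          }
          ke <- compute_evalue(sc, qlen, n_total, params)
          if (strand == "+") {
            qs <- cc$q_from; qe <- cc$q_to
            ss <- cc$s_from; se <- cc$s_to
          } else {
            qs <- qlen - cc$q_to + 1L; qe <- qlen - cc$q_from + 1L
            ss <- cc$s_to; se <- cc$s_from
          }
          push(data.frame(
            cluster_id = clusters$cluster_id[ci], mge_id = db$mge_id[mi],
            identity = cc$matches / cc$span, aln_len = cc$span,
            mismatches = mism, gap_openings = gaps,
            q_start = qs, q_end = qe, s_start = ss, s_end = se,
            evalue = ke$evalue, bitscore = ke$bitscore,
            qcov = (qe - qs + 1L) / qlen, strand = strand,
            score_raw = sc, stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (nr == 0L) return(empty_hits())
  hits <- do.call(rbind, rows[seq_len(nr)])
  hits <- hits[order(hits$cluster_id, hits$mge_id, hits$strand,
                     pmin(hits$s_start, hits$s_end), method = "radix"), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Apply the retention filters to spacer hits
#'
#' A hit is kept iff identity is strictly greater than
#' \code{params$min_identity}, query coverage strictly greater than
#' \code{params$min_qcov} and e-value strictly less than
#' \code{params$max_evalue}.  Input order is preserved.
#'
#' @param hits data.frame from [search_spacers()] or [read_tabular_hits()].
#' @param params a [search_params()] list.
#' @return the retained subset of \code{hits}.
#' @export
filter_hits <- function(hits, params = search_params()) {
  if (nrow(hits) == 0L) return(hits)
  keep <- hits$identity > params$min_identity &
    hits$qcov > params$min_qcov &
    hits$evalue < params$max_evalue
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read externally produced hits in 12-column tabular format
#'
#' Columns: query, subject, \%identity, alignment length, mismatches, gap
#' openings, q_start, q_end, s_start, s_end, e-value, bit score.  Query
#' coverage is recomputed from the query span and the spacer length, the
#' strand inferred from the subject coordinates.  Files written by
#' [write_hits_tsv()] (12 columns plus appended \code{qcov} and
#' \code{strand}) are accepted too; the appended columns are recomputed.
#'
#' @param path tabular hits file (lines starting with \code{#} ignored).
#' @param spacer_lengths named vector mapping query (cluster) ids to spacer
#'   lengths in bp.
#' @return hits data.frame as from [search_spacers()] (\code{score_raw}
#'   is \code{NA} for ingested hits).
#' @export
read_tabular_hits <- function(path, spacer_lengths) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) return(empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != 12L & nf != 14L)
  if (length(bad))
    stop("malformed tabular hits line ", lineno[bad[1]], ": expected 12 ",
         "columns, found ", nf[bad[1]], call. = FALSE)
  m <- do.call(rbind, lapply(parts, `[`, 1:12))
  qid <- m[, 1]
  unknown <- setdiff(unique(qid), names(spacer_lengths))
  if (length(unknown))
    stop("unknown query id(s) in tabular hits (no spacer length): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  num <- function(j) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v))
      stop("malformed tabular hits line ", lineno[which(is.na(v))[1]],
           ": non-numeric field ", j, call. = FALSE)
    v
  }
  qlen <- as.numeric(spacer_lengths[qid])
  qs <- num(7); qe <- num(8); ss <- num(9); se <- num(10)
  hits <- data.frame(
    cluster_id = qid, mge_id = m[, 2], identity = num(3) / 100,
    aln_len = as.integer(num(4)), mismatches = as.integer(num(5)),
    gap_openings = as.integer(num(6)),
    q_start = as.integer(qs), q_end = as.integer(qe),
    s_start = as.integer(ss), s_end = as.integer(se),
    evalue = num(11), bitscore = num(12),
    qcov = (qe - qs + 1) / qlen,
    strand = ifelse(ss <= se, "+", "-"),
    score_raw = NA_real_, stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  hits
}

#' Write hits in the 12-column tabular layout plus qcov and strand
#'
#' @param hits hits data.frame.
#' @param path output file.
#' @export
write_hits_tsv <- function(hits, path) {
  lines <- if (nrow(hits) == 0L) character(0) else
    paste(hits$cluster_id, hits$mge_id,
          sprintf("%.2f", hits$identity * 100), hits$aln_len,
          hits$mismatches, hits$gap_openings, hits$q_start, hits$q_end,
          hits$s_start, hits$s_end, sprintf("%.3g", hits$evalue),
          sprintf("%.1f", hits$bitscore), sprintf("%.4f", hits$qcov),
          hits$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
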