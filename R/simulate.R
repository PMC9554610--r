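#' Built-in synthetic CRISPR repeat library
#'
#' Three fixed, arbitrarily composed repeat sequences (synthetic, not taken
#' from any organism) labelled with CRISPR type tags, used as the default
#' repeat choices of the simulator and as a guided-detection library for
#' simulated data.
#'
#' @return data.frame with columns \code{id}, \code{seq}, \code{crispr_type}.
#' @export
default_repeat_library <- function() {
  data.frame(
    id = c("synrep_IC", "synrep_IIC", "synrep_VA"),
    seq = c("GTCACACCCGTGTAGATGGTCCGAAAGGACT",
            "ATTTCAGACGGCATACTTCGGTATGCCTTGTGAGTT",
            "GTTTGAGAGTCCCTTGAGGATTCAAGGGACTAAC"),
    crispr_type = c("I-C", "II-C", "V-A"),
    stringsAsFactors = FALSE)
}

#' Mutate a sequence by independent base substitutions
#'
#' Each base is substituted with probability \code{rate} to a different,
#' uniformly chosen base; length is preserved.  Uses the current RNG
#' state.
#'
#' @param seq DNA string.
#' @param rate per-base substitution probability in \[0, 1\].
#' @return list with \code{seq} (mutated sequence) and
#'   \code{n_substitutions}.
#' @export
mutate_sequence <- function(seq, rate) {
  stopifnot(is.numeric(rate), rate >= 0, rate <= 1)
  n <- nchar(seq)
  if (n == 0L || rate == 0) return(list(seq = seq, n_substitutions = 0L))
  hit <- which(stats::runif(n) < rate)
  if (!length(hit)) return(list(seq = seq, n_substitutions = 0L))
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    alt <- bases[bases != ch[i]]
    ch[i] <- alt[sample.int(3L, 1L)]
  }
  list(seq = paste(ch, collapse = ""), n_substitutions = length(hit))
}

#' Substitute exactly n positions of a sequence
#'
#' Picks \code{n} distinct positions uniformly and substitutes each to a
#' different base; useful for constructing fixtures that sit exactly at an
#' identity-filter boundary.
#'
#' @param seq DNA string.
#' @param n number of substitutions (at most \code{nchar(seq)}).
#' @return the mutated sequence.
#' @export
substitute_n <- function(seq, n) {
  stopifnot(n >= 0, n <= nchar(seq))
  if (n == 0L) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (i in sample.int(length(ch), n)) {
    alt <- bases[bases != ch[i]]
    ch[i] <- alt[sample.int(3L, 1L)]
  }
  paste(ch, collapse = "")
}

#' Plant a CRISPR array in a random contig
#'
#' Builds \code{flank + R (S R)^n + flank} from a repeat sequence and a
#' list of spacers, using the current RNG state for the flanks.  With
#' \code{identifiable = TRUE} the two flank bases adjoining the array are
#' adjusted (if needed) so that the repeat/spacer boundary columns are
#' polymorphic across units; a repeat-based detector can then recover the
#' planted boundaries exactly rather than up to the inherent ambiguity of
#' boundary columns shared by every unit.
#'
#' @param repeat_seq the repeat unit.
#' @param spacers character vector of spacer sequences.
#' @param flank_len length of each random flank (bp).
#' @param identifiable adjust flank boundary bases for exact recovery.
#' @return list with \code{seq}, \code{start}, \code{end} (1-based
#'   inclusive array coordinates) and \code{spacer_starts}.
#' @export
plant_crispr_contig <- function(repeat_seq, spacers, flank_len = 300L,
                                identifiable = FALSE) {
  n_sp <- length(spacers)
  stopifnot(n_sp >= 1L)
  left <- random_dna(1, flank_len)
  right <- random_dna(1, flank_len)
  if (identifiable) {
    bases <- c("A", "C", "G", "T")
    # right boundary column: first bases of all spacers + first right-flank
    firsts <- substr(spacers, 1L, 1L)
    if (length(unique(firsts)) == 1L && substr(right, 1, 1) == firsts[1])
      substr(right, 1, 1) <- bases[bases != firsts[1]][1]
    # left boundary column: last bases of all spacers + last left-flank
    lasts <- substr(spacers, nchar(spacers), nchar(spacers))
    if (length(unique(lasts)) == 1L &&
        substr(left, flank_len, flank_len) == lasts[1])
      substr(left, flank_len, flank_len) <- bases[bases != lasts[1]][1]
  }
  array_seq <- paste0(repeat_seq,
                      paste0(spacers, repeat_seq, collapse = ""))
  rl <- nchar(repeat_seq)
  sp_starts <- flank_len + 1L + rl +
    cumsum(c(0L, (nchar(spacers) + rl)[-n_sp]))
  list(seq = paste0(left, array_seq, right),
       start = flank_len + 1L,
       end = flank_len + nchar(array_seq),
       spacer_starts = sp_starts)
}

#' Configuration for the synthetic host/MGE simulator
#'
#' Defaults emulate a small pangenome-scale study: 20 hosts each carrying
#' one CRISPR array of 3-8 spacers of 32 bp, a database of 50 genuine MGEs
#' of 2-4 kb plus 10 decoy MGEs, exact (unmutated) protospacer copies, and
#' a 10% admixture of decoy spacers matching nothing.
#'
#' @param n_hosts number of host genomes.
#' @param n_mges number of genuine MGE sequences.
#' @param n_decoy_mges number of decoy MGEs (never sampled for spacers).
#' @param mge_len_range MGE length range (bp).
#' @param arrays_per_host CRISPR arrays per host contig.
#' @param spacers_per_array_range spacer-count range per array.
#' @param spacer_len spacer length (bp).
#' @param repeat_library data.frame of repeat choices with type labels.
#' @param sub_rate per-base substitution rate applied to implanted
#'   protospacer copies.
#' @param decoy_spacer_frac fraction of spacers that are random decoys.
#' @param plasmid_frac fraction of MGEs labelled plasmid (rest phage).
#' @param flank_len random flank length around and between arrays (bp);
#'   arrays on one contig are separated by at least \code{2*flank_len}.
#' @param seed RNG seed; all randomness derives from it.
#' @return a validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_hosts = 20L, n_mges = 50L, n_decoy_mges = 10L,
                       mge_len_range = c(2000L, 4000L),
                       arrays_per_host = 1L,
                       spacers_per_array_range = c(3L, 8L),
                       spacer_len = 32L,
                       repeat_library = default_repeat_library(),
                       sub_rate = 0, decoy_spacer_frac = 0.1,
                       plasmid_frac = 0.15, flank_len = 400L, seed = 1L) {
  stopifnot(n_hosts >= 0, n_mges >= 0, n_decoy_mges >= 0,
            arrays_per_host >= 0, spacer_len >= 16L,
            length(mge_len_range) == 2L,
            mge_len_range[1] <= mge_len_range[2],
            length(spacers_per_array_range) == 2L,
            spacers_per_array_range[1] >= 1L,
            spacers_per_array_range[1] <= spacers_per_array_range[2],
            sub_rate >= 0, sub_rate <= 1,
            decoy_spacer_frac >= 0, decoy_spacer_frac <= 1,
            plasmid_frac >= 0, plasmid_frac <= 1, flank_len >= 100L)
  validate_repeat_library(repeat_library)
  if (spacer_len > mge_len_range[1])
    stop("spacer_len exceeds the minimum MGE length", call. = FALSE)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate hosts with CRISPR arrays tracing a synthetic MGE database
#'
#' Generates i.i.d. uniform MGE sequences, then host contigs whose CRISPR
#' arrays alternate a library repeat with spacers; each non-decoy spacer
#' is a \code{spacer_len} segment sampled uniformly from a random genuine
#' MGE (either strand) and mutated at the configured substitution rate.
#' Decoy MGEs are never sampled and decoy spacers are uniform random DNA,
#' giving analyzable false-positive behaviour.  Fully reproducible from
#' \code{config$seed}.
#'
#' @param config a [sim_config()] object.
#' @param outdir if non-\code{NULL}, writes \code{hosts.fasta},
#'   \code{mges.fasta}, \code{mge_metadata.tsv}, \code{repeats.fasta} and
#'   \code{ground_truth.tsv} there (directory is created).
#' @return (invisibly when writing) a list with \code{hosts} (named
#'   contig sequences), \code{mges} (MGE database data.frame),
#'   \code{repeats} (the library), \code{truth} (ground-truth table; decoy
#'   spacers have \code{mge_id = NA}) and \code{paths} (when written).
#' @export
## sample one value from an integer range, robust to degenerate ranges
## (sample(4:4, 1) would otherwise draw from 1:4)
sample_range <- function(lo, hi, n = 1L) {
  v <- lo:hi
  if (length(v) == 1L) rep(v, n) else sample(v, n, replace = TRUE)
}

simulate_dataset <- function(config = sim_config(), outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed, .rng_kind = "Mersenne-Twister",
                    .rng_normal_kind = "Inversion",
                    .rng_sample_kind = "Rejection")
  lib <- config$repeat_library

  n_all <- config$n_mges + config$n_decoy_mges
  mge_ids <- c(sprintf("mge_%03d", seq_len(config$n_mges)),
               if (config$n_decoy_mges > 0)
                 sprintf("decoymge_%03d", seq_len(config$n_decoy_mges)))
  mge_len <- sample_range(config$mge_len_range[1], config$mge_len_range[2],
                          n_all)
  mges <- data.frame(
    mge_id = mge_ids,
    seq = random_dna(n_all, mge_len),
    mge_class = ifelse(stats::runif(n_all) < config$plasmid_frac,
                       "plasmid", "phage"),
    source_db = "sim",
    known_host = "",
    stringsAsFactors = FALSE)

  hosts <- character(config$n_hosts)
  names(hosts) <- sprintf("host_%03d", seq_len(config$n_hosts))
  truth <- vector("list", 0L)
  for (h in seq_len(config$n_hosts)) {
    host_id <- names(hosts)[h]
    pieces <- random_dna(1, config$flank_len)
    for (ai in seq_len(config$arrays_per_host)) {
      array_id <- sprintf("%s_arr%d", host_id, ai)
      re <- lib[sample.int(nrow(lib), 1L), ]
      n_sp <- sample_range(config$spacers_per_array_range[1],
                           config$spacers_per_array_range[2])
      sp_seqs <- character(n_sp)
      for (si in seq_len(n_sp)) {
        if (stats::runif(1) < config$decoy_spacer_frac) {
          sp <- random_dna(1, config$spacer_len)
          truth[[length(truth) + 1L]] <- data.frame(
            host_id = host_id, array_id = array_id, spacer_index = si,
            mge_id = NA_character_, rep_seq = sp, s_start = NA_integer_,
            s_end = NA_integer_, strand = NA_character_,
            n_substitutions = NA_integer_, decoy = TRUE,
            crispr_type = re$crispr_type, stringsAsFactors = FALSE)
        } else {
          mi <- sample.int(config$n_mges, 1L)
          pos <- sample.int(nchar(mges$seq[mi]) - config$spacer_len + 1L,
                            1L)
          proto <- substr(mges$seq[mi], pos, pos + config$spacer_len - 1L)
          strand <- if (stats::runif(1) < 0.5) "+" else "-"
          sp0 <- if (strand == "+") proto else revcomp(proto)
          mut <- mutate_sequence(sp0, config$sub_rate)
          sp <- mut$seq
          truth[[length(truth) + 1L]] <- data.frame(
            host_id = host_id, array_id = array_id, spacer_index = si,
            mge_id = mges$mge_id[mi], rep_seq = sp, s_start = pos,
            s_end = pos + config$spacer_len - 1L, strand = strand,
            n_substitutions = mut$n_substitutions, decoy = FALSE,
            crispr_type = re$crispr_type, stringsAsFactors = FALSE)
        }
        sp_seqs[si] <- sp
      }
      array_seq <- paste0(re$seq, paste0(sp_seqs, re$seq, collapse = ""))
      pieces <- paste0(pieces, array_seq, random_dna(1, config$flank_len))
    }
    hosts[h] <- pieces
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(host_id = character(0), array_id = character(0),
               spacer_index = integer(0), mge_id = character(0),
               rep_seq = character(0), s_start = integer(0),
               s_end = integer(0), strand = character(0),
               n_substitutions = integer(0), decoy = logical(0),
               crispr_type = character(0), stringsAsFactors = FALSE)

  out <- list(hosts = hosts, mges = mges, repeats = lib, truth = truth,
              config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      hosts = file.path(outdir, "hosts.fasta"),
      mges = file.path(outdir, "mges.fasta"),
      mge_metadata = file.path(outdir, "mge_metadata.tsv"),
      repeats = file.path(outdir, "repeats.fasta"),
      truth = file.path(outdir, "ground_truth.tsv"))
    write_fasta(hosts, paths$hosts)
    mseqs <- mges$seq; names(mseqs) <- mges$mge_id
    write_fasta(mseqs, paths$mges)
    write_tsv(mges[, c("mge_id", "mge_class", "source_db", "known_host")],
              paths$mge_metadata)
    rseqs <- lib$seq
    names(rseqs) <- sprintf("%s type=%s", lib$id, lib$crispr_type)
    write_fasta(rseqs, paths$repeats)
    write_tsv(truth, paths$truth)
    out$paths <- paths
    return(invisible(out))
  }
  out
}
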