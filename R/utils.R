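#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences over \code{A,C,G,T,N}.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA sequences
#'
#' Draws i.i.d. uniform bases using the current RNG state.
#'
#' @param n number of sequences.
#' @param len length in bp (recycled to length \code{n}).
#' @return character vector of \code{n} sequences.
#' @export
random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(len, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

## ungapped identity between two sequences: positions compared over the
## shorter length, denominator the longer length (length difference counts
## as mismatch)
ungapped_identity <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  if (la == 0L || lb == 0L) return(0)
  m <- min(la, lb)
  xa <- strsplit(substr(a, 1L, m), "", fixed = TRUE)[[1]]
  xb <- strsplit(substr(b, 1L, m), "", fixed = TRUE)[[1]]
  sum(xa == xb) / max(la, lb)
}

check_dna <- function(seq, what = "sequence") {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop(what, " is empty or missing", call. = FALSE)
  if (grepl("[^ACGTNacgtn]", seq))
    stop(what, " contains characters outside {A,C,G,T,N}", call. = FALSE)
  toupper(seq)
}

#' Construct a sequence record
#'
#' Minimal container for one input contig or genome sequence.
#'
#' @param id non-empty identifier.
#' @param seq DNA string over \code{A,C,G,T,N}.
#' @param description optional free-text description.
#' @return a list with class \code{"sequence_record"}.
#' @export
sequence_record <- function(id, seq, description = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("id must be a non-empty string", call. = FALSE)
  seq <- check_dna(seq, paste0("sequence '", id, "'"))
  structure(list(id = id, description = description, seq = seq,
                 length = nchar(seq)),
            class = "sequence_record")
}

## accept a sequence_record, or a single (optionally named) string
as_sequence_record <- function(x, default_id = "seq1") {
  if (inherits(x, "sequence_record")) return(x)
  if (is.character(x) && length(x) == 1L) {
    id <- if (!is.null(names(x)) && nzchar(names(x))) names(x) else default_id
    return(sequence_record(id, unname(x)))
  }
  stop("expected a sequence_record or a single character string", call. = FALSE)
}

#' Read a (multi-)FASTA file into sequence records
#'
#' @param path FASTA file.
#' @return list of [sequence_record()] objects; ids are the header tokens up
#'   to the first whitespace, descriptions the remainder.
#' @export
read_fasta_records <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path, call. = FALSE)
  out <- vector("list", length(ss))
  for (i in seq_along(ss))
    out[[i]] <- sequence_record(ids[i], as.character(ss[[i]]), desc[i])
  names(out) <- ids
  out
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector of sequences (names become headers).
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(unname(as.character(seqs)))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
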