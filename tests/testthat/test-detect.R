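test_that("a constructed repeat-spacer contig yields exactly one array with the planted spacers", {
  set.seed(101)
  R <- random_dna(1, 30)
  S <- random_dna(3, 35)
  ct <- plant_crispr_contig(R, S, flank_len = 300, identifiable = TRUE)
  arrays <- find_denovo_arrays(c(contigA = ct$seq))
  expect_length(arrays, 1)
  a <- arrays[[1]]
  expect_equal(nrow(a$repeats), 4)
  expect_equal(a$spacers$seq, S)
  expect_equal(a$start, ct$start)
  expect_equal(a$end, ct$end)
  expect_true(all(a$repeats$seq == R))
  expect_equal(a$consensus_repeat, R)
})

test_that("random sequence contains no de novo arrays (checked over 20 seeds)", {
  for (s in 1:20) {
    set.seed(1000 + s)
    expect_length(find_denovo_arrays(c(rnd = random_dna(1, 10000))), 0)
  }
})

test_that("two planted arrays separated by >= 500 bp are both recovered with correct boundaries", {
  set.seed(103)
  R1 <- random_dna(1, 28); S1 <- random_dna(4, 40)
  R2 <- random_dna(1, 33); S2 <- random_dna(3, 30)
  c1 <- plant_crispr_contig(R1, S1, flank_len = 300, identifiable = TRUE)
  c2 <- plant_crispr_contig(R2, S2, flank_len = 300, identifiable = TRUE)
  contig <- paste0(c1$seq, c2$seq)  # >= 600 bp of flank between arrays
  arrays <- find_denovo_arrays(c(two = contig))
  expect_length(arrays, 2)
  expect_equal(arrays[[1]]$start, c1$start)
  expect_equal(arrays[[1]]$end, c1$end)
  expect_equal(arrays[[2]]$start, nchar(c1$seq) + c2$start)
  expect_equal(arrays[[2]]$end, nchar(c1$seq) + c2$end)
  expect_equal(arrays[[1]]$spacers$seq, S1)
  expect_equal(arrays[[2]]$spacers$seq, S2)
})

test_that("de novo detection rejects empty or invalid input", {
  expect_error(find_denovo_arrays(c(x = "")), "empty")
  expect_error(find_denovo_arrays(c(x = "ACGTXQ")), "outside")
  expect_error(find_denovo_arrays(c(x = random_dna(1, 30))), "too short")
})

test_that("reported repeats and spacers round-trip to contig substrings at reported coordinates", {
  for (s in 1:10) {
    set.seed(2000 + s)
    R <- random_dna(1, sample(23:40, 1))
    S <- random_dna(sample(3:7, 1), sample(20:50, 1))
    ct <- plant_crispr_contig(R, S, flank_len = 300)
    for (a in find_denovo_arrays(c(ctg = ct$seq))) {
      for (i in seq_len(nrow(a$repeats)))
        expect_identical(a$repeats$seq[i],
                         substr(ct$seq, a$repeats$start[i],
                                a$repeats$start[i] +
                                  nchar(a$repeats$seq[i]) - 1))
      for (i in seq_len(nrow(a$spacers)))
        expect_identical(a$spacers$seq[i],
                         substr(ct$seq, a$spacers$start[i],
                                a$spacers$start[i] +
                                  nchar(a$spacers$seq[i]) - 1))
    }
  }
})

test_that("guided detection matches library repeats and inherits the CRISPR type", {
  set.seed(104)
  lib <- default_repeat_library()
  S <- random_dna(3, 35)
  ct <- plant_crispr_contig(lib$seq[lib$crispr_type == "II-C"], S)
  arrays <- find_guided_arrays(c(g1 = ct$seq), lib)
  expect_length(arrays, 1)
  expect_equal(arrays[[1]]$crispr_type, "II-C")
  expect_equal(arrays[[1]]$spacers$seq, S)
  expect_equal(arrays[[1]]$strand, "+")
  # an unrelated library finds nothing
  other <- data.frame(id = "r1", seq = random_dna(1, 30),
                      crispr_type = "I-B", stringsAsFactors = FALSE)
  expect_length(find_guided_arrays(c(g1 = ct$seq), other), 0)
})

test_that("guided detection tolerates repeat variants within the mismatch budget", {
  set.seed(105)
  lib <- default_repeat_library()[2, ]
  S <- random_dna(4, 35)
  # plant with one unit carrying 2 substitutions
  units <- rep(lib$seq, 5)
  units[3] <- substitute_n(units[3], 2)
  contig <- paste0(random_dna(1, 200),
                   paste0(units[1:4], S, collapse = ""), units[5],
                   random_dna(1, 200))
  arrays <- find_guided_arrays(c(gm = contig), lib)
  expect_length(arrays, 1)
  expect_equal(nrow(arrays[[1]]$repeats), 5)
  expect_equal(arrays[[1]]$spacers$seq, S)
})

test_that("guided arrays on the minus strand are orientation-normalized with mapped coordinates", {
  set.seed(106)
  lib <- default_repeat_library()
  S <- random_dna(3, 35)
  ct <- plant_crispr_contig(lib$seq[1], S)
  fwd <- find_guided_arrays(c(ctg = ct$seq), lib)
  rev <- find_guided_arrays(c(ctg = revcomp(ct$seq)), lib)
  expect_length(rev, 1)
  expect_equal(rev[[1]]$strand, "-")
  # oriented spacers follow the repeat orientation: identical to forward
  expect_equal(rev[[1]]$spacers$seq, fwd[[1]]$spacers$seq)
  # coordinates map: start' = L - end + 1
  L <- nchar(ct$seq)
  expect_equal(rev[[1]]$start, L - fwd[[1]]$end + 1)
  expect_equal(rev[[1]]$end, L - fwd[[1]]$start + 1)
  # reported sequences are reverse complements of contig substrings
  a <- rev[[1]]
  ctg <- revcomp(ct$seq)
  for (i in seq_len(nrow(a$spacers)))
    expect_identical(a$spacers$seq[i],
                     revcomp(substr(ctg, a$spacers$start[i],
                                    a$spacers$start[i] +
                                      nchar(a$spacers$seq[i]) - 1)))
})

test_that("guided detection validates its repeat library", {
  ct <- c(x = random_dna(1, 500))
  short <- data.frame(id = "r", seq = "ACGTACGTACGT",
                      crispr_type = NA, stringsAsFactors = FALSE)
  expect_error(find_guided_arrays(ct, short), "16 bp")
  expect_error(find_guided_arrays(ct, data.frame()), "non-empty")
})

test_that("artifact filtering removes tandem-repeat mimics and keeps genuine arrays", {
  set.seed(107)
  R <- random_dna(1, 30)
  s <- random_dna(1, 35)
  tandem <- plant_crispr_contig(R, rep(s, 3))       # identical "spacers"
  genuine <- plant_crispr_contig(R, random_dna(3, 35))
  a_t <- find_denovo_arrays(c(t1 = tandem$seq))
  a_g <- find_denovo_arrays(c(g1 = genuine$seq))
  # the tandem mimic may or may not be called; if called, it is filtered
  expect_length(filter_artifacts(a_t), 0)
  kept <- filter_artifacts(a_g)
  expect_length(kept, 1)
  expect_identical(kept[[1]], a_g[[1]])  # retained arrays unchanged
  expect_length(filter_artifacts(list()), 0)
})

test_that("random spacers have mean pairwise identity near 1/4, far below the filter cutoff", {
  set.seed(108)
  sp <- random_dna(30, 35)
  pairs <- combn(30, 2)
  ids <- vapply(seq_len(ncol(pairs)), function(j)
    crisprnet:::ungapped_identity(sp[pairs[1, j]], sp[pairs[2, j]]),
    numeric(1))
  expect_lt(mean(ids), 0.35)
  expect_gt(mean(ids), 0.15)
})

test_that("spacer extraction yields one row per slot with inherited metadata", {
  set.seed(109)
  R <- random_dna(1, 30)
  a1 <- find_denovo_arrays(c(c1 = plant_crispr_contig(R, random_dna(3, 35))$seq),
                           host_id = "hostX")
  a2 <- find_denovo_arrays(c(c2 = plant_crispr_contig(R, random_dna(5, 35))$seq),
                           host_id = "hostY")
  sp <- extract_spacers(c(a1, a2))
  expect_equal(nrow(sp), 8)  # (4-1) + (6-1) repeats
  expect_setequal(unique(sp$host_id), c("hostX", "hostY"))
  expect_equal(sp$index_in_array[sp$host_id == "hostX"], 1:3)
  expect_equal(nrow(extract_spacers(list())), 0)
})

test_that("deduplication partitions spacers, is idempotent, and supports reverse-complement collapse", {
  set.seed(110)
  s <- random_dna(1, 32); t <- random_dna(1, 32)
  sp <- data.frame(spacer_id = c("a", "b", "c"), seq = c(s, s, t),
                   host_id = "h", array_id = "arr", contig_id = "c",
                   index_in_array = 1:3, crispr_type = c("I-C", "II-C", NA),
                   stringsAsFactors = FALSE)
  cl <- deduplicate_spacers(sp)
  expect_equal(nrow(cl), 2)
  expect_setequal(cl$n_members, c(2, 1))
  expect_setequal(unlist(cl$members), c("a", "b", "c"))
  expect_equal(sum(cl$n_members), nrow(sp))
  big <- cl$members[[which(cl$n_members == 2)]]
  expect_setequal(big, c("a", "b"))
  expect_equal(cl$crispr_types[[which(cl$n_members == 2)]],
               c("I-C", "II-C"))
  # reverse-complement mode merges the two orientations
  sp_rc <- sp
  sp_rc$seq <- c(s, revcomp(s), t)
  cl_rc <- deduplicate_spacers(sp_rc, mode = "exact_rc")
  expect_equal(nrow(cl_rc), 2)
  expect_equal(cl_rc$rep_seq[cl_rc$n_members == 2], min(s, revcomp(s)))
  # n distinct spacers -> n clusters; rerunning on representatives is identity
  sp_n <- data.frame(spacer_id = sprintf("s%d", 1:15),
                     seq = random_dna(15, 32), host_id = "h",
                     array_id = "a", contig_id = "c", index_in_array = 1:15,
                     crispr_type = NA, stringsAsFactors = FALSE)
  cl_n <- deduplicate_spacers(sp_n)
  expect_equal(nrow(cl_n), 15)
  sp2 <- data.frame(spacer_id = cl_n$cluster_id, seq = cl_n$rep_seq,
                    host_id = "h", array_id = "a", contig_id = "c",
                    index_in_array = 1:15, crispr_type = NA,
                    stringsAsFactors = FALSE)
  expect_equal(deduplicate_spacers(sp2)$rep_seq, cl_n$rep_seq)
})

test_that("spacer FASTA writing round-trips occurrences and clusters", {
  set.seed(111)
  R <- random_dna(1, 30)
  arrays <- find_denovo_arrays(
    c(c1 = plant_crispr_contig(R, random_dna(4, 35))$seq),
    host_id = "hostZ")
  sp <- extract_spacers(arrays)
  cl <- deduplicate_spacers(sp)
  f <- tempfile(fileext = ".fasta")
  write_spacer_fasta(sp, cl, f)
  back <- read_spacer_fasta(f)
  expect_equal(back$spacers$seq, sp$seq)
  expect_equal(back$spacers$host_id, sp$host_id)
  expect_equal(sort(back$clusters$rep_seq), sort(cl$rep_seq))
})
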