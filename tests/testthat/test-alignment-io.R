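test_that("fragment length is the reference span of the primary alignment", {
  bam <- make_bam(c(
    sam_line("span167", pos = 1001L, cigar = "167M", seq = strrep("A", 167)),
    sam_line("del", cigar = "5M2D5M"),
    sam_line("ins", cigar = "5M2I5M", seq = strrep("A", 12),
             qual = strrep("I", 12)),
    sam_line("clip", cigar = "3S10M2S", seq = strrep("A", 15),
             qual = strrep("I", 15))
  ))
  frags <- extract_fragments(bam)
  lens <- setNames(frags$length, sub("\\..*", "", frags$sample_id))
  got <- frags$length[order(frags$start)]
  expect_equal(nrow(frags), 4)
  by_len <- sort(frags$length)
  # deletions lengthen (12), insertions and clips do not (10, 10), 167M = 167
  expect_equal(by_len, c(10L, 10L, 12L, 167L))
  span <- frags[frags$length == 167L, ]
  expect_equal(span$start, 1000L) # 0-based
  expect_equal(span$end, 1167L)
})

test_that("the filter policy drops flagged, low-mapq, and low-qs reads", {
  bam <- make_bam(c(
    sam_line("ok", tags = "qs:f:14.5"),
    sam_line("dup", flag = 1024L, tags = "qs:f:14.5"),
    sam_line("sec", flag = 256L, tags = "qs:f:14.5"),
    sam_line("supp", flag = 2048L, tags = "qs:f:14.5"),
    sam_line("lowmapq", mapq = 10L, tags = "qs:f:14.5"),
    sam_line("lowqs", tags = "qs:f:5"),
    # no qs tag: read-level quality falls back to mean base quality
    sam_line("meanq_lo", qual = strrep("#", 10)),   # q2 -> dropped
    sam_line("meanq_hi", qual = strrep("I", 10))    # q40 -> kept
  ))
  frags <- extract_fragments(bam)
  expect_equal(nrow(frags), 2)
  rep <- filter_report(frags)
  expect_equal(rep$total, 8)
  expect_equal(rep$retained, 2)
  expect_equal(rep$dropped_flag, 3)
  expect_equal(rep$dropped_mapq, 1)
  expect_equal(rep$dropped_qs, 2)
})

test_that("extraction counts match a brute-force flag-scan oracle", {
  # 1,000 reads: 850 clean, 100 duplicates, 50 secondary
  recs <- c(
    vapply(1:850, function(i) sam_line(paste0("c", i), tags = "qs:f:12"), ""),
    vapply(1:100, function(i) sam_line(paste0("d", i), flag = 1024L,
                                       tags = "qs:f:12"), ""),
    vapply(1:50, function(i) sam_line(paste0("s", i), flag = 256L,
                                      tags = "qs:f:12"), ""))
  bam <- make_bam(recs)
  frags <- extract_fragments(bam)
  expect_equal(nrow(frags), 850)
  # independent oracle: scan the SAM text
  sam <- Rsamtools::asSam(bam, tempfile(), overwrite = TRUE)
  lines <- readLines(sam)
  lines <- lines[!startsWith(lines, "@")]
  flags <- as.integer(vapply(strsplit(lines, "\t"), `[`, "", 2))
  mapqs <- as.integer(vapply(strsplit(lines, "\t"), `[`, "", 5))
  expect_equal(sum(bitwAnd(flags, 0xD04L) == 0L & mapqs >= 20L), nrow(frags))
})

test_that("stratification keeps exactly the in-range records", {
  dir <- withr::local_tempdir()
  bam <- make_bam(c(
    sam_line("a", cigar = "100M", seq = strrep("A", 100)),
    sam_line("b", cigar = "150M", seq = strrep("A", 150)),
    sam_line("c", cigar = "250M", seq = strrep("A", 250))
  ), dir = dir)
  res <- stratify_bam_by_length(bam, list(c(75, 200)),
                                file.path(dir, "mid.bam"))
  expect_equal(res$n_retained, 2)
  got <- extract_fragments(file.path(dir, "mid.bam"))
  expect_setequal(got$length, c(100L, 150L))
})

test_that("nested ranges nest and disjoint ranges partition", {
  dir <- withr::local_tempdir()
  withr::with_seed(11, {
    lens <- sample(c(80:300, 900:4300), 300, replace = TRUE)
  })
  recs <- vapply(seq_along(lens), function(i) {
    sam_line(paste0("r", i), pos = i, cigar = paste0(lens[i], "M"),
             seq = strrep("A", lens[i]))
  }, "")
  bam <- make_bam(recs, contigs = c(chr1 = 50000L), dir = dir)
  outs <- file.path(dir, c("narrow.bam", "wide.bam", "long.bam"))
  res <- stratify_bam_by_length(bam, list(c(75, 145), c(75, 200),
                                          c(900, 4300)), outs)
  # oracle over the known lengths
  expect_equal(res$n_retained,
               c(sum(lens >= 75 & lens <= 145), sum(lens >= 75 & lens <= 200),
                 sum(lens >= 900 & lens <= 4300)))
  narrow <- extract_fragments(outs[1], sample_id = "x")
  wide <- extract_fragments(outs[2], sample_id = "x")
  expect_true(all(narrow$start %in% wide$start)) # subset by position
  # disjoint covering ranges partition the records
  part <- stratify_bam_by_length(bam, list(c(0, 200), c(201, Inf)),
                                 file.path(dir, c("p1.bam", "p2.bam")))
  expect_equal(sum(part$n_retained), length(lens))
  # round trip: [0, Inf) reproduces the full record set
  rt <- stratify_bam_by_length(bam, list(c(0, Inf)),
                               file.path(dir, "all.bam"))
  expect_equal(rt$n_retained, length(lens))
  all_frags <- extract_fragments(file.path(dir, "all.bam"), sample_id = "x")
  orig <- extract_fragments(bam, sample_id = "x")
  expect_equal(dplyr::arrange(all_frags, start), dplyr::arrange(orig, start),
               ignore_attr = TRUE)
  expect_error(stratify_bam_by_length(bam, list(c(0, 10), c(20, 30)),
                                      file.path(dir, c("z.bam", "z.bam"))),
               "overlap")
})

test_that("anonymization restores mismatches, masks insertions, and is idempotent", {
  dir <- withr::local_tempdir()
  withr::with_seed(3, {
    refseq <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                    collapse = "")
  })
  fa <- file.path(dir, "ref.fa")
  ref <- Biostrings::DNAStringSet(setNames(refseq, "chr1"))
  Biostrings::writeXStringSet(ref, fa)
  exact <- substr(refseq, 100, 149)
  mism <- exact
  substr(mism, 10, 10) <- if (substr(exact, 10, 10) == "T") "A" else "T"
  with_ins <- paste0(substr(exact, 1, 20), "GG", substr(exact, 21, 50))
  bam <- make_bam(c(
    sam_line("identical", pos = 100L, cigar = "50M", seq = exact),
    sam_line("mismatch", pos = 100L, cigar = "50M", seq = mism,
             tags = c("NM:i:1", paste0("MD:Z:9", substr(exact, 10, 10), "40"))),
    sam_line("insertion", pos = 100L, cigar = "20M2I30M", seq = with_ins)
  ), contigs = c(chr1 = 300L), dir = dir)
  out <- file.path(dir, "anon.bam")
  summ <- anonymize_bam(bam, fa, out)
  expect_equal(summ$mismatches_restored, 1)
  expect_equal(summ$insertion_bases_masked, 2)
  got <- Rsamtools::scanBam(out, param = Rsamtools::ScanBamParam(
    what = c("qname", "seq", "cigar")))[[1]]
  seqs <- setNames(as.character(got$seq), got$qname)
  expect_equal(seqs[["identical"]], exact)
  expect_equal(seqs[["mismatch"]], exact)   # C->T style variant restored
  expect_equal(seqs[["insertion"]],
               paste0(substr(exact, 1, 20), "NN", substr(exact, 21, 50)))
  expect_equal(got$cigar[got$qname == "insertion"], "20M2I30M")
  # MD/NM dropped
  sam <- Rsamtools::asSam(out, tempfile(), overwrite = TRUE)
  expect_false(any(grepl("MD:Z:|NM:i:", readLines(sam))))
  # idempotence
  out2 <- file.path(dir, "anon2.bam")
  summ2 <- anonymize_bam(out, fa, out2)
  expect_equal(summ2$mismatches_restored, 0)
  expect_equal(summ2$insertion_bases_masked, 2) # Ns re-masked, same bases
  expect_error(anonymize_bam(make_bam(sam_line("x", rname = "chrZ"),
                                      contigs = c(chrZ = 1000L), dir = dir),
                             fa, file.path(dir, "y.bam")),
               "chrZ")
})

test_that("unreadable input fails loudly and names the file", {
  expect_error(extract_fragments("/nonexistent/file.bam"), "nonexistent")
})
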