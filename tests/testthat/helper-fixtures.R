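# Shared fixture builders. Everything is generated in code at test time;
# no binary files ship with the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build a BAM from hand-written SAM alignment lines.
make_bam <- function(records, contigs = c(chr1 = 10000L),
                     dir = withr::local_tempdir(.local_envir = parent.frame())) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs))
  sam <- file.path(dir, "fixture.sam")
  writeLines(c(header, records), sam)
  Rsamtools::asBam(sam, file.path(dir, "fixture"), overwrite = TRUE,
                   indexDestination = TRUE)
}

# One SAM alignment line with sane defaults.
sam_line <- function(qname, flag = 0L, rname = "chr1", pos = 100L,
                     mapq = 60L, cigar = "10M",
                     seq = strrep("A", 10), qual = strrep("I", nchar(seq)),
                     tags = character()) {
  paste(c(qname, flag, rname, pos, mapq, cigar, "*", 0, 0, seq, qual, tags),
        collapse = "\t")
}

# A small cohort spec sized for fast tests.
test_cohort_spec <- function(n_samples_per_class = c(healthy_like = 5,
                                                     hypofragmented = 3,
                                                     hyperfragmented = 3,
                                                     ultralong = 2),
                             fragments_per_sample = 2000, seed = 1, ...) {
  cohort_spec(n_samples_per_class = n_samples_per_class,
              fragments_per_sample = fragments_per_sample, seed = seed, ...)
}

# Independent binning oracle: per-fragment exponent rounding + tapply
# aggregation, sharing no code with length_profile().
oracle_profile <- function(lengths, min_bp = 50, max_bp = 50000, step = 0.01) {
  ex <- round(log10(lengths) / step) * step
  ex <- pmin(pmax(ex, round(log10(min_bp) / step) * step),
             round(log10(max_bp) / step) * step)
  key <- sprintf("%.2f", ex)
  all_keys <- sprintf("%.2f", (round(log10(min_bp) / step):
                                 round(log10(max_bp) / step)) * step)
  cnt <- table(factor(key, levels = all_keys))
  bp <- tapply(as.numeric(lengths), factor(key, levels = all_keys), sum,
               default = 0)
  list(fragment_proportion = as.numeric(cnt) / length(lengths),
       dna_proportion = as.numeric(bp) / sum(as.numeric(lengths)))
}

# Independent end-motif oracle: a literal per-read scan over SAM text.
oracle_motif_calls <- function(bam_path, min_baseq = 20,
                               adapter_tail = "CACCT") {
  sam <- Rsamtools::asSam(bam_path, tempfile(), overwrite = TRUE)
  lines <- readLines(sam)
  unlink(sam)
  lines <- lines[!startsWith(lines, "@")]
  out <- list()
  rc <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    cigar <- f[6]; seq <- f[10]; qual <- utf8ToInt(f[11]) - 33L
    if (cigar == "*") next
    toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
    ops <- substring(toks, nchar(toks), nchar(toks))
    lens <- as.integer(substring(toks, 1, nchar(toks) - 1))
    lclip <- if (ops[1] == "S") lens[1] else 0L
    rclip <- if (ops[length(ops)] == "S") lens[length(lens)] else 0L
    n_aligned <- nchar(seq) - lclip - rclip
    if (lclip >= 5 && n_aligned >= 5) {
      clip <- substr(seq, 1, lclip)
      if (substr(clip, lclip - 4, lclip) == adapter_tail) {
        motif <- substr(seq, lclip + 1, lclip + 5)
        pass <- all(qual[(lclip + 1):(lclip + 5)] >= min_baseq)
        out[[length(out) + 1]] <- data.frame(qname = f[1], side = "left",
                                             motif = motif,
                                             passed_quality = pass)
      }
    }
    if (rclip >= 5 && n_aligned >= 5) {
      L <- nchar(seq)
      clip <- substr(seq, L - rclip + 1, L)
      if (substr(clip, 1, 5) == rc(adapter_tail)) {
        last5 <- substr(seq, L - rclip - 4, L - rclip)
        pass <- all(qual[(L - rclip - 4):(L - rclip)] >= min_baseq)
        out[[length(out) + 1]] <- data.frame(qname = f[1], side = "right",
                                             motif = rc(last5),
                                             passed_quality = pass)
      }
    }
  }
  do.call(rbind, out)
}
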