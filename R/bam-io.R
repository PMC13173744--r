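#' Read filter policy
#'
#' The read-level retention contract applied before any fragmentomic
#' analysis: minimum read-level basecall quality (`qs`), minimum mapping
#' quality, and a SAM flag mask whose set bits cause removal. The default
#' mask `0xD04` drops unmapped, secondary, duplicate, and supplementary
#' records, so each retained record is one primary alignment = one fragment.
#'
#' @param min_read_qs Minimum read-level mean basecall quality (default 10).
#' @param min_mapq Minimum mapping quality (default 20).
#' @param excluded_flags Integer flag mask (default `0xD04`).
#' @return A `read_filter_policy` list.
#' @export
read_filter_policy <- function(min_read_qs = 10, min_mapq = 20,
                               excluded_flags = 0xD04L) {
  stopifnot(min_read_qs >= 0, min_mapq >= 0, excluded_flags >= 0)
  structure(list(min_read_qs = min_read_qs, min_mapq = as.integer(min_mapq),
                 excluded_flags = as.integer(excluded_flags)),
            class = "read_filter_policy")
}

phred_means <- function(qual) {
  # mean per-base Phred score per read; NA for missing ('*') qualities
  il <- as(qual, "IntegerList")
  m <- sum(il) / lengths(il)
  m[lengths(il) == 0] <- NA_real_
  as.numeric(m)
}

#' Extract fragment records from a BAM file
#'
#' One record per retained primary alignment. Fragment length is the
#' reference span of the alignment (end minus start on the reference, so
#' deletions lengthen a fragment and insertions do not). Records failing the
#' policy are dropped and tallied by reason in the `filter_report` attribute
#' (also available via [filter_report()]).
#'
#' The read-level quality `read_qs` is taken from the alignment's `qs` tag
#' when present and is otherwise the mean base quality of the record.
#'
#' @param bam_path Path to a BAM file.
#' @param policy A [read_filter_policy()].
#' @param sample_id Sample label for the output; defaults to the BAM base
#'   name.
#' @return Tibble of fragment records (`sample_id`, `chrom`, `start` 0-based,
#'   `end` exclusive, `length`, `mapq`, `read_qs`, `is_duplicate`, `flags`)
#'   with attribute `filter_report`.
#' @export
extract_fragments <- function(bam_path, policy = read_filter_policy(),
                              sample_id = NULL) {
  if (!file.exists(bam_path)) {
    abort(sprintf("BAM file not found: %s", bam_path))
  }
  sample_id <- sample_id %||% sub("\\.bam$", "", basename(bam_path))
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "qual"),
    tag = "qs")
  res <- tryCatch(Rsamtools::scanBam(bam_path, param = param)[[1]],
                  error = function(e) {
                    abort(sprintf("failed to read BAM file %s: %s",
                                  bam_path, conditionMessage(e)))
                  })
  n_total <- length(res$flag)
  if (n_total == 0) {
    warn(sprintf("no records in %s", bam_path))
  }
  flag_fail <- bitwAnd(res$flag, policy$excluded_flags) != 0L
  mapq <- res$mapq
  mapq_fail <- !flag_fail & (is.na(mapq) | mapq < policy$min_mapq)
  qs <- res$tag$qs
  if (is.null(qs)) qs <- rep(NA_real_, n_total)
  qs <- ifelse(is.na(qs), phred_means(res$qual), as.numeric(qs))
  qs_fail <- !flag_fail & !mapq_fail & (is.na(qs) | qs < policy$min_read_qs)
  keep <- !(flag_fail | mapq_fail | qs_fail)
  width <- rep(NA_integer_, n_total)
  has_cig <- !is.na(res$cigar)
  width[has_cig] <-
    GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar[has_cig])
  out <- tibble(
    sample_id = sample_id,
    chrom = as.character(res$rname)[keep],
    start = res$pos[keep] - 1L,
    end = res$pos[keep] - 1L + width[keep],
    length = width[keep],
    mapq = res$mapq[keep],
    read_qs = qs[keep],
    is_duplicate = bitwAnd(res$flag[keep], 0x400L) != 0L,
    flags = res$flag[keep])
  if (n_total > 0 && nrow(out) == 0) {
    warn(sprintf("no records retained from %s under the filter policy",
                 bam_path))
  }
  attr(out, "filter_report") <- tibble(
    sample_id = sample_id, total = n_total, retained = sum(keep),
    dropped_flag = sum(flag_fail), dropped_mapq = sum(mapq_fail),
    dropped_qs = sum(qs_fail))
  out
}

#' Retrieve the filter report of an extraction
#' @param fragments Output of [extract_fragments()].
#' @return One-row tibble with total/retained/dropped-by-reason counts.
#' @export
filter_report <- function(fragments) {
  attr(fragments, "filter_report")
}

read_sam_lines <- function(bam_path) {
  sam <- Rsamtools::asSam(bam_path,
                          tempfile(fileext = ""), overwrite = TRUE)
  lines <- readLines(sam)
  unlink(sam)
  list(header = lines[startsWith(lines, "@")],
       records = lines[!startsWith(lines, "@")])
}

write_bam_from_sam <- function(header, records, out_path) {
  samfile <- tempfile(fileext = ".sam")
  writeLines(c(header, records), samfile)
  dest <- sub("\\.bam$", "", out_path)
  bam <- Rsamtools::asBam(samfile, dest, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(samfile)
  bam
}

sam_ref_width <- function(records) {
  fields <- strsplit(records, "\t", fixed = TRUE)
  cigar <- map_chr(fields, 6)
  w <- rep(NA_integer_, length(cigar))
  ok <- cigar != "*"
  w[ok] <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar[ok])
  w
}

#' Split a BAM by fragment length
#'
#' Writes one output BAM per closed length range `[min_bp, max_bp]`,
#' containing exactly the records whose reference-span fragment length falls
#' in the range (the same length definition as [extract_fragments()]).
#' Headers are preserved; unmapped records, which have no reference span,
#' are never written.
#'
#' @param bam_path Input BAM.
#' @param ranges List of two-element numeric vectors `c(min_bp, max_bp)`
#'   (`max_bp` may be `Inf`).
#' @param out_paths Output BAM paths, one per range, all distinct.
#' @return Tibble with `min_bp`, `max_bp`, `out_path`, `n_retained`.
#' @export
stratify_bam_by_length <- function(bam_path, ranges, out_paths) {
  if (length(ranges) != length(out_paths)) {
    abort("`ranges` and `out_paths` must have equal length")
  }
  if (anyDuplicated(normalizePath(out_paths, mustWork = FALSE))) {
    abort("output paths overlap")
  }
  sam <- read_sam_lines(bam_path)
  width <- sam_ref_width(sam$records)
  out <- map(seq_along(ranges), function(i) {
    r <- ranges[[i]]
    stopifnot(length(r) == 2, r[1] <= r[2])
    keep <- !is.na(width) & width >= r[1] & width <= r[2]
    if (!any(keep)) {
      warn(sprintf("no records in range [%s, %s]; writing empty BAM",
                   r[1], r[2]))
    }
    write_bam_from_sam(sam$header, sam$records[keep], out_paths[[i]])
    tibble(min_bp = r[1], max_bp = r[2], out_path = out_paths[[i]],
           n_retained = sum(keep))
  })
  list_rbind(out)
}

strip_fasta_names <- function(dss) {
  names(dss) <- sub("\\s.*$", "", names(dss))
  dss
}

anonymize_record <- function(fields, ref) {
  cigar <- fields[6]
  seq <- fields[10]
  if (cigar == "*" || seq == "*") {
    return(list(fields = fields, n_sub = 0L, n_ins = 0L))
  }
  chrom <- fields[3]
  rpos <- as.integer(fields[4])
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  qraw <- charToRaw(seq)
  qpos <- 1L
  n_sub <- 0L; n_ins <- 0L
  for (k in seq_along(ops)) {
    op <- ops[k]; len <- lens[k]
    if (op %in% c("M", "=", "X")) {
      rchunk <- charToRaw(toupper(as.character(
        Biostrings::subseq(ref[[chrom]], rpos, rpos + len - 1L))))
      idx <- which(qraw[qpos:(qpos + len - 1L)] != rchunk)
      if (length(idx)) {
        qraw[qpos + idx - 1L] <- rchunk[idx]
        n_sub <- n_sub + length(idx)
      }
      qpos <- qpos + len; rpos <- rpos + len
    } else if (op == "I") {
      qraw[qpos:(qpos + len - 1L)] <- charToRaw(strrep("N", len))
      n_ins <- n_ins + len
      qpos <- qpos + len
    } else if (op %in% c("D", "N")) {
      rpos <- rpos + len
    } else if (op == "S") {
      qpos <- qpos + len
    } # H, P consume neither
  }
  fields[10] <- rawToChar(qraw)
  # variant-bearing auxiliary tags are no longer valid after scrubbing
  if (length(fields) > 11) {
    opt <- fields[12:length(fields)]
    fields <- c(fields[1:11], opt[!grepl("^(MD:Z:|NM:i:)", opt)])
  }
  list(fields = fields, n_sub = n_sub, n_ins = n_ins)
}

#' Anonymize a BAM against a reference genome
#'
#' Replaces every aligned mismatch base with the reference base and every
#' inserted base with `N`, leaving coordinates, CIGAR strings, base
#' qualities, deletions, and clips untouched. `MD`/`NM` tags, which would
#' otherwise still encode the variants, are dropped. The result carries no
#' single-nucleotide or insertion variant information.
#'
#' @param bam_path Input BAM.
#' @param reference_fasta FASTA matching the BAM's sequence dictionary.
#' @param out_path Output BAM path.
#' @return One-row tibble: `reads`, `mismatches_restored`,
#'   `insertion_bases_masked`, `out_path`.
#' @export
anonymize_bam <- function(bam_path, reference_fasta, out_path) {
  ref <- strip_fasta_names(Biostrings::readDNAStringSet(reference_fasta))
  sam <- read_sam_lines(bam_path)
  fields <- strsplit(sam$records, "\t", fixed = TRUE)
  chroms <- unique(map_chr(fields, 3))
  chroms <- setdiff(chroms, "*")
  missing <- setdiff(chroms, names(ref))
  if (length(missing)) {
    abort(sprintf("contig(s) absent from reference FASTA: %s",
                  paste(missing, collapse = ", ")))
  }
  res <- map(fields, anonymize_record, ref = ref)
  records <- map_chr(res, ~ paste(.x$fields, collapse = "\t"))
  write_bam_from_sam(sam$header, records, out_path)
  tibble(reads = length(records),
         mismatches_restored = sum(map_int(res, "n_sub")),
         insertion_bases_masked = sum(map_int(res, "n_ins")),
         out_path = out_path)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Write a toy reference FASTA
#'
#' Random uniform sequence per contig of the toy genome (deterministic under
#' the caller's RNG state).
#'
#' @param genome Toy genome tibble ([toy_genome()]).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_toy_fasta <- function(genome, path) {
  seqs <- Biostrings::DNAStringSet(vapply(genome$length, rand_dna, ""))
  names(seqs) <- genome$chrom
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write simulated fragments as per-sample BAM files
#'
#' Serializes each simulated fragment as one primary alignment whose
#' reference span equals the fragment length. Each read carries a 7-bp
#' leading soft clip ending in the adapter tail `CACCT` and a 7-bp trailing
#' soft clip starting with its reverse complement, so the adapter-anchored
#' end-motif caller is fully exercised: the first five aligned bases are the
#' fragment's left motif and the last five are the reverse complement of its
#' right motif. With probability `p_low_qual` per end, one of the five
#' motif-adjacent base qualities is set below the calling threshold.
#'
#' @param fragments Fragment tibble from [simulate_cohort()].
#' @param genome Toy genome used for the simulation.
#' @param out_dir Output directory (created if needed).
#' @param p_low_qual Per-end probability of a disqualifying low-quality base.
#' @param fasta Whether to also write the toy reference FASTA
#'   (`<out_dir>/toy_genome.fa`).
#' @return Tibble with `sample_id`, `bam`, `n_fragments` (plus attribute
#'   `fasta` when written).
#' @export
write_cohort_bam <- function(fragments, genome, out_dir, p_low_qual = 0,
                             fasta = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", genome$chrom, genome$length))
  fa_path <- NULL
  if (fasta) {
    fa_path <- file.path(out_dir, "toy_genome.fa")
    write_toy_fasta(genome, fa_path)
  }
  out <- fragments |>
    group_by(.data$sample_id) |>
    dplyr::group_map(function(df, key) {
      n <- nrow(df)
      core <- vapply(seq_len(n), function(i) {
        len <- df$length[i]
        mid <- if (len > 10) rand_dna(len - 10) else ""
        paste0(df$left_motif[i],
               substr(mid, 1, max(len - 10, 0)),
               revcomp(df$right_motif[i]))
      }, "")
      seq <- paste0("NNCACCT", core, "AGGTGNN")
      qual <- vapply(df$length + 14L, function(L) strrep("I", L), "")
      # optionally degrade one of the five motif-adjacent bases per end
      low_l <- runif(n) < p_low_qual
      low_r <- runif(n) < p_low_qual
      for (i in which(low_l)) {
        p <- 7L + sample.int(5L, 1)
        substr(qual[i], p, p) <- "#"
      }
      for (i in which(low_r)) {
        p <- nchar(qual[i]) - 7L - sample.int(5L, 1) + 1L
        substr(qual[i], p, p) <- "#"
      }
      recs <- sprintf("frag%06d\t0\t%s\t%d\t%d\t7S%dM7S\t*\t0\t0\t%s\t%s\tqs:f:%s",
                      seq_len(n), df$chrom, df$start + 1L, df$mapq,
                      df$length, seq, qual, format(df$read_qs))
      bam <- write_bam_from_sam(header, recs,
                                file.path(out_dir, paste0(key$sample_id, ".bam")))
      tibble(sample_id = key$sample_id, bam = bam, n_fragments = n)
    }) |>
    list_rbind()
  attr(out, "fasta") <- fa_path
  out
}
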