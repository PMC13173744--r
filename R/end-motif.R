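#' Call adapter-anchored 5' end motifs from a BAM file
#'
#' A fragment end yields a motif call only when the soft-clipped sequence
#' immediately flanking the aligned portion carries a perfect match to the
#' terminal 5 bp of the sequencing adapter (`CACCT`) directly adjacent to the
#' alignment — evidence that the read captured the true molecule end. The
#' motif is the first five aligned bases in read orientation; if any of those
#' five bases has basecall quality below `min_baseq` the end is rejected
#' (`passed_quality = FALSE`). The two ends of a fragment are independent
#' observations: the 3' read end is handled symmetrically, anchoring on the
#' reverse complement of the adapter tail at the start of the trailing soft
#' clip and reverse-complementing the last five aligned bases into 5'-to-3'
#' fragment-end orientation.
#'
#' @param bam_path Path to a BAM file.
#' @param min_baseq Minimum basecall quality over the 5 motif bases.
#' @param adapter_tail Final 5 bp of the adapter (read orientation).
#' @param policy A [read_filter_policy()] applied before calling, or `NULL`
#'   to call on all records.
#' @param sample_id Sample label; defaults to the BAM base name.
#' @return Tibble of candidate calls (ends with an adapter anchor):
#'   `sample_id`, `qname`, `side` (`left`/`right`), `motif`,
#'   `passed_quality`, `length` (fragment reference span). Reads lacking
#'   base qualities are skipped and counted in the `n_skipped_noqual`
#'   attribute.
#' @export
call_end_motifs <- function(bam_path, min_baseq = 20, adapter_tail = "CACCT",
                            policy = read_filter_policy(), sample_id = NULL) {
  sample_id <- sample_id %||% sub("\\.bam$", "", basename(bam_path))
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "mapq", "cigar", "seq", "qual"), tag = "qs")
  res <- Rsamtools::scanBam(bam_path, param = param)[[1]]
  keep <- !is.na(res$cigar)
  if (!is.null(policy)) {
    qs <- res$tag$qs
    if (is.null(qs)) qs <- rep(NA_real_, length(res$flag))
    qs <- ifelse(is.na(qs), phred_means(res$qual), as.numeric(qs))
    keep <- keep &
      bitwAnd(res$flag, policy$excluded_flags) == 0L &
      !is.na(res$mapq) & res$mapq >= policy$min_mapq &
      !is.na(qs) & qs >= policy$min_read_qs
  }
  seq <- as.character(res$seq)[keep]
  qual <- as(res$qual, "IntegerList")[keep]
  cigar <- res$cigar[keep]
  qname <- res$qname[keep]
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  noqual <- lengths(qual) == 0 | lengths(qual) != nchar(seq)
  n_skip <- sum(noqual)
  seq <- seq[!noqual]; qual <- qual[!noqual]; cigar <- cigar[!noqual]
  qname <- qname[!noqual]; width <- width[!noqual]

  lclip <- suppressWarnings(as.integer(
    sub("^([0-9]+)S.*$", "\\1", cigar, perl = TRUE)))
  lclip[!grepl("^[0-9]+S", cigar)] <- 0L
  rclip <- suppressWarnings(as.integer(
    sub("^.*?([0-9]+)S$", "\\1", cigar, perl = TRUE)))
  rclip[!grepl("[0-9]+S$", cigar)] <- 0L
  L <- nchar(seq)
  n_aligned <- L - lclip - rclip
  anchor_rc <- revcomp(adapter_tail)
  k <- nchar(adapter_tail)

  calls <- list()
  # left (5' read) end
  ok_l <- lclip >= k & n_aligned >= 5 &
    substr(seq, lclip - k + 1L, lclip) == adapter_tail
  if (any(ok_l)) {
    idx <- which(ok_l)
    motif <- substr(seq[idx], lclip[idx] + 1L, lclip[idx] + 5L)
    qpass <- map_lgl_idx(qual, idx, lclip[idx] + 1L, min_baseq)
    calls$left <- tibble(sample_id = sample_id, qname = qname[idx],
                         side = "left", motif = motif,
                         passed_quality = qpass, length = width[idx])
  }
  # right (3' read) end, reported in fragment 5'-to-3' orientation
  ok_r <- rclip >= k & n_aligned >= 5 &
    substr(seq, L - rclip + 1L, L - rclip + k) == anchor_rc
  if (any(ok_r)) {
    idx <- which(ok_r)
    last5_start <- L[idx] - rclip[idx] - 4L
    motif <- revcomp(substr(seq[idx], last5_start, last5_start + 4L))
    qpass <- map_lgl_idx(qual, idx, last5_start, min_baseq)
    calls$right <- tibble(sample_id = sample_id, qname = qname[idx],
                          side = "right", motif = motif,
                          passed_quality = qpass, length = width[idx])
  }
  out <- if (length(calls)) list_rbind(unname(calls)) else
    tibble(sample_id = character(), qname = character(), side = character(),
           motif = character(), passed_quality = logical(),
           length = integer())
  attr(out, "n_skipped_noqual") <- n_skip
  out
}

map_lgl_idx <- function(qual, idx, starts, min_baseq) {
  vapply(seq_along(idx), function(j) {
    q <- qual[[idx[j]]][starts[j]:(starts[j] + 4L)]
    all(q >= min_baseq)
  }, logical(1))
}

#' Motif calls from simulated fragment records
#'
#' Pivots the ground-truth `left_motif`/`right_motif` columns of a simulated
#' fragment table into the call format used by [motif_spectrum()], so the
#' motif statistics can be computed without a BAM round trip.
#'
#' @param fragments Fragment tibble from [simulate_cohort()].
#' @return Call tibble (`sample_id`, `side`, `motif`, `passed_quality`,
#'   `length`).
#' @export
fragment_motif_calls <- function(fragments) {
  fragments |>
    select("sample_id", "length", left = "left_motif", right = "right_motif") |>
    tidyr::pivot_longer(c("left", "right"), names_to = "side",
                        values_to = "motif") |>
    mutate(passed_quality = TRUE) |>
    select("sample_id", "side", "motif", "passed_quality", "length")
}

#' Motif spectrum of a set of end-motif calls
#'
#' Counts quality-passing calls per 5-mer and derives the CC- and
#' CCCA-prefix fractions (the DNASE1L3 cleavage signature).
#'
#' @param calls Call tibble ([call_end_motifs()] or
#'   [fragment_motif_calls()]).
#' @return Tibble (`motif`, `n`, `freq`) sorted by decreasing count, with
#'   attributes `n_calls`, `cc_frac`, `ccca_frac` (also see
#'   [motif_fractions()]). Zero calls give an empty sentinel with `NA`
#'   fractions.
#' @export
motif_spectrum <- function(calls) {
  passed <- filter(calls, .data$passed_quality)
  out <- passed |>
    count(.data$motif, name = "n", sort = TRUE) |>
    mutate(freq = .data$n / sum(.data$n))
  attr(out, "n_calls") <- nrow(passed)
  attr(out, "cc_frac") <- if (nrow(passed)) mean(startsWith(passed$motif, "CC")) else NA_real_
  attr(out, "ccca_frac") <- if (nrow(passed)) mean(startsWith(passed$motif, "CCCA")) else NA_real_
  out
}

#' CC/CCCA end-motif fractions
#'
#' @param calls Call tibble; grouped per sample when a `sample_id` column is
#'   present.
#' @return Tibble with `sample_id` (if present), `n_calls`, `cc_frac`,
#'   `ccca_frac`.
#' @export
motif_fractions <- function(calls) {
  passed <- filter(calls, .data$passed_quality)
  by <- intersect("sample_id", names(passed))
  passed |>
    summarise(n_calls = n(),
              cc_frac = mean(startsWith(.data$motif, "CC")),
              ccca_frac = mean(startsWith(.data$motif, "CCCA")),
              .by = dplyr::all_of(by))
}

#' Length-stratified end-motif fractions
#'
#' Computes CC/CCCA fractions within fragment-length strata; both ends of a
#' fragment fall in the stratum of the fragment's length. Strata must be
#' disjoint closed intervals.
#'
#' @param calls Call tibble carrying a `length` column.
#' @param strata List of `c(min_bp, max_bp)` intervals (`max_bp` may be
#'   `Inf`).
#' @return Tibble with `sample_id` (if present), `stratum`, `min_bp`,
#'   `max_bp`, `n_calls`, `cc_frac`, `ccca_frac`. Empty strata appear with
#'   `n_calls = 0` and `NA` fractions.
#' @export
motifs_by_length <- function(calls,
                             strata = list(c(100, 400), c(7500, Inf))) {
  bounds <- list_rbind(map(strata, ~ tibble(min_bp = .x[1], max_bp = .x[2])))
  o <- order(bounds$min_bp)
  if (any(bounds$min_bp[o][-1] <= bounds$max_bp[o][-nrow(bounds)])) {
    abort("strata must be disjoint")
  }
  by <- intersect("sample_id", names(calls))
  out <- map(seq_len(nrow(bounds)), function(i) {
    sub <- filter(calls, .data$passed_quality,
                  .data$length >= bounds$min_bp[i],
                  .data$length <= bounds$max_bp[i])
    res <- sub |>
      summarise(n_calls = n(),
                cc_frac = mean(startsWith(.data$motif, "CC")),
                ccca_frac = mean(startsWith(.data$motif, "CCCA")),
                .by = dplyr::all_of(by))
    if (nrow(res) == 0) {
      res <- tibble(n_calls = 0L, cc_frac = NA_real_, ccca_frac = NA_real_)
    }
    mutate(res,
           stratum = sprintf("%g-%g", bounds$min_bp[i], bounds$max_bp[i]),
           min_bp = bounds$min_bp[i], max_bp = bounds$max_bp[i],
           .before = 1)
  })
  list_rbind(out)
}
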