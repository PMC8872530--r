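#' Filter placements on mapping quality
#'
#' Removes placements with mapping quality below `min_mq` (default 30, the
#' conventional cut for degraded-sample pipelines); the boundary value is
#' retained.
#'
#' @param placements A placement tibble carrying an `mq` column (chimeric or
#'   lifted coordinates).
#' @param min_mq Minimum retained mapping quality.
#' @return The retained rows, with the number removed recorded in the
#'   `"n_mq_filtered"` attribute; `"insertions"`, `"rejected"` and
#'   `"circle_length"` attributes are carried through (insertions restricted
#'   to surviving reads).
#' @export
filter_placements <- function(placements, min_mq = 30) {
  check_columns(placements, "mq", "placements")
  keep <- placements$mq >= min_mq
  out <- placements[keep, ]
  out <- carry_attrs(out, placements)
  attr(out, "n_mq_filtered") <- sum(!keep)
  out
}

#' Remove duplicate placements
#'
#' Collapses placements sharing identical circular fragment endpoints
#' (`rcrs_start`, `rcrs_end`, and strand when present) to a single
#' representative — the criterion approximating duplicate marking of merged
#' single-end fragments, where identical endpoints indicate PCR copies of
#' one molecule. The representative is the highest-MQ placement, ties broken
#' by first `read_id`. Idempotent.
#'
#' @param lifted Lifted placement tibble from [liftover_to_rcrs()].
#' @return Unique placements, with the number removed in the
#'   `"n_duplicates_removed"` attribute.
#' @export
deduplicate_placements <- function(lifted) {
  check_columns(lifted, c("read_id", "rcrs_start", "rcrs_end", "mq"),
                "lifted")
  strand <- if ("strand" %in% names(lifted)) lifted$strand else "+"
  key <- paste(lifted$rcrs_start, lifted$rcrs_end, strand, sep = "|")
  ord <- order(key, -lifted$mq, lifted$read_id)
  keep_sorted <- !duplicated(key[ord])
  keep <- logical(nrow(lifted))
  keep[ord] <- keep_sorted
  out <- lifted[keep, ]
  out <- carry_attrs(out, lifted)
  attr(out, "n_duplicates_removed") <- sum(!keep)
  out
}

# carry bookkeeping attributes across filtering steps
carry_attrs <- function(out, src) {
  ins <- attr(src, "insertions")
  if (!is.null(ins)) {
    attr(out, "insertions") <- ins %>%
      filter(.data$read_id %in% out$read_id)
  }
  for (a in c("rejected", "circle_length", "n_mq_filtered",
              "n_duplicates_removed")) {
    if (!is.null(attr(src, a))) attr(out, a) <- attr(src, a)
  }
  out
}

#' Filter read records for sparse-SNP analysis
#'
#' Retains read records usable for autosomal SNP calling in degraded
#' samples: length strictly greater than `min_length_excl` (short fragments
#' invite spurious microbial mappings) and mapping quality at least
#' `min_mq`. Defaults follow the conventional thresholds: reads > 35 bp,
#' MQ >= 30.
#'
#' @param reads A tibble with columns `length` and `mq`.
#' @param min_length_excl Exclusive length threshold (default 35; a 35 bp
#'   read is dropped, a 36 bp read kept).
#' @param min_mq Inclusive mapping-quality threshold (default 30).
#' @return The retained rows.
#' @export
#' @examples
#' reads <- tibble::tibble(length = c(35, 36, 50), mq = c(60, 29, 30))
#' filter_reads_for_snps(reads) # only the 50 bp MQ30 read survives
filter_reads_for_snps <- function(reads, min_length_excl = 35, min_mq = 30) {
  check_columns(reads, c("length", "mq"), "reads")
  if (anyNA(reads$length) || anyNA(reads$mq)) {
    abort("`reads` must carry complete `length` and `mq` fields")
  }
  reads[reads$length > min_length_excl & reads$mq >= min_mq, ]
}
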