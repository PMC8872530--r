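#' Simulate per-chromosome read counts for a sexed sample
#'
#' Distributes `total_reads` over the 22 autosomes and the X chromosome by a
#' multinomial draw with weights proportional to chromosome length times
#' copy-number dosage: the X weight is halved for males (one X copy against
#' two of every autosome), left full for females. This is the generative
#' model behind X-to-autosome ratio sexing of shotgun data.
#'
#' @param sex `"female"` or `"male"`.
#' @param total_reads Total mapped read count (>= 0).
#' @param chrom_lengths Length table with columns `chrom` and `length_bp`
#'   covering chr1-22 and X; defaults to [grch37_chrom_lengths()].
#' @param seed Optional integer seed.
#' @return A tibble with columns `chrom`, `n_reads`, `length_bp`; counts sum
#'   to `total_reads` exactly.
#' @export
#' @examples
#' simulate_chromosome_counts("male", 1e5, seed = 1)
simulate_chromosome_counts <- function(sex = c("female", "male"), total_reads,
                                       chrom_lengths = grch37_chrom_lengths(),
                                       seed = NULL) {
  sex <- match.arg(sex)
  total_reads <- check_count(total_reads, "total_reads", min = 0)
  check_columns(chrom_lengths, c("chrom", "length_bp"), "chrom_lengths")
  chrom_lengths <- chrom_lengths %>%
    mutate(chrom = normalise_chrom(.data$chrom))
  wanted <- c(as.character(1:22), "X")
  if (!all(wanted %in% chrom_lengths$chrom)) {
    abort("`chrom_lengths` must cover chromosomes 1-22 and X")
  }
  chrom_lengths <- chrom_lengths[match(wanted, chrom_lengths$chrom), ]
  dosage <- c(rep(1, 22), if (sex == "male") 0.5 else 1)
  w <- chrom_lengths$length_bp * dosage
  counts <- if (total_reads == 0L) {
    rep(0L, 23L)
  } else {
    with_seed_or_current(seed, as.integer(rmultinom(1L, total_reads, w)))
  }
  tibble(
    chrom = chrom_lengths$chrom,
    n_reads = counts,
    length_bp = chrom_lengths$length_bp
  )
}

#' Read or write a per-chromosome read-count table as TSV
#'
#' Columns: `chrom`, `n_reads`, `length_bp`.
#'
#' @param path File path.
#' @param counts Count tibble.
#' @return `read_chromosome_counts()` returns the tibble; the writer returns
#'   its input invisibly.
#' @export
read_chromosome_counts <- function(path) {
  counts <- readr::read_tsv(path, show_col_types = FALSE,
                            col_types = readr::cols(
                              chrom = readr::col_character()
                            ))
  check_columns(counts, c("chrom", "n_reads", "length_bp"), "counts")
  counts
}

#' @rdname read_chromosome_counts
#' @export
write_chromosome_counts <- function(counts, path) {
  check_columns(counts, c("chrom", "n_reads", "length_bp"), "counts")
  readr::write_tsv(counts, path)
  invisible(counts)
}
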