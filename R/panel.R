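#' Allele-frequency laws for simulated SNP panels
#'
#' Constructors for the sampling law of population alternate-allele
#' frequencies used by [simulate_panel()]. Each returns a function of a
#' single count `n` producing `n` frequencies strictly inside `(0, 1)`.
#'
#' `freq_uniform()` is the package default: a uniform law on
#' `(floor, 1 - floor)` as a stand-in for common-SNP genotyping-array
#' frequency spectra, which are enriched for informative intermediate
#' frequencies. `freq_beta()` rescales a Beta law into the same floored
#' interval for spectra skewed toward rare alleles. `freq_constant()` is the
#' degenerate law, useful for analytic checks.
#'
#' @param min,max Bounds of the uniform law; must satisfy
#'   `0 < min <= max < 1`.
#' @param value Constant frequency in `(0, 1)`.
#' @param shape1,shape2 Beta shape parameters.
#' @param floor Distance from 0 and 1 the law is bounded away by.
#' @return A function `n -> numeric(n)`.
#' @seealso [simulate_panel()]
#' @export
freq_uniform <- function(min = 0.05, max = 0.95) {
  stopifnot(min > 0, max < 1, min <= max)
  function(n) runif(n, min, max)
}

#' @rdname freq_uniform
#' @export
freq_constant <- function(value = 0.5) {
  check_fraction(value, "value")
  stopifnot(value > 0, value < 1)
  function(n) rep(value, n)
}

#' @rdname freq_uniform
#' @export
freq_beta <- function(shape1 = 0.8, shape2 = 0.8, floor = 0.05) {
  stopifnot(shape1 > 0, shape2 > 0, floor > 0, floor < 0.5)
  function(n) floor + (1 - 2 * floor) * stats::rbeta(n, shape1, shape2)
}

#' Simulate a SNP marker panel
#'
#' Generates a biallelic SNP panel of the kind used for genealogy-scale
#' genotyping: sites spread over the 22 autosomes in proportion to GRCh37
#' chromosome lengths, with population alternate-allele frequencies drawn
#' i.i.d. from `freq_law`. The panel is the sampling frame for genotype
#' simulation and for the mismatch-proportion null; real analyses would load
#' an equivalent table (e.g. a ~1.3 million-site array frame with reference
#' European frequencies) via [read_panel()].
#'
#' @param n_sites Number of sites to generate (>= 1).
#' @param freq_law A frequency law from [freq_uniform()] and friends, or any
#'   function `n -> numeric(n)` with values strictly inside (0, 1).
#' @param seed Optional integer seed; fixing it makes the panel reproducible.
#' @return A tibble with one row per site and columns `site_id`, `chrom`,
#'   `pos` (1-based), `ref`, `alt` (single distinct bases) and `alt_freq`.
#'   `(chrom, pos)` pairs are unique.
#' @export
#' @examples
#' simulate_panel(5, freq_constant(0.5), seed = 1)
simulate_panel <- function(n_sites, freq_law = freq_uniform(), seed = NULL) {
  n_sites <- check_count(n_sites, "n_sites")
  stopifnot(is.function(freq_law))
  with_seed_or_current(seed, {
    lens <- grch37_chrom_lengths() %>% filter(.data$chrom != "X")
    chrom_idx <- sample.int(
      nrow(lens), n_sites,
      replace = TRUE, prob = lens$length_bp
    )
    n_per <- tabulate(chrom_idx, nbins = nrow(lens))
    # positions unique within chromosome by construction
    pos_list <- lapply(seq_len(nrow(lens)), function(i) {
      if (n_per[i] == 0L) integer(0) else
        sort(sample.int(lens$length_bp[i], n_per[i]))
    })
    panel <- tibble(
      chrom = rep(lens$chrom, n_per),
      pos = unlist(pos_list)
    )
    ref <- sample(DNA_BASES, n_sites, replace = TRUE)
    alt_shift <- sample.int(3L, n_sites, replace = TRUE)
    alt <- DNA_BASES[(match(ref, DNA_BASES) - 1L + alt_shift) %% 4L + 1L]
    freqs <- freq_law(n_sites)
    if (any(freqs <= 0 | freqs >= 1)) {
      abort("`freq_law` produced frequencies outside (0, 1)")
    }
    panel %>%
      mutate(
        site_id = sprintf("snp%07d", row_number()),
        ref = ref, alt = alt, alt_freq = freqs
      ) %>%
      select("site_id", "chrom", "pos", "ref", "alt", "alt_freq")
  })
}

#' Read or write a SNP panel as TSV
#'
#' Tab-separated interchange format with header columns
#' `site_id, chrom, pos, ref, alt, alt_freq`.
#'
#' @param path File path.
#' @param panel A panel tibble as produced by [simulate_panel()].
#' @return `read_panel()` returns the panel tibble; `write_panel()` returns
#'   `panel` invisibly.
#' @export
read_panel <- function(path) {
  panel <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             chrom = readr::col_character(),
                             pos = readr::col_integer(),
                             alt_freq = readr::col_double()
                           ))
  check_columns(panel, c("site_id", "chrom", "pos", "ref", "alt", "alt_freq"),
                "panel")
  validate_panel(panel)
  panel
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  readr::write_tsv(panel, path)
  invisible(panel)
}

validate_panel <- function(panel) {
  check_columns(panel, c("site_id", "chrom", "pos", "ref", "alt", "alt_freq"),
                "panel")
  if (any(panel$alt_freq < 0 | panel$alt_freq > 1)) {
    abort("panel `alt_freq` must lie in [0, 1]")
  }
  if (any(panel$ref == panel$alt)) {
    abort("panel `ref` and `alt` alleles must differ at every site")
  }
  if (anyDuplicated(paste(panel$chrom, panel$pos))) {
    abort("panel (chrom, pos) pairs must be unique")
  }
  if (anyDuplicated(panel$site_id)) {
    abort("panel `site_id` values must be unique")
  }
  invisible(panel)
}
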