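#' Restrict observations to a SNP panel
#'
#' Drops observations at sites outside the marker panel — the first
#' reduction step of the sparse-SNP kinship workflow, which confines the
#' analysis to a genealogy-style marker frame with known population
#' frequencies. Duplicate observations at one site are retained for
#' downstream pseudo-haploid sampling.
#'
#' @param observations A tibble with a `site_id` column.
#' @param panel The SNP panel tibble.
#' @return The retained observations, with the retained-site count in the
#'   `"n_sites_retained"` attribute.
#' @export
reduce_to_panel <- function(observations, panel) {
  check_columns(observations, "site_id", "observations")
  validate_panel(panel)
  out <- observations %>% filter(.data$site_id %in% panel$site_id)
  attr(out, "n_sites_retained") <- length(unique(out$site_id))
  out
}

#' Force observations into a pseudo-haploid profile
#'
#' Collapses per-site observations to exactly one allele per site by a
#' uniform random choice among the observations at that site — the "forced
#' haploid" representation standard for very low-coverage data, where
#' diploid genotypes cannot be called and each site is represented by a
#' single sampled read.
#'
#' @param observations A tibble with columns `site_id` and `allele`
#'   (possibly several rows per site).
#' @param sample_id Optional label attached to the profile.
#' @param seed Optional integer seed.
#' @return A tibble of class `pseudo_haploid_profile` with columns
#'   `site_id`, `allele` (one row per site) and the `sample_id` attribute.
#' @export
pseudo_haploidize <- function(observations, sample_id = NULL, seed = NULL) {
  check_columns(observations, c("site_id", "allele"), "observations")
  with_seed_or_current(seed, {
    n <- nrow(observations)
    shuffled <- observations[sample.int(n, n), c("site_id", "allele")]
    out <- shuffled[!duplicated(shuffled$site_id), ]
    out <- out[order(out$site_id), ]
    out <- as_tibble(out)
    class(out) <- c("pseudo_haploid_profile", class(out))
    attr(out, "sample_id") <- sample_id
    out
  })
}

#' Allele mismatch proportion between two pseudo-haploid profiles
#'
#' Computes the fraction of sites, among those called in both profiles, at
#' which the two profiles carry different alleles. Its expectation falls
#' with relatedness (kinship coefficient), which is what makes it usable as
#' a relatedness statistic for sparse data. Symmetric in its arguments;
#' undefined (an error) when the profiles share no sites.
#'
#' @param profile_a,profile_b Pseudo-haploid profiles
#'   (see [pseudo_haploidize()]); any tibble with `site_id` and `allele`
#'   columns and one row per site works.
#' @return A list of class `mismatch_result` with `n_overlap`,
#'   `n_mismatch`, `proportion`.
#' @export
#' @examples
#' a <- tibble::tibble(site_id = letters[1:10], allele = rep("A", 10))
#' b <- tibble::tibble(site_id = letters[1:10],
#'                     allele = c(rep("A", 8), "C", "C"))
#' mismatch_proportion(a, b)$proportion # 0.2
mismatch_proportion <- function(profile_a, profile_b) {
  check_columns(profile_a, c("site_id", "allele"), "profile_a")
  check_columns(profile_b, c("site_id", "allele"), "profile_b")
  if (anyDuplicated(profile_a$site_id) || anyDuplicated(profile_b$site_id)) {
    abort("profiles must carry at most one allele per site")
  }
  joined <- inner_join(
    profile_a, profile_b,
    by = "site_id", suffix = c("_a", "_b")
  )
  if (nrow(joined) == 0L) {
    abort("profiles share no called sites; mismatch proportion is undefined")
  }
  n_mismatch <- sum(joined$allele_a != joined$allele_b)
  structure(
    list(
      n_overlap = nrow(joined),
      n_mismatch = n_mismatch,
      proportion = n_mismatch / nrow(joined)
    ),
    class = "mismatch_result"
  )
}

#' @export
print.mismatch_result <- function(x, ...) {
  cat(sprintf(
    "<mismatch_result> %d/%d mismatching sites (proportion %.4f)\n",
    x$n_mismatch, x$n_overlap, x$proportion
  ))
  invisible(x)
}

#' Closed-form expected mismatch proportion
#'
#' Analytic expectation of the pseudo-haploid mismatch proportion over a
#' panel, from the kinship-coefficient argument: sampling one allele from
#' each individual, the two draws are identical by descent with probability
#' equal to the kinship coefficient phi (1/2 same individual, 1/4
#' parent-child and full siblings, 0 unrelated), and non-IBD draws mismatch
#' with probability 2p(1-p) at a site of alternate frequency p. Hence the
#' per-site no-error mismatch probability is `(1 - phi_pair) * 2p(1-p)`
#' with `phi_pair = 2*phi` the probability the sampled pair is IBD:
#' `2p(1-p)` unrelated, `1.5 p(1-p)` parent-child and siblings, `p(1-p)`
#' same individual. A symmetric observation error `e` per sampled allele
#' transforms this to `m((1-e)^2 + e^2) + (1-m) * 2e(1-e)`. The function
#' returns the panel average — the independent oracle the Monte Carlo null
#' is validated against.
#'
#' @param panel SNP panel tibble (only `alt_freq` is used), or a bare
#'   numeric vector of alternate-allele frequencies.
#' @param relationship Relationship class.
#' @param error_rate Symmetric flip probability in `[0, 0.5)`.
#' @return The expected mismatch proportion (scalar).
#' @export
#' @examples
#' expected_mismatch_closed_form(rep(0.5, 10), "unrelated") # 0.5
#' expected_mismatch_closed_form(rep(0.5, 10), "same_individual") # 0.25
expected_mismatch_closed_form <- function(panel, relationship,
                                          error_rate = 0) {
  check_relationship(relationship)
  check_fraction(error_rate, "error_rate", 0, 0.5, hi_open = TRUE)
  p <- if (is.numeric(panel)) panel else {
    check_columns(panel, "alt_freq", "panel")
    panel$alt_freq
  }
  pq <- p * (1 - p)
  m <- switch(relationship,
    unrelated = 2 * pq,
    parent_child = 1.5 * pq,
    full_siblings = 1.5 * pq,
    same_individual = pq
  )
  e <- error_rate
  m_obs <- m * ((1 - e)^2 + e^2) + (1 - m) * 2 * e * (1 - e)
  mean(m_obs)
}
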