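RELATIONSHIP_CLASSES <- c(
  "same_individual", "parent_child", "full_siblings", "unrelated"
)

check_relationship <- function(relationship) {
  if (!is.character(relationship) || length(relationship) != 1L ||
      !relationship %in% RELATIONSHIP_CLASSES) {
    abort(sprintf(
      "`relationship` must be one of: %s",
      paste(RELATIONSHIP_CLASSES, collapse = ", ")
    ))
  }
  relationship
}

#' Simulate a pair of diploid genotypes under a relationship class
#'
#' Draws two diploid genotypes on every site of a SNP panel under
#' Hardy-Weinberg equilibrium at the panel's population alternate-allele
#' frequencies, with the dependence structure implied by the relationship:
#'
#' * `same_individual` — one founder genotype, duplicated;
#' * `parent_child` — the child receives one allele transmitted at random
#'   from the parent and one independent population draw;
#' * `full_siblings` — two children each receiving one random allele from
#'   each of two simulated founder parents (transmissions independent
#'   between siblings);
#' * `unrelated` — two independent founders.
#'
#' @param panel A SNP panel tibble (see [simulate_panel()]).
#' @param relationship One of `"same_individual"`, `"parent_child"`,
#'   `"full_siblings"`, `"unrelated"`.
#' @param seed Optional integer seed.
#' @return A tibble with columns `site_id`, allele columns `a1`, `a2`,
#'   `b1`, `b2` (bases drawn from the panel's ref/alt), and the
#'   `relationship`, carried as an attribute of the same name.
#' @export
#' @examples
#' p <- simulate_panel(4, freq_constant(0.5), seed = 1)
#' simulate_genotype_pair(p, "parent_child", seed = 2)
simulate_genotype_pair <- function(panel, relationship, seed = NULL) {
  validate_panel(panel)
  check_relationship(relationship)
  p <- panel$alt_freq
  n <- length(p)
  with_seed_or_current(seed, {
    draw_allele <- function() rbinom(n, 1L, p) # 1 = alt
    transmit <- function(g1, g2) ifelse(rbinom(n, 1L, 0.5) == 1L, g1, g2)
    a1 <- draw_allele(); a2 <- draw_allele()
    if (relationship == "same_individual") {
      b1 <- a1; b2 <- a2
    } else if (relationship == "unrelated") {
      b1 <- draw_allele(); b2 <- draw_allele()
    } else if (relationship == "parent_child") {
      b1 <- transmit(a1, a2)     # transmitted from parent A
      b2 <- draw_allele()        # from the unobserved other parent
    } else { # full_siblings: A and B are children of two founders
      m1 <- draw_allele(); m2 <- draw_allele()
      f1 <- draw_allele(); f2 <- draw_allele()
      a1 <- transmit(m1, m2); a2 <- transmit(f1, f2)
      b1 <- transmit(m1, m2); b2 <- transmit(f1, f2)
    }
    base_of <- function(x) ifelse(x == 1L, panel$alt, panel$ref)
    out <- tibble(
      site_id = panel$site_id,
      a1 = base_of(a1), a2 = base_of(a2),
      b1 = base_of(b1), b2 = base_of(b2)
    )
    attr(out, "relationship") <- relationship
    out
  })
}

#' Apply a symmetric biallelic observation error
#'
#' Flips each observed allele to the other allele of its site with
#' probability `error_rate`, independently per observation. This is the
#' simplistic error model used to absorb deamination, depurination, PCR,
#' sequencing and mapping error in degraded-sample data; rates above 2% are
#' rarely plausible and the model is undefined at or above 0.5.
#'
#' @param observations A tibble with columns `site_id` and `allele`.
#' @param panel The SNP panel supplying `ref`/`alt` per site.
#' @param error_rate Flip probability in `[0, 0.5)`.
#' @param seed Optional integer seed.
#' @return `observations` with `allele` perturbed.
#' @export
apply_observation_error <- function(observations, panel, error_rate,
                                    seed = NULL) {
  check_columns(observations, c("site_id", "allele"), "observations")
  check_fraction(error_rate, "error_rate", 0, 0.5, hi_open = TRUE)
  if (error_rate == 0) {
    return(observations)
  }
  idx <- match(observations$site_id, panel$site_id)
  if (anyNA(idx)) {
    abort("`observations` contain site_ids absent from `panel`")
  }
  with_seed_or_current(seed, {
    flip <- rbinom(nrow(observations), 1L, error_rate) == 1L
    other <- ifelse(observations$allele == panel$ref[idx],
                    panel$alt[idx], panel$ref[idx])
    observations$allele <- ifelse(flip, other, observations$allele)
    observations
  })
}

#' Simulate correlated sparse coverage masks for two samples
#'
#' Selects the panel sites covered by at least one read in each of two
#' low-coverage samples. At `overlap_correlation = 0` each sample's covered
#' set is a uniform draw without replacement, so the overlap count follows a
#' hypergeometric law with mean `n_covered_a * n_covered_b / n_sites`. With
#' positive correlation both samples share a latent per-site log-normal
#' "mappability" weight (sd `2 * overlap_correlation` on the log scale) and
#' sites are drawn by weighted sampling without replacement, inflating the
#' expected overlap monotonically — degraded-hair shotgun data show severalfold
#' more shared sites than independence predicts.
#'
#' @param panel A SNP panel tibble.
#' @param n_covered_a,n_covered_b Covered-site counts for the two samples.
#' @param overlap_correlation Correlation parameter in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return A list with character vectors `covered_a`, `covered_b` of
#'   `site_id`s, and `overlap` (their intersection).
#' @export
simulate_coverage_mask <- function(panel, n_covered_a, n_covered_b,
                                   overlap_correlation = 0, seed = NULL) {
  validate_panel(panel)
  n_covered_a <- check_count(n_covered_a, "n_covered_a", min = 0)
  n_covered_b <- check_count(n_covered_b, "n_covered_b", min = 0)
  check_fraction(overlap_correlation, "overlap_correlation")
  n <- nrow(panel)
  if (n_covered_a > n || n_covered_b > n) {
    abort("covered-site counts cannot exceed the panel size")
  }
  with_seed_or_current(seed, {
    if (overlap_correlation == 0) {
      ia <- sample.int(n, n_covered_a)
      ib <- sample.int(n, n_covered_b)
    } else {
      w <- exp(2 * overlap_correlation * rnorm(n))
      # exponential-race keys give weighted sampling without replacement
      ia <- order(rexp(n) / w)[seq_len(n_covered_a)]
      ib <- order(rexp(n) / w)[seq_len(n_covered_b)]
    }
    covered_a <- panel$site_id[sort(ia)]
    covered_b <- panel$site_id[sort(ib)]
    list(
      covered_a = covered_a,
      covered_b = covered_b,
      overlap = intersect(covered_a, covered_b)
    )
  })
}

#' Turn simulated genotypes into per-site read observations
#'
#' Restricts a genotype table to a covered-site set and emits `depth`
#' allele observations per covered site, each a uniform draw of one of the
#' sample's two alleles — the generative model of very low-coverage
#' sequencing where each read samples one chromosome at random.
#'
#' @param genotype_pair Output of [simulate_genotype_pair()].
#' @param sample One of `"a"`, `"b"` — which member of the pair to observe.
#' @param covered_sites Character vector of covered `site_id`s.
#' @param depth Observations per covered site (default 1, the sparse regime).
#' @param seed Optional integer seed.
#' @return A tibble with columns `site_id` and `allele`.
#' @export
observe_genotypes <- function(genotype_pair, sample = c("a", "b"),
                              covered_sites, depth = 1, seed = NULL) {
  sample <- match.arg(sample)
  depth <- check_count(depth, "depth")
  cols <- if (sample == "a") c("a1", "a2") else c("b1", "b2")
  check_columns(genotype_pair, c("site_id", cols), "genotype_pair")
  g <- genotype_pair %>% filter(.data$site_id %in% covered_sites)
  with_seed_or_current(seed, {
    idx <- rep(seq_len(nrow(g)), each = depth)
    pick <- rbinom(length(idx), 1L, 0.5) == 1L
    tibble(
      site_id = g$site_id[idx],
      allele = ifelse(pick, g[[cols[1]]][idx], g[[cols[2]]][idx])
    )
  })
}

#' Read or write per-sample allele observations as TSV
#'
#' Columns: `sample_id`, `site_id`, `allele`.
#'
#' @param path File path.
#' @param observations Observation tibble.
#' @return `read_observations()` returns the tibble; the writer returns its
#'   input invisibly.
#' @export
read_observations <- function(path) {
  obs <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(obs, c("sample_id", "site_id", "allele"), "observations")
  obs
}

#' @rdname read_observations
#' @export
write_observations <- function(observations, path) {
  check_columns(observations, c("sample_id", "site_id", "allele"),
                "observations")
  readr::write_tsv(observations, path)
  invisible(observations)
}
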