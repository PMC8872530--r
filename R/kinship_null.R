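# Vectorised replicate engine: S sites x n_rep replicates at dosage level.
# Per replicate, a genotype pair is drawn for the relationship, each member
# is pseudo-haploidised (one allele sampled uniformly, i.e. alt with
# probability dosage/2) and a symmetric flip error applied; the column mean
# of the disagreement indicator is the replicate's mismatch proportion.
# Identical in distribution to looping simulate_genotype_pair() +
# pseudo_haploidize(), but fast enough for 10^4-replicate grids.
sim_mismatch_replicates <- function(p, relationship, error_rate, n_rep) {
  S <- length(p)
  P <- rep(p, times = n_rep)
  n <- S * n_rep
  founder <- function() rbinom(n, 2L, P)
  pseudo <- function(g) rbinom(n, 1L, g / 2)
  flip <- function(a, e) if (e == 0) a else (a + rbinom(n, 1L, e)) %% 2L
  if (relationship == "same_individual") {
    g <- founder()
    a <- pseudo(g); b <- pseudo(g)
  } else if (relationship == "unrelated") {
    a <- pseudo(founder()); b <- pseudo(founder())
  } else if (relationship == "parent_child") {
    gp <- founder()
    child <- rbinom(n, 1L, gp / 2) + rbinom(n, 1L, P)
    a <- pseudo(gp); b <- pseudo(child)
  } else { # full_siblings
    gm <- founder(); gf <- founder()
    sib <- function() rbinom(n, 1L, gm / 2) + rbinom(n, 1L, gf / 2)
    a <- pseudo(sib()); b <- pseudo(sib())
  }
  a <- flip(a, error_rate); b <- flip(b, error_rate)
  colMeans(matrix(a != b, nrow = S, ncol = n_rep))
}

#' Simulate the mismatch-proportion null distributions
#'
#' Builds, by Monte Carlo, the distribution of the pseudo-haploid mismatch
#' proportion for each relationship class and each genotyping error rate,
#' conditioned on exactly the site set (with its allele frequencies) over
#' which the observed comparison was made. Each replicate draws a fresh
#' genotype pair under Hardy-Weinberg at the panel frequencies,
#' pseudo-haploidises both members, applies the symmetric observation
#' error, and records the mismatch proportion across the sites.
#'
#' @param panel_restriction SNP panel tibble restricted to the overlap-site
#'   set of the observed comparison (its `alt_freq` column drives the
#'   simulation).
#' @param relationships Character vector of relationship classes (default:
#'   all four).
#' @param error_grid Numeric vector of error rates in `[0, 0.5)`; the
#'   default `{0, 0.005, 0.01, 0.02}` spans the 0-2% range plausible for
#'   degraded samples.
#' @param n_replicates Replicates per (class, error) cell (default 10,000;
#'   at least 100).
#' @param seed Optional integer seed.
#' @return An object of class `mismatch_null`: a list with `summary`
#'   (tibble: `relationship`, `error_rate`, `mean`, `sd`, `lo`, `hi` — the
#'   central 95% replicate interval — and `n_replicates`), `replicates`
#'   (tibble: `relationship`, `error_rate`, `replicate`, `proportion`),
#'   `n_sites`, and the panel restriction's frequencies.
#' @export
simulate_mismatch_null <- function(panel_restriction,
                                   relationships = RELATIONSHIP_CLASSES,
                                   error_grid = c(0, 0.005, 0.01, 0.02),
                                   n_replicates = 10000, seed = NULL) {
  check_columns(panel_restriction, "alt_freq", "panel_restriction")
  if (nrow(panel_restriction) == 0L) {
    abort("`panel_restriction` is empty; the null is undefined")
  }
  relationships <- vapply(relationships, check_relationship, character(1))
  for (e in error_grid) check_fraction(e, "error_grid", 0, 0.5,
                                       hi_open = TRUE)
  n_replicates <- check_count(n_replicates, "n_replicates", min = 100)
  p <- panel_restriction$alt_freq
  grid <- tidyr::expand_grid(relationship = unname(relationships),
                             error_rate = error_grid)
  with_seed_or_current(seed, {
    replicates <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
      props <- sim_mismatch_replicates(
        p, grid$relationship[i], grid$error_rate[i], n_replicates
      )
      tibble(
        relationship = grid$relationship[i],
        error_rate = grid$error_rate[i],
        replicate = seq_len(n_replicates),
        proportion = props
      )
    })
    summary <- replicates %>%
      group_by(.data$relationship, .data$error_rate) %>%
      summarise(
        mean = mean(.data$proportion),
        sd = sd(.data$proportion),
        lo = unname(quantile(.data$proportion, 0.025)),
        hi = unname(quantile(.data$proportion, 0.975)),
        n_replicates = n(),
        .groups = "drop"
      )
    structure(
      list(
        summary = summary,
        replicates = replicates,
        n_sites = length(p),
        alt_freq = p
      ),
      class = "mismatch_null"
    )
  })
}

#' @export
print.mismatch_null <- function(x, ...) {
  cat(sprintf(
    "<mismatch_null> %d classes x %d error rates, %d replicates each, on %d sites\n",
    length(unique(x$summary$relationship)),
    length(unique(x$summary$error_rate)),
    x$summary$n_replicates[1], x$n_sites
  ))
  print(x$summary)
  invisible(x)
}

#' @rdname tidy_sparsekin
#' @export
tidy.mismatch_null <- function(x, ...) x$summary

#' @rdname tidy_sparsekin
#' @export
glance.mismatch_null <- function(x, ...) {
  tibble(
    n_sites = x$n_sites,
    n_cells = nrow(x$summary),
    n_replicates = x$summary$n_replicates[1]
  )
}

#' Classify the relationship of an observed profile pair
#'
#' Evaluates an observed mismatch proportion against the simulated null: a
#' relationship class is *compatible* at an error rate when the observation
#' lies inside that class's central 95% replicate interval. A verdict is
#' issued when exactly one class is compatible somewhere on the error grid
#' and no other class is compatible anywhere on it; otherwise the call is
#' inconclusive (either no class fits — the observation is outside all
#' simulated classes — or several do).
#'
#' @param observed A `mismatch_result` from [mismatch_proportion()].
#' @param null A `mismatch_null` built on the observed overlap-site set.
#' @return An object of class `relatedness_call`: a list with `observed`,
#'   `compatibility` (tibble: `relationship`, `error_rate`, `lo`, `hi`,
#'   `compatible`), `compatible_classes` and `verdict` (a relationship
#'   class, or an "inconclusive..." string).
#' @export
classify_relationship <- function(observed, null) {
  stopifnot(inherits(observed, "mismatch_result"),
            inherits(null, "mismatch_null"))
  if (observed$n_overlap != null$n_sites) {
    abort(sprintf(
      "null was built on %d sites but the observation covers %d; rebuild the null on the observed overlap set",
      null$n_sites, observed$n_overlap
    ))
  }
  compat <- null$summary %>%
    mutate(compatible = observed$proportion >= .data$lo &
             observed$proportion <= .data$hi) %>%
    select("relationship", "error_rate", "lo", "hi", "compatible")
  classes <- compat %>%
    filter(.data$compatible) %>%
    pull(.data$relationship) %>%
    unique()
  verdict <- if (length(classes) == 1L) {
    classes
  } else if (length(classes) == 0L) {
    "inconclusive - outside simulated classes"
  } else {
    "inconclusive - multiple classes compatible"
  }
  structure(
    list(
      observed = observed,
      compatibility = compat,
      compatible_classes = classes,
      verdict = verdict
    ),
    class = "relatedness_call"
  )
}

#' @export
print.relatedness_call <- function(x, ...) {
  cat(sprintf(
    "<relatedness_call> observed proportion %.4f over %d sites -> %s\n",
    x$observed$proportion, x$observed$n_overlap, x$verdict
  ))
  invisible(x)
}

#' @rdname tidy_sparsekin
#' @export
tidy.relatedness_call <- function(x, ...) x$compatibility

#' @rdname tidy_sparsekin
#' @export
glance.relatedness_call <- function(x, ...) {
  tibble(
    n_overlap = x$observed$n_overlap,
    proportion = x$observed$proportion,
    n_compatible_classes = length(x$compatible_classes),
    verdict = x$verdict
  )
}

#' Plots for sparsekin result objects
#'
#' `autoplot()` methods: for a `mismatch_null`, the null mismatch
#' distributions per relationship class across the error grid (optionally
#' with the observed proportion as a dashed line — the standard figure for
#' reading off which classes an observation is compatible with); for an
#' `mt_call_set`, coverage along the circular genome with heteroplasmic
#' positions marked; for an `rx_result`, the per-autosome ratios with the
#' sexing thresholds.
#'
#' @param object The result object.
#' @param observed Optional `mismatch_result` overlaid as a dashed line.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot_sparsekin
NULL

#' @rdname autoplot_sparsekin
#' @export
autoplot.mismatch_null <- function(object, observed = NULL, ...) {
  reps <- object$replicates %>%
    mutate(error_label = sprintf("error rate %.1f%%",
                                 100 * .data$error_rate))
  p <- ggplot2::ggplot(
    reps,
    ggplot2::aes(x = .data$proportion, fill = .data$relationship)
  ) +
    ggplot2::geom_histogram(bins = 60, alpha = 0.6,
                            position = "identity") +
    ggplot2::facet_wrap(ggplot2::vars(.data$error_label), ncol = 1) +
    ggplot2::labs(
      x = "pseudo-haploid mismatch proportion", y = "replicates",
      fill = "relationship",
      title = "Simulated mismatch-proportion null"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_vline(xintercept = observed$proportion,
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' broom-style accessors for sparsekin result objects
#'
#' `tidy()` returns the per-component table of a fitted/simulated object
#' (null summary rows, per-class compatibility, per-autosome ratios);
#' `glance()` returns a one-row summary.
#'
#' @param x The result object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_sparsekin
NULL
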