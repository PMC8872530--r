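CONFIG_KEYS <- list(
  top = c("seed", "panel", "kinship", "sexing", "mito"),
  panel = c("n_sites", "freq_min", "freq_max"),
  kinship = c("relationship", "n_covered_a", "n_covered_b",
              "overlap_correlation", "error_rate", "error_grid",
              "n_replicates"),
  sexing = c("sex", "total_reads"),
  mito = c("reference_length", "rotation_origin", "spacer_len",
           "depth_target", "mean_length_bp", "deamination_rate",
           "prop_low_mq", "dup_rate")
)

#' Default end-to-end run configuration
#'
#' A small fully synthetic configuration exercising every stage: a sparse
#' SNP panel with correlated two-sample coverage, a same-individual pair
#' observed at 1% genotyping error, a female chromosome-count table, and a
#' degraded mitochondrial read set (terminal deamination, some low-MQ reads
#' and PCR duplicates) carrying a 14-difference haplotype. Sized to run in
#' seconds; scale `panel$n_sites`, coverage and `kinship$n_replicates` up
#' for production-like runs.
#'
#' @param seed Master seed; every stage seed is derived from it.
#' @return A named list understood by [run_pipeline()].
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    panel = list(n_sites = 20000L, freq_min = 0.05, freq_max = 0.95),
    kinship = list(
      relationship = "same_individual",
      n_covered_a = 1500L, n_covered_b = 3000L,
      overlap_correlation = 0.55,
      error_rate = 0.01,
      error_grid = c(0, 0.005, 0.01, 0.02),
      n_replicates = 500L
    ),
    sexing = list(sex = "female", total_reads = 100000L),
    mito = list(
      reference_length = 16569L, rotation_origin = 8284L, spacer_len = 14L,
      depth_target = 60, mean_length_bp = 60,
      deamination_rate = 0.02, prop_low_mq = 0.05, dup_rate = 0.05
    )
  )
}

#' Validate a run configuration
#'
#' Rejects unknown keys at every level (typo safety), requires a master
#' `seed`, and checks each stage parameter's type and range. Returns the
#' config with integer-ish values normalised.
#'
#' @param config A configuration list (see [default_run_config()]).
#' @return The validated config, invisibly usable downstream.
#' @export
validate_run_config <- function(config) {
  stopifnot(is.list(config))
  check_keys <- function(x, allowed, where) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown) > 0L) {
      abort(sprintf("unknown %s key(s): %s", where,
                    paste(unknown, collapse = ", ")))
    }
  }
  check_keys(config, CONFIG_KEYS$top, "config")
  if (is.null(config$seed)) {
    abort("config must carry a master `seed` (every stochastic stage needs one)")
  }
  check_seed(config$seed)
  for (sect in c("panel", "kinship", "sexing", "mito")) {
    if (is.null(config[[sect]])) {
      abort(sprintf("config is missing the `%s` section", sect))
    }
    check_keys(config[[sect]], CONFIG_KEYS[[sect]], sect)
  }
  with(config$panel, {
    check_count(n_sites, "panel$n_sites")
    stopifnot(freq_min > 0, freq_max < 1, freq_min <= freq_max)
  })
  with(config$kinship, {
    check_relationship(relationship)
    check_count(n_covered_a, "kinship$n_covered_a")
    check_count(n_covered_b, "kinship$n_covered_b")
    check_fraction(overlap_correlation, "kinship$overlap_correlation")
    check_fraction(error_rate, "kinship$error_rate", 0, 0.5, hi_open = TRUE)
    check_count(n_replicates, "kinship$n_replicates", min = 100)
  })
  with(config$sexing, {
    stopifnot(sex %in% c("female", "male"))
    check_count(total_reads, "sexing$total_reads", min = 0)
  })
  with(config$mito, {
    check_count(reference_length, "mito$reference_length")
    check_count(rotation_origin, "mito$rotation_origin")
    stopifnot(depth_target > 0, mean_length_bp >= 1)
    check_fraction(deamination_rate, "mito$deamination_rate")
    check_fraction(prop_low_mq, "mito$prop_low_mq")
    check_fraction(dup_rate, "mito$dup_rate")
  })
  config
}

#' Read or write a run configuration as JSON
#'
#' The file representation round-trips losslessly through
#' `read_run_config(write_run_config(config, path))`.
#'
#' @param path JSON file path.
#' @param config A configuration list.
#' @return The config list (reader) or `path` invisibly (writer).
#' @export
read_run_config <- function(path) {
  config <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(config)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  validate_run_config(config)
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the full synthetic pipeline
#'
#' Executes every stage in dependency order from one validated
#' configuration, all randomness derived deterministically from the master
#' seed: (1) simulate the SNP panel, the related genotype pair, correlated
#' coverage and error-prone observations, then reduce, force-haploidise,
#' compute the observed mismatch proportion, simulate the null on the
#' overlap-site set and classify the relationship; (2) simulate sexed
#' chromosome counts and compute Rx with its assignment; (3) simulate
#' degraded circular mitochondrial reads from a 14-difference haplotype,
#' place them on the chimeric reference, lift back, filter on MQ,
#' deduplicate, call the consensus and express the haplotype as reference
#' differences. Regenerating with the same config reproduces identical
#' headline numbers.
#'
#' @param config Configuration list (see [default_run_config()]); validated
#'   before anything runs.
#' @return An object of class `run_report`: a list with `config`,
#'   `config_hash`, `seeds` (per-stage derived seeds) and headline results
#'   under `kinship`, `sexing`, `mito`.
#' @export
#' @examples
#' \donttest{
#' report <- run_pipeline(default_run_config(seed = 7))
#' report$kinship$verdict
#' }
run_pipeline <- function(config = default_run_config()) {
  config <- validate_run_config(config)
  seeds <- lapply(
    setNames(nm = c("panel", "pair", "mask", "obs", "null", "sexing",
                    "mito_ref", "mito_reads")),
    function(label) derive_seed(config$seed, label)
  )

  # --- kinship branch ---
  panel <- simulate_panel(
    config$panel$n_sites,
    freq_uniform(config$panel$freq_min, config$panel$freq_max),
    seed = seeds$panel
  )
  pair <- simulate_genotype_pair(panel, config$kinship$relationship,
                                 seed = seeds$pair)
  mask <- simulate_coverage_mask(
    panel, config$kinship$n_covered_a, config$kinship$n_covered_b,
    config$kinship$overlap_correlation, seed = seeds$mask
  )
  obs_a <- observe_genotypes(pair, "a", mask$covered_a,
                             seed = derive_seed(seeds$obs, "a")) %>%
    apply_observation_error(panel, config$kinship$error_rate,
                            seed = derive_seed(seeds$obs, "ea"))
  obs_b <- observe_genotypes(pair, "b", mask$covered_b,
                             seed = derive_seed(seeds$obs, "b")) %>%
    apply_observation_error(panel, config$kinship$error_rate,
                            seed = derive_seed(seeds$obs, "eb"))
  prof_a <- pseudo_haploidize(reduce_to_panel(obs_a, panel), "sample_a",
                              seed = derive_seed(seeds$obs, "pa"))
  prof_b <- pseudo_haploidize(reduce_to_panel(obs_b, panel), "sample_b",
                              seed = derive_seed(seeds$obs, "pb"))
  observed <- mismatch_proportion(prof_a, prof_b)
  restriction <- panel %>%
    filter(.data$site_id %in% intersect(prof_a$site_id, prof_b$site_id))
  null <- simulate_mismatch_null(
    restriction,
    error_grid = config$kinship$error_grid,
    n_replicates = config$kinship$n_replicates,
    seed = seeds$null
  )
  call <- classify_relationship(observed, null)

  # --- sexing branch ---
  counts <- simulate_chromosome_counts(config$sexing$sex,
                                       config$sexing$total_reads,
                                       seed = seeds$sexing)
  rx <- compute_rx(counts)

  # --- mitochondrial branch ---
  m <- config$mito
  reference <- synthetic_rcrs(m$reference_length, seed = seeds$mito_ref)
  chim <- build_chimeric_reference(reference, m$rotation_origin,
                                   m$spacer_len)
  haplotype <- locket_like_haplotype(reference)
  read_set <- simulate_mt_reads(
    reference, haplotype,
    depth_target = m$depth_target,
    length_law = length_lognormal(m$mean_length_bp),
    deamination_rate = m$deamination_rate,
    prop_low_mq = m$prop_low_mq,
    dup_rate = m$dup_rate,
    seed = seeds$mito_reads
  )
  placements <- place_on_chimeric(read_set, chim)
  lifted <- liftover_to_rcrs(placements, chim)
  lifted <- filter_placements(lifted)
  lifted <- deduplicate_placements(lifted)
  callset <- pileup_and_call(lifted, reference)
  diffs <- haplotype_diff(callset)
  stats <- depth_length_stats(callset, lifted)

  report <- structure(
    list(
      config = config,
      config_hash = rlang::hash(config),
      seeds = seeds,
      kinship = list(
        n_covered_a = length(mask$covered_a),
        n_covered_b = length(mask$covered_b),
        n_overlap = observed$n_overlap,
        n_mismatch = observed$n_mismatch,
        proportion = observed$proportion,
        verdict = call$verdict,
        call = call,
        null_summary = null$summary
      ),
      sexing = list(
        rx = rx$rx, sd = rx$sd, ci_low = rx$ci_low, ci_high = rx$ci_high,
        assignment = rx$assignment, result = rx
      ),
      mito = list(
        n_reads_simulated = nrow(read_set$reads),
        n_spacer_rejected = nrow(attr(lifted, "rejected")),
        n_mq_filtered = attr(lifted, "n_mq_filtered"),
        n_duplicates_removed = attr(lifted, "n_duplicates_removed"),
        n_retained = nrow(lifted),
        profile = diffs$notation,
        simulated_profile = haplotype_notation(haplotype),
        profile_recovered = identical(diffs$notation,
                                      haplotype_notation(haplotype)),
        depth_mean = stats$depth_mean,
        mean_length = stats$mean_length,
        callset = callset,
        stats = stats
      )
    ),
    class = "run_report"
  )
  report
}

# notation of a simulated haplotype spec, for truth comparison
haplotype_notation <- function(diffs) {
  diffs <- diffs %>% arrange(.data$pos, !is.na(.data$rank), .data$rank)
  ifelse(diffs$type == "ins",
         sprintf("%d.%d%s", diffs$pos, diffs$rank, diffs$base),
         paste0(diffs$pos, diffs$base))
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>", substr(x$config_hash, 1, 12), "\n")
  cat(sprintf(
    "  kinship: %d overlap sites, mismatch %.4f -> %s\n",
    x$kinship$n_overlap, x$kinship$proportion, x$kinship$verdict
  ))
  cat(sprintf(
    "  sexing:  Rx %.3f (CI %.3f-%.3f) -> %s\n",
    x$sexing$rx, x$sexing$ci_low, x$sexing$ci_high, x$sexing$assignment
  ))
  cat(sprintf(
    "  mito:    %d/%d placements retained, depth %.1fx, profile %s (%d diffs)\n",
    x$mito$n_retained, x$mito$n_reads_simulated, x$mito$depth_mean,
    if (x$mito$profile_recovered) "recovered exactly" else "NOT recovered",
    length(x$mito$profile)
  ))
  invisible(x)
}

#' Write the headline numbers of a run report as JSON
#'
#' Serialises the scalar headline results (not the embedded result
#' objects); byte-identical across reruns of the same config.
#'
#' @param report A `run_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  headline <- list(
    config_hash = report$config_hash,
    kinship = report$kinship[c("n_covered_a", "n_covered_b", "n_overlap",
                               "n_mismatch", "proportion", "verdict")],
    sexing = report$sexing[c("rx", "sd", "ci_low", "ci_high", "assignment")],
    mito = report$mito[c("n_reads_simulated", "n_spacer_rejected",
                         "n_mq_filtered", "n_duplicates_removed",
                         "n_retained", "profile", "profile_recovered",
                         "depth_mean", "mean_length")]
  )
  jsonlite::write_json(headline, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
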