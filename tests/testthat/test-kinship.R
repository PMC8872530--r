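test_that("reduce_to_panel keeps exactly the on-panel observations", {
  panel <- fixed_freq_panel(rep(0.5, 10))
  obs <- tibble::tibble(
    site_id = c(panel$site_id[1:7], "off1", "off2", "off3"),
    allele = "A"
  )
  red <- reduce_to_panel(obs, panel)
  expect_equal(nrow(red), 7)
  expect_equal(attr(red, "n_sites_retained"), 7)

  none <- reduce_to_panel(tibble::tibble(site_id = "zzz", allele = "A"),
                          panel)
  expect_equal(nrow(none), 0)

  # duplicates at one site survive reduction (collapsed only later)
  dup <- reduce_to_panel(
    tibble::tibble(site_id = rep(panel$site_id[1], 3), allele = "A"), panel
  )
  expect_equal(nrow(dup), 3)
})

test_that("filter_reads_for_snps applies strict-length and MQ thresholds", {
  reads <- tibble::tibble(
    length = c(35, 36, 50, 36, 100),
    mq = c(60, 29, 30, 30, NA)
  )
  expect_error(filter_reads_for_snps(reads), "complete")
  kept <- filter_reads_for_snps(reads[1:4, ])
  # 35 bp dropped even at MQ 60; MQ 29 dropped even at 36 bp; MQ 30 kept
  expect_equal(nrow(kept), 2)
  expect_true(all(kept$length > 35 & kept$mq >= 30))
  expect_error(filter_reads_for_snps(tibble::tibble(length = 40)), "mq")
})

test_that("pseudo_haploidize picks one observation per site uniformly", {
  single <- tibble::tibble(site_id = c("a", "b"), allele = c("A", "G"))
  expect_equal(pseudo_haploidize(single, seed = 1)$allele, c("A", "G"))

  hom <- tibble::tibble(site_id = rep("a", 2), allele = c("C", "C"))
  expect_equal(pseudo_haploidize(hom, seed = 2)$allele, "C")

  het <- tibble::tibble(site_id = rep("a", 2), allele = c("A", "G"))
  picks <- vapply(1:400, function(s) {
    pseudo_haploidize(het, seed = s)$allele
  }, character(1))
  frac_a <- mean(picks == "A")
  expect_lt(abs(frac_a - 0.5), 3 * sqrt(0.25 / 400))

  expect_identical(pseudo_haploidize(het, seed = 5),
                   pseudo_haploidize(het, seed = 5))
})

test_that("mismatch_proportion counts over the site intersection", {
  a <- make_profile(sprintf("s%04d", 1:1196), rep("A", 1196))
  expect_equal(mismatch_proportion(a, a)$proportion, 0)

  b10 <- make_profile(sprintf("s%02d", 1:10),
                      c(rep("A", 8), "G", "G"))
  a10 <- make_profile(sprintf("s%02d", 1:10), rep("A", 10))
  res <- mismatch_proportion(a10, b10)
  expect_equal(res$proportion, 0.2)
  expect_equal(res$n_overlap, 10)

  # symmetry and invariance to site ordering
  flipped <- mismatch_proportion(b10, a10)
  expect_equal(flipped$proportion, res$proportion)
  shuffled <- b10[sample(10), ]
  expect_equal(mismatch_proportion(a10, shuffled)$proportion, 0.2)

  disjoint <- make_profile("other", "A")
  expect_error(mismatch_proportion(a10, disjoint), "undefined")
  expect_error(
    mismatch_proportion(a10, make_profile(c("s01", "s01"), c("A", "G"))),
    "one allele"
  )
})

test_that("closed-form expected mismatch matches the enumeration oracle", {
  for (p in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    for (rel in c("same_individual", "parent_child", "full_siblings",
                  "unrelated")) {
      for (e in c(0, 0.01, 0.1)) {
        expect_equal(
          expected_mismatch_closed_form(p, rel, e),
          enum_mismatch_prob(p, rel, e),
          tolerance = 1e-12,
          info = sprintf("p=%.1f %s e=%.2f", p, rel, e)
        )
      }
    }
  }
  # frozen values from the oracle at p = 0.5, e = 0
  expect_equal(expected_mismatch_closed_form(0.5, "unrelated"), 0.5)
  expect_equal(expected_mismatch_closed_form(0.5, "same_individual"), 0.25)
  expect_equal(expected_mismatch_closed_form(0.5, "parent_child"), 0.375)
  # monomorphic panel: no mismatches possible without error
  expect_equal(expected_mismatch_closed_form(c(0, 1, 0), "unrelated"), 0)
  expect_error(expected_mismatch_closed_form(0.5, "same_individual", 0.5),
               "error_rate")
})

test_that("Monte Carlo null agrees with the closed form and is ordered", {
  p <- c(rep(0.2, 120), rep(0.5, 120), rep(0.8, 60))
  panel <- fixed_freq_panel(p)
  null <- simulate_mismatch_null(panel, error_grid = c(0, 0.02),
                                 n_replicates = 400, seed = 42)
  s <- null$summary
  for (i in seq_len(nrow(s))) {
    expected <- expected_mismatch_closed_form(p, s$relationship[i],
                                              s$error_rate[i])
    se <- s$sd[i] / sqrt(s$n_replicates[i])
    expect_lt(abs(s$mean[i] - expected), 3 * se,
              label = sprintf("%s e=%.3f |MC-closed|",
                              s$relationship[i], s$error_rate[i]))
  }

  m <- function(rel, e) s$mean[s$relationship == rel & s$error_rate == e]
  # relatedness ordering at each error rate; pc and siblings share a mean
  for (e in c(0, 0.02)) {
    expect_lt(m("same_individual", e), m("parent_child", e))
    expect_lt(m("parent_child", e), m("unrelated", e) + 1e-12)
    expect_lt(m("full_siblings", e), m("unrelated", e))
  }
  # monotone in error rate for every class
  for (rel in unique(s$relationship)) {
    expect_lt(m(rel, 0), m(rel, 0.02))
  }

  expect_identical(
    simulate_mismatch_null(panel, error_grid = 0, n_replicates = 150,
                           seed = 9)$summary,
    simulate_mismatch_null(panel, error_grid = 0, n_replicates = 150,
                           seed = 9)$summary
  )
  expect_error(simulate_mismatch_null(panel[0, ]), "empty")
  expect_error(simulate_mismatch_null(panel, n_replicates = 50), "100")
})

test_that("low-heterozygosity same-individual replicates are near zero", {
  panel <- fixed_freq_panel(rep(1e-4, 50))
  null <- simulate_mismatch_null(panel, relationships = "same_individual",
                                 error_grid = 0, n_replicates = 150,
                                 seed = 3)
  expect_lt(max(null$replicates$proportion), 0.05)
})

test_that("classification follows 95% interval membership", {
  p <- rep(0.5, 500)
  panel <- fixed_freq_panel(p)
  null <- simulate_mismatch_null(panel, n_replicates = 500, seed = 21)

  # an observation at the unrelated expectation is classified unrelated
  obs <- structure(
    list(n_overlap = 500L, n_mismatch = 250L, proportion = 0.5),
    class = "mismatch_result"
  )
  call <- classify_relationship(obs, null)
  expect_equal(call$verdict, "unrelated")
  expect_equal(call$compatible_classes, "unrelated")

  # far outside every class: inconclusive, never a forced call
  out <- structure(
    list(n_overlap = 500L, n_mismatch = 0L, proportion = 0),
    class = "mismatch_result"
  )
  expect_match(classify_relationship(out, null)$verdict, "inconclusive")

  # null built on a different site count is rejected
  wrong <- structure(
    list(n_overlap = 400L, n_mismatch = 100L, proportion = 0.25),
    class = "mismatch_result"
  )
  expect_error(classify_relationship(wrong, null), "rebuild")

  expect_equal(nrow(tidy(call)), nrow(null$summary))
  expect_equal(glance(call)$verdict, "unrelated")
  expect_s3_class(autoplot(null, observed = obs), "ggplot")
})
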