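# Independent oracles and small fixture builders used across test files.

# Exact per-site pseudo-haploid mismatch probability by enumeration over the
# joint genotype distribution and single-allele draws. Independent of the
# package's closed form: builds the (dosage_a, dosage_b) joint law for each
# relationship from Mendelian transmission and Hardy-Weinberg founders, then
# sums P(observed alleles differ) over it.
enum_mismatch_prob <- function(p, relationship, e = 0) {
  hwe <- c((1 - p)^2, 2 * p * (1 - p), p^2) # alt dosage 0,1,2
  t_alt <- c(0, 0.5, 1)                     # P(transmit alt | dosage)
  J <- matrix(0, 3, 3)
  if (relationship == "same_individual") {
    diag(J) <- hwe
  } else if (relationship == "unrelated") {
    J <- outer(hwe, hwe)
  } else if (relationship == "parent_child") {
    for (g in 0:2) for (t in 0:1) for (o in 0:1) {
      pt <- if (t == 1) t_alt[g + 1] else 1 - t_alt[g + 1]
      po <- if (o == 1) p else 1 - p
      J[g + 1, t + o + 1] <- J[g + 1, t + o + 1] + hwe[g + 1] * pt * po
    }
  } else { # full_siblings
    for (gm in 0:2) for (gf in 0:2) {
      cd <- rep(0, 3) # child dosage law given both parents
      for (tm in 0:1) for (tf in 0:1) {
        ptm <- if (tm == 1) t_alt[gm + 1] else 1 - t_alt[gm + 1]
        ptf <- if (tf == 1) t_alt[gf + 1] else 1 - t_alt[gf + 1]
        cd[tm + tf + 1] <- cd[tm + tf + 1] + ptm * ptf
      }
      J <- J + hwe[gm + 1] * hwe[gf + 1] * outer(cd, cd)
    }
  }
  s_alt <- c(0, 0.5, 1)                      # P(sample alt | dosage)
  obs_alt <- s_alt * (1 - e) + (1 - s_alt) * e # after symmetric flip
  mm <- outer(obs_alt, 1 - obs_alt) + outer(1 - obs_alt, obs_alt)
  sum(J * mm)
}

# P(two unrelated HWE genotypes share >= 1 allele identical by state),
# by enumeration: complement of the two disjoint homozygote pairings.
enum_ibs_share_prob <- function(p) {
  1 - 2 * p^2 * (1 - p)^2
}

# A panel with externally fixed frequencies, bypassing the frequency law.
fixed_freq_panel <- function(p) {
  n <- length(p)
  tibble::tibble(
    site_id = sprintf("s%05d", seq_len(n)),
    chrom = "1",
    pos = seq_len(n),
    ref = "A",
    alt = "G",
    alt_freq = p
  )
}

# A pseudo-haploid profile from bare vectors.
make_profile <- function(site_id, allele) {
  out <- tibble::tibble(site_id = site_id, allele = allele)
  class(out) <- c("pseudo_haploid_profile", class(out))
  out
}

# Manual lifted-placement table for pileup tests: each element of `reads`
# is list(start, seq, mq); insertion annotations optional.
make_lifted <- function(reads, circle_length, insertions = NULL) {
  out <- tibble::tibble(
    read_id = sprintf("r%03d", seq_along(reads)),
    rcrs_start = vapply(reads, function(r) as.integer(r$start), integer(1)),
    length = vapply(reads, function(r) nchar(r$seq), integer(1)),
    mq = vapply(reads, function(r) as.integer(r$mq %||% 60L), integer(1)),
    sequence = vapply(reads, function(r) r$seq, character(1))
  )
  out$rcrs_end <- ((out$rcrs_start + out$length - 2L) %% circle_length) + 1L
  attr(out, "circle_length") <- circle_length
  if (!is.null(insertions)) attr(out, "insertions") <- insertions
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
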