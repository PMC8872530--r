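RCRS_LENGTH <- 16569L

#' Synthetic circular mitochondrial reference
#'
#' Generates a random circular DNA sequence of the canonical human
#' mitochondrial genome length (16,569 bp by default). It is a *synthetic*
#' stand-in: coordinate arithmetic, liftover and variant notation depend only
#' on length and the supplied haplotype differences, never on the true rCRS
#' bases, so all desk-scale validation can run without shipping the
#' reference sequence itself.
#'
#' @param length Circle length in bp (default 16,569).
#' @param seed Optional integer seed.
#' @return A single character string of A/C/G/T bases.
#' @export
synthetic_rcrs <- function(length = RCRS_LENGTH, seed = NULL) {
  length <- check_count(length, "length")
  with_seed_or_current(seed, {
    paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
  })
}

#' Fragment-length laws for degraded-DNA read simulation
#'
#' `length_lognormal()` returns a sampling function for read lengths with
#' the heavy-tailed, short-fragment profile typical of aged samples
#' (log-normal, rounded to integer bp, floored at `min_bp`). Mean mtDNA
#' fragment lengths observed in century-old hair shafts range roughly from
#' 38 to 93 bp depending on library; `mean_bp = 60` is a representative
#' default. `length_constant()` is the degenerate law for analytic checks.
#'
#' @param mean_bp Target mean length in bp.
#' @param cv Coefficient of variation of the log-normal (default 0.3).
#' @param min_bp Minimum emitted length.
#' @return A function `n -> integer(n)` carrying its nominal mean in the
#'   `"mean_bp"` attribute.
#' @export
length_lognormal <- function(mean_bp = 60, cv = 0.3, min_bp = 18) {
  stopifnot(mean_bp >= 1, cv > 0, min_bp >= 1)
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean_bp) - sdlog^2 / 2
  law <- function(n) pmax(as.integer(min_bp),
                          as.integer(round(rlnorm(n, meanlog, sdlog))))
  attr(law, "mean_bp") <- mean_bp
  law
}

#' @rdname length_lognormal
#' @export
length_constant <- function(mean_bp = 60) {
  mean_bp <- check_count(mean_bp, "mean_bp")
  law <- function(n) rep(mean_bp, n)
  attr(law, "mean_bp") <- mean_bp
  law
}

#' Specify a mitochondrial haplotype as differences from the reference
#'
#' A haplotype is a tibble of differences with columns `pos` (1-based
#' reference coordinate; the anchor position for insertions), `type`
#' (`"sub"` or `"ins"`), `rank` (insertion rank after the anchor, `NA` for
#' substitutions) and `base` (the substituted or inserted base).
#'
#' `haplotype_spec()` validates such a table against a reference.
#' `locket_like_haplotype()` builds a 14-difference haplotype with the
#' structure of a typical full-mitogenome forensic profile: eleven
#' substitutions plus a control-region single-base insertion and a
#' dinucleotide insertion (anchor ranks 1 and 2).
#'
#' @param diffs A difference tibble.
#' @param reference Circular reference sequence (character string).
#' @return The validated difference tibble.
#' @export
haplotype_spec <- function(diffs, reference) {
  check_columns(diffs, c("pos", "type", "rank", "base"), "diffs")
  L <- nchar(reference)
  if (any(diffs$pos < 1 | diffs$pos > L)) {
    abort("haplotype difference positions must lie in 1..reference length")
  }
  if (!all(diffs$type %in% c("sub", "ins"))) {
    abort("haplotype difference `type` must be 'sub' or 'ins'")
  }
  if (!all(diffs$base %in% DNA_BASES)) {
    abort("haplotype difference `base` must be a single A/C/G/T base")
  }
  subs <- diffs[diffs$type == "sub", ]
  if (nrow(subs) > 0) {
    ref_at <- substring(reference, subs$pos, subs$pos)
    if (any(ref_at == subs$base)) {
      abort("substitution base equals the reference base at some position")
    }
  }
  diffs
}

#' @rdname haplotype_spec
#' @export
locket_like_haplotype <- function(reference) {
  sub_pos <- c(263L, 750L, 1438L, 3010L, 4137L, 4769L, 8860L,
               15326L, 16111L, 16357L, 16519L)
  sub_base <- c("G", "G", "G", "A", "T", "G", "G", "G", "T", "C", "C")
  ref_at <- substring(reference, sub_pos, sub_pos)
  # keep the canonical profile base unless the synthetic reference happens
  # to carry it already, in which case rotate to the next base
  clash <- ref_at == sub_base
  sub_base[clash] <- DNA_BASES[match(ref_at[clash], DNA_BASES) %% 4L + 1L]
  diffs <- dplyr::bind_rows(
    tibble(pos = sub_pos, type = "sub", rank = NA_integer_, base = sub_base),
    tibble(pos = c(315L, 524L, 524L), type = "ins",
           rank = c(1L, 1L, 2L), base = c("C", "A", "C"))
  ) %>% arrange(.data$pos, .data$rank)
  haplotype_spec(diffs, reference)
}

#' Simulate reads from a circular mitochondrial genome
#'
#' Emits a degraded-DNA read set from a circular reference carrying a given
#' haplotype. Read start positions are uniform on the circle, so fragments
#' spanning the origin (position L back to 1) arise naturally; lengths are
#' drawn from `length_law`; each terminal base that is a C is rendered T
#' with probability `deamination_rate`, mimicking end-concentrated
#' hydrolytic deamination damage. An optional fraction of reads receives a
#' low mapping quality and an optional duplication rate appends PCR-style
#' exact copies, so that downstream filtering and deduplication are
#' exercisable.
#'
#' Read sequences are stored reference-aligned: `sequence` has exactly
#' `length` bases covering the footprint, and inserted bases (from `ins`
#' haplotype differences whose anchor and successor both fall inside the
#' footprint) are carried in a separate per-read annotation table, as a
#' CIGAR would carry them after alignment.
#'
#' @param reference Circular reference sequence (character string).
#' @param haplotype_diffs Difference tibble (see [haplotype_spec()]) or
#'   `NULL` for the reference haplotype.
#' @param depth_target Mean per-position depth to aim for (> 0).
#' @param length_law Fragment-length law (see [length_lognormal()]).
#' @param deamination_rate Per-terminal-base C-to-T probability in `[0, 1]`.
#' @param prop_low_mq Fraction of reads given mapping quality below 30.
#' @param dup_rate Expected fraction of additional duplicate reads.
#' @param seed Optional integer seed.
#' @return A list of class `mt_read_set` with elements `reads` (tibble:
#'   `read_id`, `start_rcrs`, `length`, `mq`, `origin_spanning`,
#'   `sequence`), `insertions` (tibble: `read_id`, `anchor`, `rank`,
#'   `base`), `reference_length`, `haplotype_diffs`.
#' @export
simulate_mt_reads <- function(reference, haplotype_diffs = NULL,
                              depth_target = 60,
                              length_law = length_lognormal(60),
                              deamination_rate = 0,
                              prop_low_mq = 0, dup_rate = 0, seed = NULL) {
  stopifnot(is.character(reference), length(reference) == 1L)
  if (!(is.numeric(depth_target) && depth_target > 0)) {
    abort("`depth_target` must be positive")
  }
  check_fraction(deamination_rate, "deamination_rate")
  check_fraction(prop_low_mq, "prop_low_mq")
  check_fraction(dup_rate, "dup_rate")
  L <- nchar(reference)
  if (is.null(haplotype_diffs)) {
    haplotype_diffs <- tibble(pos = integer(), type = character(),
                              rank = integer(), base = character())
  } else {
    haplotype_diffs <- haplotype_spec(haplotype_diffs, reference)
  }
  with_seed_or_current(seed, {
    sample_bases <- strsplit(reference, "", fixed = TRUE)[[1]]
    subs <- haplotype_diffs[haplotype_diffs$type == "sub", ]
    sample_bases[subs$pos] <- subs$base
    ins <- haplotype_diffs[haplotype_diffs$type == "ins", ]

    mean_bp <- attr(length_law, "mean_bp") %||% mean(length_law(10000L))
    n_reads <- max(1L, as.integer(round(depth_target * L / mean_bp)))
    starts <- sample.int(L, n_reads, replace = TRUE)
    lens <- length_law(n_reads)
    if (any(lens < 1L)) abort("`length_law` produced lengths < 1")
    lens <- pmin(lens, L) # a fragment cannot exceed the circle

    # reference-aligned sequences via the doubled-sequence trick
    doubled <- c(sample_bases, sample_bases)
    seqs <- substring(paste(doubled, collapse = ""), starts,
                      starts + lens - 1L)

    if (deamination_rate > 0) {
      first <- substring(seqs, 1L, 1L)
      hit <- first == "C" & runif(n_reads) < deamination_rate
      substring(seqs[hit], 1L, 1L) <- "T"
      last <- substring(seqs, lens, lens)
      hit2 <- last == "C" & runif(n_reads) < deamination_rate
      if (any(hit2)) {
        idx <- which(hit2)
        seqs[idx] <- paste0(substring(seqs[idx], 1L, lens[idx] - 1L), "T")
      }
    }

    mq <- rep(60L, n_reads)
    if (prop_low_mq > 0) {
      low <- runif(n_reads) < prop_low_mq
      mq[low] <- sample(0:29, sum(low), replace = TRUE)
    }

    reads <- tibble(
      read_id = sprintf("read%06d", seq_len(n_reads)),
      start_rcrs = starts,
      length = lens,
      mq = mq,
      origin_spanning = starts + lens - 1L > L,
      sequence = seqs
    )

    # per-read insertion annotations: anchor and its successor inside footprint
    ins_tab <- tibble(read_id = character(), anchor = integer(),
                      rank = integer(), base = character())
    if (nrow(ins) > 0) {
      per_read <- purrr::map_dfr(seq_len(nrow(ins)), function(i) {
        anchor <- ins$pos[i]
        # offset of anchor within the read footprint, modulo the circle
        off <- (anchor - reads$start_rcrs) %% L
        holds <- off < reads$length - 1L # successor also inside
        tibble(read_id = reads$read_id[holds], anchor = anchor,
               rank = ins$rank[i], base = ins$base[i])
      })
      ins_tab <- per_read %>% arrange(.data$read_id, .data$anchor, .data$rank)
    }

    if (dup_rate > 0 && n_reads > 0) {
      n_dup <- stats::rpois(1L, dup_rate * n_reads)
      if (n_dup > 0) {
        src <- sample.int(n_reads, n_dup, replace = TRUE)
        dup_reads <- reads[src, ]
        dup_reads$read_id <- sprintf("dup%06d", seq_len(n_dup))
        dup_ins <- ins_tab %>%
          inner_join(tibble(read_id = reads$read_id[src],
                            new_id = dup_reads$read_id),
                     by = "read_id", relationship = "many-to-many") %>%
          mutate(read_id = .data$new_id) %>%
          select("read_id", "anchor", "rank", "base")
        reads <- bind_rows(reads, dup_reads)
        ins_tab <- bind_rows(ins_tab, dup_ins)
      }
    }

    structure(
      list(reads = reads, insertions = ins_tab, reference_length = L,
           haplotype_diffs = haplotype_diffs),
      class = "mt_read_set"
    )
  })
}

#' @export
print.mt_read_set <- function(x, ...) {
  cat(sprintf(
    "<mt_read_set> %d reads on a %d bp circle (%d origin-spanning, %d with insertions)\n",
    nrow(x$reads), x$reference_length,
    sum(x$reads$origin_spanning), length(unique(x$insertions$read_id))
  ))
  invisible(x)
}

#' Write simulated mitochondrial reads to FASTA plus a placement TSV
#'
#' The FASTA holds the (reference-aligned) read sequences; the TSV holds the
#' placement table (`read_id`, `start_rcrs`, `length`, `mq`,
#' `origin_spanning`).
#'
#' @param read_set An `mt_read_set` from [simulate_mt_reads()].
#' @param fasta_path,tsv_path Output paths.
#' @return `read_set`, invisibly.
#' @export
write_mt_reads <- function(read_set, fasta_path, tsv_path) {
  stopifnot(inherits(read_set, "mt_read_set"))
  seqs <- Biostrings::DNAStringSet(read_set$reads$sequence)
  names(seqs) <- read_set$reads$read_id
  Biostrings::writeXStringSet(seqs, fasta_path)
  readr::write_tsv(
    read_set$reads %>% select(-"sequence"), tsv_path
  )
  invisible(read_set)
}
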