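#' Consensus call for one position from base counts
#'
#' Applies the point-heteroplasmy rule used throughout the mitochondrial
#' caller: the consensus is the major base; any further base whose count is
#' at least `het_min_reads` and whose fraction of the depth is at least
#' `het_min_fraction` joins it in an IUPAC mixed call. The thresholds
#' (defaults 10% and 2 reads) are chosen so that a 24% minor allele (57 T /
#' 18 C) is reported as a mixed `Y` while a 1.9% minor allele (53 C / 1 T,
#' plausibly terminal deamination) collapses to a homoplasmic call.
#'
#' @param counts Named numeric vector of base counts over `A`, `C`, `G`,
#'   `T` (missing names count as zero).
#' @param het_min_fraction Minimum minor-allele fraction for a mixed call.
#' @param het_min_reads Minimum minor-allele read count for a mixed call.
#' @return A list with `call` (single base, IUPAC code, or `NA` at zero
#'   depth), `depth`, `major_base`, `major_fraction`, `heteroplasmic`.
#' @export
#' @examples
#' call_position(c(T = 57, C = 18)) # mixed: Y, major fraction 0.76
#' call_position(c(C = 53, T = 1))  # homoplasmic C
call_position <- function(counts, het_min_fraction = 0.10,
                          het_min_reads = 2) {
  full <- setNames(numeric(4L), DNA_BASES)
  full[intersect(names(counts), DNA_BASES)] <-
    counts[intersect(names(counts), DNA_BASES)]
  depth <- sum(full)
  if (depth == 0) {
    return(list(call = NA_character_, depth = 0, major_base = NA_character_,
                major_fraction = NA_real_, heteroplasmic = FALSE))
  }
  major <- names(full)[which.max(full)]
  included <- names(full)[full >= het_min_reads &
                            full / depth >= het_min_fraction]
  included <- union(major, included)
  list(
    call = iupac_code(included),
    depth = depth,
    major_base = major,
    major_fraction = unname(full[major] / depth),
    heteroplasmic = length(included) > 1L
  )
}

#' Pile up lifted placements and call the mitochondrial consensus
#'
#' Builds per-position base counts over the whole circle from
#' reference-aligned read sequences (wrapping footprints handled modulo the
#' circle length), then applies the [call_position()] rule at every
#' position. Insertion observations carried in the `"insertions"` attribute
#' of the placements (anchor position, rank, base per read) are counted and
#' reported in `anchor.rank` notation; an insertion joins the consensus when
#' supported by a majority of the reads spanning its anchor. Zero-depth
#' positions are reported as no-calls (`NA`), never as reference matches.
#'
#' @param lifted Lifted, deduplicated placement tibble (see
#'   [liftover_to_rcrs()] and [deduplicate_placements()]).
#' @param reference The circular reference sequence (character string).
#' @param het_min_fraction,het_min_reads Heteroplasmy thresholds, see
#'   [call_position()].
#' @return An object of class `mt_call_set`: a list with `positions`
#'   (tibble: `pos`, `ref`, `A`, `C`, `G`, `T`, `depth`, `call`,
#'   `major_fraction`, `heteroplasmic`), `insertions` (tibble: `anchor`,
#'   `rank`, `base`, `count`, `depth`, `fraction`, `called`, `notation`),
#'   and the calling parameters.
#' @export
pileup_and_call <- function(lifted, reference, het_min_fraction = 0.10,
                            het_min_reads = 2) {
  check_columns(lifted, c("read_id", "rcrs_start", "length", "sequence"),
                "lifted")
  L <- nchar(reference)
  if (nrow(lifted) > 0 && any(nchar(lifted$sequence) != lifted$length)) {
    abort("placement `sequence` must be reference-aligned (nchar == length)")
  }
  lens <- lifted$length
  pos_all <- if (nrow(lifted) > 0) {
    starts_rep <- rep(lifted$rcrs_start, lens)
    offset <- sequence(lens)
    ((starts_rep + offset - 2L) %% L) + 1L
  } else integer(0)
  base_all <- unlist(strsplit(lifted$sequence, "", fixed = TRUE),
                     use.names = FALSE)
  base_idx <- match(base_all, DNA_BASES)
  ok <- !is.na(base_idx)
  counts <- matrix(
    tabulate(pos_all[ok] + (base_idx[ok] - 1L) * L, nbins = 4L * L),
    nrow = L, ncol = 4L, dimnames = list(NULL, DNA_BASES)
  )
  depth <- as.integer(rowSums(counts))
  frac <- counts / pmax(depth, 1L)
  incl <- counts >= het_min_reads & frac >= het_min_fraction
  major_idx <- max.col(counts, ties.method = "first")
  has_depth <- depth > 0L
  incl[cbind(seq_len(L), major_idx)] <- has_depth
  n_incl <- rowSums(incl)
  call <- rep(NA_character_, L)
  call[has_depth & n_incl == 1L] <- DNA_BASES[major_idx[has_depth &
                                                          n_incl == 1L]]
  multi <- which(has_depth & n_incl > 1L)
  for (i in multi) {
    call[i] <- iupac_code(DNA_BASES[incl[i, ]])
  }
  major_count <- counts[cbind(seq_len(L), major_idx)]
  positions <- tibble(
    pos = seq_len(L),
    ref = strsplit(reference, "", fixed = TRUE)[[1]],
    A = counts[, "A"], C = counts[, "C"],
    G = counts[, "G"], T = counts[, "T"],
    depth = depth,
    call = call,
    major_fraction = ifelse(has_depth, major_count / depth, NA_real_),
    heteroplasmic = has_depth & n_incl > 1L
  )

  ins_obs <- attr(lifted, "insertions") %||%
    tibble(read_id = character(), anchor = integer(), rank = integer(),
           base = character())
  insertions <- ins_obs %>%
    count(.data$anchor, .data$rank, .data$base, name = "count") %>%
    mutate(
      depth = positions$depth[.data$anchor],
      fraction = .data$count / pmax(.data$depth, 1L),
      called = .data$fraction > 0.5,
      notation = sprintf("%d.%d%s", .data$anchor, .data$rank, .data$base)
    ) %>%
    arrange(.data$anchor, .data$rank)

  structure(
    list(
      positions = positions,
      insertions = insertions,
      het_min_fraction = het_min_fraction,
      het_min_reads = het_min_reads,
      n_placements = nrow(lifted)
    ),
    class = "mt_call_set"
  )
}

#' @export
print.mt_call_set <- function(x, ...) {
  called <- sum(!is.na(x$positions$call))
  cat(sprintf(
    "<mt_call_set> %d/%d positions called from %d placements; %d heteroplasmic, %d consensus insertion(s)\n",
    called, nrow(x$positions), x$n_placements,
    sum(x$positions$heteroplasmic), sum(x$insertions$called)
  ))
  invisible(x)
}

#' Express a call set as differences from the reference
#'
#' Substitution differences are written `<pos><base>` (IUPAC codes at mixed
#' positions, e.g. `16169Y`); consensus insertions are written
#' `<anchor>.<rank><base>` (e.g. `315.1C`). Positions with zero depth are
#' no-calls and never contribute a difference. The list is ordered by
#' position, then insertion rank.
#'
#' @param callset An `mt_call_set`.
#' @return A tibble with columns `pos`, `rank` (`NA` for substitutions),
#'   `type` (`"sub"`/`"ins"`), `call`, `notation`.
#' @export
haplotype_diff <- function(callset) {
  stopifnot(inherits(callset, "mt_call_set"))
  subs <- callset$positions %>%
    filter(!is.na(.data$call), .data$call != .data$ref) %>%
    mutate(
      rank = NA_integer_, type = "sub",
      notation = paste0(.data$pos, .data$call)
    ) %>%
    select("pos", "rank", "type", call = "call", "notation")
  ins <- callset$insertions %>%
    filter(.data$called) %>%
    mutate(type = "ins") %>%
    select(pos = "anchor", "rank", "type", call = "base", "notation")
  bind_rows(subs, ins) %>%
    arrange(.data$pos, !is.na(.data$rank), .data$rank)
}

#' Compare two haplotype difference lists
#'
#' Returns the shared differences and the symmetric difference between two
#' profiles, optionally restricted to positions called in both (pass the
#' called-position sets of each sample to exclude no-call positions from
#' the comparison, as forensic profile comparison requires).
#'
#' @param diff_a,diff_b Difference tibbles from [haplotype_diff()].
#' @param called_a,called_b Optional integer vectors of positions with
#'   calls in each sample; `NULL` means all positions were called.
#' @return A list with tibbles `shared`, `only_a`, `only_b` and the count
#'   `n_differences` (`nrow(only_a) + nrow(only_b)`).
#' @export
compare_haplotypes <- function(diff_a, diff_b, called_a = NULL,
                               called_b = NULL) {
  restrict <- function(d) {
    if (!is.null(called_a)) d <- d %>% filter(.data$pos %in% called_a)
    if (!is.null(called_b)) d <- d %>% filter(.data$pos %in% called_b)
    d
  }
  a <- restrict(diff_a)
  b <- restrict(diff_b)
  shared <- a %>% semi_join(b, by = "notation")
  only_a <- a %>% filter(!.data$notation %in% b$notation)
  only_b <- b %>% filter(!.data$notation %in% a$notation)
  list(
    shared = shared, only_a = only_a, only_b = only_b,
    n_differences = nrow(only_a) + nrow(only_b)
  )
}

#' Depth and fragment-length summaries
#'
#' Per-position depth statistics over the whole circle (zero-depth
#' positions included) and the fragment-length distribution of the unique
#' placements, binned at 1 bp.
#'
#' @param callset An `mt_call_set`.
#' @param lifted The lifted, deduplicated placements the calls came from.
#' @return A list of class `depth_length_stats` with `depth_mean`,
#'   `depth_min`, `depth_max`, `depth_sd`, `mean_length`, `n_reads` and
#'   `length_hist` (tibble `length`, `n`).
#' @export
depth_length_stats <- function(callset, lifted) {
  stopifnot(inherits(callset, "mt_call_set"))
  if (nrow(lifted) == 0L) {
    abort("cannot summarise an empty placement set")
  }
  d <- callset$positions$depth
  structure(
    list(
      depth_mean = mean(d),
      depth_min = min(d),
      depth_max = max(d),
      depth_sd = sd(d),
      mean_length = mean(lifted$length),
      n_reads = nrow(lifted),
      length_hist = lifted %>% count(length = .data$length, name = "n")
    ),
    class = "depth_length_stats"
  )
}

#' @export
print.depth_length_stats <- function(x, ...) {
  cat(sprintf(
    "<depth_length_stats> depth %.1fx (range %d-%d, SD %.2f); %d reads, mean length %.2f bp\n",
    x$depth_mean, x$depth_min, x$depth_max, x$depth_sd,
    x$n_reads, x$mean_length
  ))
  invisible(x)
}

#' Write a minimal VCF of the mitochondrial calls
#'
#' Emits substitution and consensus-insertion differences from the
#' reference as a minimal VCF 4.2 text file (`CHROM=chrM`, `POS`, `REF`,
#' `ALT`, with `AF` and `DP` in `INFO`). Mixed positions report the
#' non-reference base with its observed allele fraction.
#'
#' @param callset An `mt_call_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mt_vcf <- function(callset, path) {
  stopifnot(inherits(callset, "mt_call_set"))
  pos_tab <- callset$positions
  counts <- as.matrix(pos_tab[, DNA_BASES])
  rows <- character(0)
  sub_idx <- which(!is.na(pos_tab$call) & pos_tab$call != pos_tab$ref)
  for (i in sub_idx) {
    bases <- DNA_BASES[counts[i, ] > 0]
    alts <- setdiff(bases, pos_tab$ref[i])
    # report only bases surviving the calling rule
    in_call <- strsplit(names(which(IUPAC_CODES == pos_tab$call[i])), "")[[1]]
    if (pos_tab$call[i] %in% DNA_BASES) in_call <- pos_tab$call[i]
    alts <- intersect(alts, in_call)
    if (length(alts) == 0L) next
    af <- counts[i, alts] / pos_tab$depth[i]
    rows <- c(rows, sprintf(
      "chrM\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AF=%s",
      pos_tab$pos[i], pos_tab$ref[i], paste(alts, collapse = ","),
      pos_tab$depth[i], paste(sprintf("%.4f", af), collapse = ",")
    ))
  }
  ins <- callset$insertions %>% filter(.data$called)
  if (nrow(ins) > 0) {
    ins_grouped <- ins %>%
      group_by(.data$anchor) %>%
      summarise(
        inserted = paste(.data$base[order(.data$rank)], collapse = ""),
        depth = .data$depth[1],
        fraction = min(.data$fraction),
        .groups = "drop"
      )
    for (i in seq_len(nrow(ins_grouped))) {
      anchor <- ins_grouped$anchor[i]
      ref_base <- pos_tab$ref[anchor]
      rows <- c(rows, sprintf(
        "chrM\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AF=%.4f",
        anchor, ref_base, paste0(ref_base, ins_grouped$inserted[i]),
        ins_grouped$depth[i], ins_grouped$fraction[i]
      ))
    }
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrM>",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname autoplot_sparsekin
#' @export
autoplot.mt_call_set <- function(object, ...) {
  pos_tab <- object$positions
  het <- pos_tab %>% filter(.data$heteroplasmic)
  ggplot2::ggplot(pos_tab, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(data = het, colour = "firebrick") +
    ggplot2::labs(
      x = "circular genome position (bp)", y = "read depth",
      title = "Mitochondrial coverage",
      subtitle = "points mark mixed (heteroplasmic) calls"
    ) +
    ggplot2::theme_minimal()
}
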