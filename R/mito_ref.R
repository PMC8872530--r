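#' Build a chimeric doubled reference for a circular genome
#'
#' Linear aligners cannot place reads across the origin of a circular
#' genome. The standard workaround is a chimeric linear reference: the full
#' genome (positions 1..L), a spacer of `spacer_len` N bases, then a second
#' full copy rotated to begin at `rotation_origin` (so the second copy runs
#' `rotation_origin..L` then `1..rotation_origin - 1`). For the canonical
#' 16,569 bp human mitochondrial genome with origin 8284 and a 14 N spacer
#' this yields a 33,152 bp sequence. Reads spanning the circular origin map
#' cleanly inside the second copy and are lifted back with
#' [liftover_to_rcrs()].
#'
#' @param reference Circular reference sequence (character string, length L).
#' @param rotation_origin 1-based position at which the second copy starts
#'   (default 8284).
#' @param spacer_len Number of N bases between the copies (default 14).
#' @return A list of class `chimeric_reference` with elements `sequence`
#'   (length `2L + spacer_len`), `circle_length`, `spacer_start`,
#'   `spacer_end`, `copy2_origin`, `spacer_len`.
#' @export
#' @examples
#' ref <- synthetic_rcrs(seed = 1)
#' chim <- build_chimeric_reference(ref)
#' nchar(chim$sequence) # 33152
build_chimeric_reference <- function(reference, rotation_origin = 8284L,
                                     spacer_len = 14L) {
  stopifnot(is.character(reference), length(reference) == 1L)
  L <- nchar(reference)
  rotation_origin <- check_count(rotation_origin, "rotation_origin")
  spacer_len <- check_count(spacer_len, "spacer_len", min = 0)
  if (rotation_origin > L) {
    abort("`rotation_origin` must lie in 1..reference length")
  }
  rotated <- paste0(
    substring(reference, rotation_origin, L),
    if (rotation_origin > 1L) substring(reference, 1L, rotation_origin - 1L)
    else ""
  )
  sequence <- paste0(reference, strrep("N", spacer_len), rotated)
  structure(
    list(
      sequence = sequence,
      circle_length = L,
      spacer_start = L + 1L,
      spacer_end = L + spacer_len,
      copy2_origin = as.integer(rotation_origin),
      spacer_len = as.integer(spacer_len)
    ),
    class = "chimeric_reference"
  )
}

#' @export
print.chimeric_reference <- function(x, ...) {
  cat(sprintf(
    "<chimeric_reference> %d bp (= 2 x %d + %d N spacer), copy 2 starts at circle position %d\n",
    nchar(x$sequence), x$circle_length, x$spacer_len, x$copy2_origin
  ))
  invisible(x)
}

#' Write a chimeric reference to FASTA
#'
#' @param chimeric_ref A `chimeric_reference`.
#' @param path Output FASTA path.
#' @param name Sequence name in the FASTA header.
#' @return The reference, invisibly.
#' @export
write_chimeric_reference <- function(chimeric_ref, path,
                                     name = "chrM_chimeric") {
  stopifnot(inherits(chimeric_ref, "chimeric_reference"))
  seqs <- Biostrings::DNAStringSet(chimeric_ref$sequence)
  names(seqs) <- name
  Biostrings::writeXStringSet(seqs, path)
  invisible(chimeric_ref)
}

#' Map one chimeric-reference position to the circular coordinate
#'
#' Positions in the first copy map identically; spacer positions map to
#' `NA`; positions in the second copy map through the rotation.
#'
#' @param q 1-based positions on the chimeric reference (vectorised).
#' @param chimeric_ref A `chimeric_reference`.
#' @return Integer vector of 1-based circular coordinates (`NA` for spacer).
#' @export
chimeric_to_circle <- function(q, chimeric_ref) {
  L <- chimeric_ref$circle_length
  sp <- chimeric_ref$spacer_len
  origin <- chimeric_ref$copy2_origin
  out <- rep(NA_integer_, length(q))
  in1 <- q >= 1L & q <= L
  out[in1] <- as.integer(q[in1])
  in2 <- q > L + sp & q <= 2L * L + sp
  out[in2] <- as.integer(((q[in2] - (L + sp) + origin - 2L) %% L) + 1L)
  out
}

#' Place simulated circular-coordinate reads onto the chimeric reference
#'
#' The simulator emits reads in circular (rCRS-like) coordinates; an aligner
#' would report them on the chimeric reference. This deterministic stand-in
#' places non-wrapping reads on the first copy and origin-spanning reads on
#' the second copy, reproducing what a linear aligner achieves with the
#' chimeric construction.
#'
#' @param read_set An `mt_read_set` from [simulate_mt_reads()].
#' @param chimeric_ref A `chimeric_reference` over the same circle length.
#' @return A tibble of placements: `read_id`, `chimeric_start`, `length`,
#'   `mq`, `sequence`, with the insertion annotations of `read_set` carried
#'   in the `"insertions"` attribute.
#' @export
place_on_chimeric <- function(read_set, chimeric_ref) {
  stopifnot(inherits(read_set, "mt_read_set"),
            inherits(chimeric_ref, "chimeric_reference"))
  L <- chimeric_ref$circle_length
  if (read_set$reference_length != L) {
    abort("read set and chimeric reference disagree on circle length")
  }
  sp <- chimeric_ref$spacer_len
  origin <- chimeric_ref$copy2_origin
  r <- read_set$reads
  wraps <- r$start_rcrs + r$length - 1L > L
  q <- ifelse(
    wraps,
    L + sp + ((r$start_rcrs - origin) %% L) + 1L,
    r$start_rcrs
  )
  if (any(wraps & ((r$start_rcrs - origin) %% L) + r$length > L)) {
    abort("some origin-spanning reads cannot be placed inside copy 2")
  }
  out <- tibble(
    read_id = r$read_id,
    chimeric_start = as.integer(q),
    length = r$length,
    mq = r$mq,
    sequence = r$sequence
  )
  attr(out, "insertions") <- read_set$insertions
  out
}

#' Lift chimeric-reference placements back to circular coordinates
#'
#' Deterministic inverse of the chimeric construction: first-copy positions
#' map identically, second-copy positions map through the rotation, and a
#' read whose footprint runs past position L wraps to the start of the
#' circle (its circular footprint splits into two intervals). Placements
#' overlapping the N spacer cannot arise from genuine circular fragments
#' and are rejected with a reason rather than silently dropped.
#'
#' @param placements Placement tibble with columns `read_id`,
#'   `chimeric_start`, `length`, `mq`, `sequence` (from [place_on_chimeric()]
#'   or a SAM-derived table of the same shape).
#' @param chimeric_ref The `chimeric_reference` the placements refer to.
#' @return A tibble with columns `read_id`, `rcrs_start`, `rcrs_end`
#'   (1-based inclusive, `rcrs_end` < `rcrs_start` when the footprint wraps
#'   the origin), `length`, `mq`, `wraps_origin`, `sequence`; rejected
#'   placements are reported in the `"rejected"` attribute (tibble with
#'   `read_id`, `reason`), and insertion annotations are passed through in
#'   the `"insertions"` attribute.
#' @export
liftover_to_rcrs <- function(placements, chimeric_ref) {
  stopifnot(inherits(chimeric_ref, "chimeric_reference"))
  check_columns(placements,
                c("read_id", "chimeric_start", "length", "mq", "sequence"),
                "placements")
  L <- chimeric_ref$circle_length
  sp <- chimeric_ref$spacer_len
  q_start <- placements$chimeric_start
  q_end <- q_start + placements$length - 1L
  total <- 2L * L + sp
  bad_range <- q_start < 1L | q_end > total
  spacer_hit <- q_start <= chimeric_ref$spacer_end &
    q_end >= chimeric_ref$spacer_start
  reject <- bad_range | spacer_hit
  rejected <- tibble(
    read_id = placements$read_id[reject],
    reason = ifelse(bad_range[reject], "outside chimeric reference",
                    "overlaps N spacer")
  )
  keep <- placements[!reject, ]
  qs <- keep$chimeric_start
  starts <- chimeric_to_circle(qs, chimeric_ref)
  ends <- ((starts + keep$length - 2L) %% L) + 1L
  out <- tibble(
    read_id = keep$read_id,
    rcrs_start = starts,
    rcrs_end = as.integer(ends),
    length = keep$length,
    mq = keep$mq,
    wraps_origin = starts + keep$length - 1L > L,
    sequence = keep$sequence
  )
  ins <- attr(placements, "insertions")
  if (!is.null(ins)) {
    attr(out, "insertions") <- ins %>% filter(.data$read_id %in% out$read_id)
  }
  attr(out, "rejected") <- rejected
  attr(out, "circle_length") <- L
  out
}

#' Circular footprint of a lifted placement
#'
#' Expands each lifted placement into one or two circular intervals (two
#' when the footprint wraps the origin).
#'
#' @param lifted Output of [liftover_to_rcrs()].
#' @return A tibble with columns `read_id`, `start`, `end` (1-based
#'   inclusive, `start <= end` within each row).
#' @export
rcrs_footprint <- function(lifted) {
  check_columns(lifted, c("read_id", "rcrs_start", "length"), "lifted")
  L <- attr(lifted, "circle_length") %||% RCRS_LENGTH
  s <- lifted$rcrs_start
  e_lin <- s + lifted$length - 1L
  wraps <- e_lin > L
  main <- tibble(
    read_id = lifted$read_id,
    start = s,
    end = pmin(e_lin, L)
  )
  if (any(wraps)) {
    tail <- tibble(
      read_id = lifted$read_id[wraps],
      start = 1L,
      end = as.integer(e_lin[wraps] - L)
    )
    main <- bind_rows(main, tail) %>% arrange(.data$read_id, .data$start)
  }
  main
}
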