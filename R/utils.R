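# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC code for an unordered set of observed bases (2- and 3-base mixtures).
IUPAC_CODES <- c(
  "AC" = "M", "AG" = "R", "AT" = "W",
  "CG" = "S", "CT" = "Y", "GT" = "K",
  "ACG" = "V", "ACT" = "H", "AGT" = "D", "CGT" = "B",
  "ACGT" = "N"
)

iupac_code <- function(bases) {
  bases <- sort(unique(bases))
  if (length(bases) == 1L) {
    return(bases)
  }
  key <- paste(bases, collapse = "")
  code <- IUPAC_CODES[[key]]
  if (is.null(code)) {
    abort(sprintf("no IUPAC code for base set '%s'", key))
  }
  code
}

# Run `expr` under `seed` without touching the caller's RNG stream; a NULL
# seed uses (and advances) the current stream so pipelines can pass seeds
# down explicitly while interactive use stays ordinary.
with_seed_or_current <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    check_seed(seed)
    withr::with_seed(as.integer(seed), expr)
  }
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != trunc(seed) || abs(seed) >= 2^31) {
    abort("`seed` must be a single integer below 2^31")
  }
  invisible(seed)
}

# Deterministic 31-bit sub-seed for a named pipeline stage.
derive_seed <- function(seed, label) {
  check_seed(seed)
  h <- rlang::hash(list(as.integer(seed), as.character(label)))
  strtoi(substr(h, 1L, 7L), base = 16L)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != trunc(x)) {
    abort(sprintf("`%s` must be a single integer >= %s", name, format(min)))
  }
  invisible(as.integer(x))
}

check_fraction <- function(x, name, lo = 0, hi = 1, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x >= lo &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    abort(sprintf(
      "`%s` must be a single number in [%s, %s%s", name,
      format(lo), format(hi), if (hi_open) ")" else "]"
    ))
  }
  invisible(as.numeric(x))
}

check_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf(
      "`%s` is missing required column(s): %s", name,
      paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# GRCh37 (hg19) chromosome lengths for chr1-22 and X, in bp.
#' Chromosome lengths of the GRCh37 human assembly
#'
#' Lengths in base pairs for the 22 autosomes and the X chromosome of the
#' GRCh37 (hg19) assembly, the build the read-placement conventions of this
#' package assume. Used as the default length table for simulating
#' per-chromosome read counts and for length-normalising X-to-autosome
#' coverage ratios.
#'
#' @return A tibble with columns `chrom` (character, `"1"`..`"22"`, `"X"`)
#'   and `length_bp` (integer).
#' @export
#' @examples
#' grch37_chrom_lengths()
grch37_chrom_lengths <- function() {
  tibble(
    chrom = c(as.character(1:22), "X"),
    length_bp = c(
      249250621L, 243199373L, 198022430L, 191154276L, 180915260L,
      171115067L, 159138663L, 146364022L, 141213431L, 135534747L,
      135006516L, 133851895L, 115169878L, 107349540L, 102531392L,
      90354753L, 81195210L, 78077248L, 59128983L, 63025520L,
      48129895L, 51304566L, 155270560L
    )
  )
}

# Normalise chromosome labels: strip an optional "chr" prefix, uppercase X.
normalise_chrom <- function(chrom) {
  out <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  toupper(out)
}
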