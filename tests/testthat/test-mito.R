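test_that("chimeric reference construction matches the doubled-circle layout", {
  ref <- synthetic_rcrs(seed = 1)
  chim <- build_chimeric_reference(ref)
  expect_equal(nchar(chim$sequence), 33152) # 2*16569 + 14
  expect_equal(chim$spacer_start, 16570)
  expect_equal(chim$spacer_end, 16583)
  expect_equal(substr(chim$sequence, 16570, 16583), strrep("N", 14))
  # copy 2 starts at circle position 8284 and ends at 8283
  expect_equal(substr(chim$sequence, 16584, 16584), substr(ref, 8284, 8284))
  expect_equal(substr(chim$sequence, 33152, 33152), substr(ref, 8283, 8283))
  expect_equal(substr(chim$sequence, 1, 16569), ref)

  toy <- build_chimeric_reference(strrep("ACGTT", 20), rotation_origin = 51)
  expect_equal(nchar(toy$sequence), 214) # 2*100 + 14

  expect_error(build_chimeric_reference("ACGT", rotation_origin = 10),
               "rotation_origin")
})

test_that("liftover maps chimeric coordinates back to the circle", {
  ref <- synthetic_rcrs(seed = 2)
  chim <- build_chimeric_reference(ref)
  expect_equal(chimeric_to_circle(1L, chim), 1L)
  expect_equal(chimeric_to_circle(16584L, chim), 8284L)
  expect_true(is.na(chimeric_to_circle(16575L, chim))) # spacer

  # a copy-2 placement wrapping the origin splits into two intervals
  pl <- tibble::tibble(read_id = "r1", chimeric_start = 24865L,
                       length = 10L, mq = 60L, sequence = strrep("A", 10))
  lifted <- liftover_to_rcrs(pl, chim)
  expect_equal(lifted$rcrs_start, 16565L)
  expect_true(lifted$wraps_origin)
  fp <- rcrs_footprint(lifted)
  expect_equal(fp$start, c(1L, 16565L))
  expect_equal(fp$end, c(5L, 16569L))

  # spacer-overlapping placements are rejected with a reason
  bad <- tibble::tibble(read_id = "r2", chimeric_start = 16565L,
                        length = 10L, mq = 60L, sequence = strrep("A", 10))
  lifted2 <- liftover_to_rcrs(bad, chim)
  expect_equal(nrow(lifted2), 0)
  rej <- attr(lifted2, "rejected")
  expect_equal(rej$read_id, "r2")
  expect_match(rej$reason, "spacer")
})

test_that("build + liftover round trip covers the circle exactly twice", {
  ref <- synthetic_rcrs(length = 50, seed = 3)
  chim <- build_chimeric_reference(ref, rotation_origin = 21, spacer_len = 14)
  all_q <- seq_len(nchar(chim$sequence))
  mapped <- chimeric_to_circle(all_q, chim)
  expect_equal(sum(is.na(mapped)), 14) # only the spacer is unmapped
  counts <- table(mapped)
  expect_equal(length(counts), 50) # every circle position reachable
  expect_true(all(counts == 2))    # exactly two preimages each
  # sequence agreement at every mapped position
  chim_bases <- strsplit(chim$sequence, "")[[1]]
  ref_bases <- strsplit(ref, "")[[1]]
  ok <- !is.na(mapped)
  expect_equal(chim_bases[ok], ref_bases[mapped[ok]])
})

test_that("deduplication collapses identical fragment endpoints only", {
  lifted <- make_lifted(list(
    list(start = 10, seq = strrep("A", 20), mq = 50),
    list(start = 10, seq = strrep("A", 20), mq = 60), # duplicate, higher MQ
    list(start = 10, seq = strrep("A", 25), mq = 60), # same start, new end
    list(start = 30, seq = strrep("C", 20), mq = 60)
  ), circle_length = 100)
  dd <- deduplicate_placements(lifted)
  expect_equal(nrow(dd), 3)
  expect_equal(attr(dd, "n_duplicates_removed"), 1)
  # representative is the higher-MQ copy
  expect_true(all(dd$mq[dd$rcrs_start == 10 & dd$length == 20] == 60))
  # idempotent
  dd2 <- deduplicate_placements(dd)
  expect_equal(nrow(dd2), 3)
  expect_equal(attr(dd2, "n_duplicates_removed"), 0)
})

test_that("mapping-quality filtering keeps the MQ 30 boundary", {
  lifted <- make_lifted(list(
    list(start = 1, seq = "ACGT", mq = 29),
    list(start = 5, seq = "ACGT", mq = 30),
    list(start = 9, seq = "ACGT", mq = 60)
  ), circle_length = 100)
  kept <- filter_placements(lifted)
  expect_equal(nrow(kept), 2)
  expect_equal(attr(kept, "n_mq_filtered"), 1)
  empty <- filter_placements(lifted[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("consensus calling applies the point-heteroplasmy rule", {
  # worked example: 57 T / 18 C is a mixed Y call at 76% major fraction
  mixed <- call_position(c(T = 57, C = 18))
  expect_equal(mixed$call, "Y")
  expect_equal(mixed$major_fraction, 0.76)
  expect_true(mixed$heteroplasmic)
  expect_equal(mixed$depth, 75)

  # 53 C / 1 T: the lone T (1.9%, plausibly deamination) is ignored
  homo <- call_position(c(C = 53, T = 1))
  expect_equal(homo$call, "C")
  expect_false(homo$heteroplasmic)

  # zero depth is a no-call
  expect_true(is.na(call_position(c(A = 0))$call))
})

test_that("pileup calls substitutions, mixtures and insertions in notation", {
  ref <- synthetic_rcrs(length = 60, seed = 4)
  ref_bases <- strsplit(ref, "")[[1]]
  stopifnot(ref_bases[10] != "G") # fixture sanity
  sub_seq <- ref_bases
  sub_seq[10] <- "G"
  reads <- c(
    replicate(10, list(start = 1, seq = paste(sub_seq[1:30], collapse = ""),
                       mq = 60), simplify = FALSE),
    replicate(4, list(start = 1, seq = paste(ref_bases[1:30], collapse = ""),
                      mq = 60), simplify = FALSE)
  )
  ins <- tibble::tibble(read_id = sprintf("r%03d", 1:10), anchor = 20L,
                        rank = 1L, base = "C")
  lifted <- make_lifted(reads, circle_length = 60, insertions = ins)
  cs <- pileup_and_call(lifted, ref)

  pos10 <- cs$positions[cs$positions$pos == 10, ]
  expect_equal(pos10$depth, 14)
  expect_true(pos10$heteroplasmic) # 4/14 = 29% minor
  expect_equal(pos10$call, iupac_code(c("G", ref_bases[10])))

  # 10/14 reads support the insertion: consensus, notation anchor.rank
  ins_row <- cs$insertions
  expect_equal(nrow(ins_row), 1)
  expect_true(ins_row$called)
  expect_equal(ins_row$notation, "20.1C")

  # uncovered positions are no-calls, not reference matches
  expect_true(all(is.na(cs$positions$call[cs$positions$depth == 0])))
  expect_true(all(cs$positions$depth ==
                    rowSums(cs$positions[, c("A", "C", "G", "T")])))

  diffs <- haplotype_diff(cs)
  expect_true("20.1C" %in% diffs$notation)
  expect_true(any(grepl("^10", diffs$notation)))

  # a clean substitution at full depth yields "<pos><base>"
  clean <- make_lifted(list(list(start = 5, seq = "GGGG", mq = 60)),
                       circle_length = 60)
  ref2 <- paste(c(rep("A", 60)), collapse = "")
  cs2 <- pileup_and_call(clean, ref2)
  d2 <- haplotype_diff(cs2)
  expect_equal(d2$notation, c("5G", "6G", "7G", "8G"))
})

test_that("haplotype comparison returns shared and symmetric differences", {
  ref <- paste(rep("A", 30), collapse = "")
  cs <- pileup_and_call(
    make_lifted(list(list(start = 1, seq = paste(rep("A", 30),
                                                 collapse = ""))),
                circle_length = 30),
    ref
  )
  expect_equal(nrow(haplotype_diff(cs)), 0) # identical to reference

  d <- haplotype_diff(cs)
  cmp_same <- compare_haplotypes(d, d)
  expect_equal(cmp_same$n_differences, 0)

  da <- tibble::tibble(pos = c(5L, 10L), rank = NA_integer_, type = "sub",
                       call = c("G", "T"), notation = c("5G", "10T"))
  db <- tibble::tibble(pos = c(5L, 12L), rank = NA_integer_, type = "sub",
                       call = c("G", "C"), notation = c("5G", "12C"))
  cmp <- compare_haplotypes(da, db)
  expect_equal(cmp$shared$notation, "5G")
  expect_equal(cmp$only_a$notation, "10T")
  expect_equal(cmp$only_b$notation, "12C")
  expect_equal(cmp$n_differences, 2)

  # restriction to positions called in both drops one-sided no-calls
  cmp_restricted <- compare_haplotypes(da, db, called_a = c(5L, 10L, 12L),
                                       called_b = c(5L, 12L))
  expect_equal(cmp_restricted$only_a$notation, character(0))
  expect_equal(cmp_restricted$n_differences, 1)
})

test_that("simulated circular reads respect length, depth and wrapping", {
  ref <- synthetic_rcrs(length = 1000, seed = 5)
  rs <- simulate_mt_reads(ref, depth_target = 30,
                          length_law = length_constant(45), seed = 6)
  # coverage identity: depth = sum(lengths) / L
  expect_equal(sum(rs$reads$length) / 1000, 30, tolerance = 0.05)
  expect_equal(mean(rs$reads$length), 45)
  expect_true(any(rs$reads$origin_spanning))

  # every read is an exact substring of the doubled reference
  doubled <- paste0(ref, ref)
  extracted <- substring(doubled, rs$reads$start_rcrs,
                         rs$reads$start_rcrs + rs$reads$length - 1L)
  expect_identical(extracted, rs$reads$sequence)

  # log-normal law hits its nominal mean within 3 SE
  law <- length_lognormal(45, cv = 0.3)
  lens <- withr::with_seed(7, law(20000))
  expect_lt(abs(mean(lens) - 45), 3 * sd(lens) / sqrt(20000))

  # determinism
  rs2 <- simulate_mt_reads(ref, depth_target = 30,
                           length_law = length_constant(45), seed = 6)
  expect_identical(rs$reads, rs2$reads)

  bad_hap <- tibble::tibble(pos = 2000L, type = "sub", rank = NA_integer_,
                            base = "A")
  expect_error(simulate_mt_reads(ref, bad_hap, depth_target = 1,
                                 length_law = length_constant(40)),
               "1..reference")
})

test_that("terminal deamination stays below the heteroplasmy threshold", {
  ref <- synthetic_rcrs(length = 2000, seed = 8)
  rs <- simulate_mt_reads(ref, depth_target = 60,
                          length_law = length_constant(50),
                          deamination_rate = 0.05, seed = 9)
  chim <- build_chimeric_reference(ref, rotation_origin = 500)
  lifted <- liftover_to_rcrs(place_on_chimeric(rs, chim), chim)
  cs <- pileup_and_call(deduplicate_placements(filter_placements(lifted)),
                        ref)
  # damage-induced minor T alleles never reach a mixed call at this depth
  expect_equal(sum(cs$positions$heteroplasmic), 0)
  expect_equal(nrow(haplotype_diff(cs)), 0)
  # but raw counts do show C->T noise somewhere
  t_at_c <- cs$positions$T[cs$positions$ref == "C"]
  expect_gt(sum(t_at_c), 0)
})

test_that("depth and length statistics summarise the placement set", {
  ref <- paste(rep("A", 100), collapse = "")
  lifted <- make_lifted(list(list(start = 1, seq = strrep("A", 50))),
                        circle_length = 100)
  cs <- pileup_and_call(lifted, ref)
  st <- depth_length_stats(cs, lifted)
  expect_equal(st$depth_mean, 0.5) # 50 covered bases over a 100 bp circle
  expect_equal(st$depth_min, 0)
  expect_equal(st$depth_max, 1)
  expect_equal(st$mean_length, 50)
  expect_equal(sum(st$length_hist$n), 1)
  expect_error(depth_length_stats(cs, lifted[0, ]), "empty")
})

test_that("the minimal VCF writer reports substitutions, mixtures and insertions", {
  ref <- paste(rep("A", 40), collapse = "")
  reads <- c(
    replicate(6, list(start = 1, seq = paste0("AAAA", "G",
                                              strrep("A", 15))),
              simplify = FALSE), # G at position 5
    replicate(4, list(start = 1, seq = strrep("A", 20)), simplify = FALSE)
  )
  ins <- tibble::tibble(read_id = sprintf("r%03d", 1:8), anchor = 10L,
                        rank = 1L, base = "C")
  cs <- pileup_and_call(make_lifted(reads, 40, insertions = ins), ref)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_mt_vcf(cs, path)
  lines <- readLines(path)
  expect_true(any(grepl("^##fileformat=VCFv4.2", lines)))
  body <- lines[!startsWith(lines, "#")]
  fields <- strsplit(body, "\t")
  # mixed position 5: REF A, ALT G with AF 0.6, DP 10
  pos5 <- fields[[which(vapply(fields, `[`, "", 2) == "5")]]
  expect_equal(pos5[c(1, 4, 5)], c("chrM", "A", "G"))
  expect_match(pos5[8], "DP=10")
  expect_match(pos5[8], "AF=0.6000")
  # consensus insertion at anchor 10: REF A, ALT AC
  pos10 <- fields[[which(vapply(fields, `[`, "", 2) == "10")]]
  expect_equal(pos10[c(4, 5)], c("A", "AC"))
})

test_that("FASTA and placement writers emit readable files", {
  ref <- synthetic_rcrs(length = 500, seed = 10)
  chim <- build_chimeric_reference(ref, rotation_origin = 251)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_chimeric_reference(chim, fa)
  back <- Biostrings::readDNAStringSet(fa)
  expect_equal(as.character(back[[1]]), chim$sequence)

  rs <- simulate_mt_reads(ref, depth_target = 2,
                          length_law = length_constant(40), seed = 11)
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_mt_reads(rs, fa2, tsv)
  seqs <- Biostrings::readDNAStringSet(fa2)
  expect_equal(length(seqs), nrow(rs$reads))
  placements <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(placements$start_rcrs, rs$reads$start_rcrs)
})
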