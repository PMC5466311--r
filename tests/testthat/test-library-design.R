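# independent constraint checker for barcode sets
check_barcode_set <- function(bc, length_range, min_distance,
                              enzA = "EcoRI", enzB = "MseI") {
  b <- bc$barcode
  ea <- ddgbs_enzymes(enzA); eb <- ddgbs_enzymes(enzB)
  remnant <- substr(ea$recognition, ea$cut_offset + 1,
                    nchar(ea$recognition))
  ok_unique <- !anyDuplicated(b)
  ok_len <- all(nchar(b) >= length_range[1] & nchar(b) <= length_range[2])
  ok_gg <- !any(startsWith(b, "GG"))
  ok_site <- all(vapply(b, function(x) {
    ext <- paste0(x, remnant)
    length(naive_cut_sites(ext, ea$recognition, ea$cut_offset)) == 0 &&
      length(naive_cut_sites(ext, eb$recognition, eb$cut_offset)) == 0
  }, logical(1)))
  ok_dist <- TRUE
  if (length(b) > 1)
    for (i in 1:(length(b) - 1)) for (j in (i + 1):length(b)) {
      L <- min(nchar(b[i]), nchar(b[j]))
      d <- sum(strsplit(substr(b[i], 1, L), "")[[1]] !=
                 strsplit(substr(b[j], 1, L), "")[[1]])
      if (d < min_distance) ok_dist <- FALSE
    }
  c(unique = ok_unique, length = ok_len, gg = ok_gg, site = ok_site,
    distance = ok_dist)
}

test_that("generated barcodes satisfy all design constraints", {
  bc <- generate_barcodes(24, c(6, 9), min_distance = 3, seed = 1)
  expect_equal(nrow(bc), 24)
  expect_true(all(check_barcode_set(bc, c(6, 9), 3)))
  # lengths spread across the range
  expect_gt(length(unique(nchar(bc$barcode))), 1)
  # deterministic given the seed
  bc2 <- generate_barcodes(24, c(6, 9), min_distance = 3, seed = 1)
  expect_identical(bc, bc2)
  # a single fixed-length barcode
  one <- generate_barcodes(1, c(6, 6), min_distance = 1, seed = 0)
  expect_equal(nchar(one$barcode), 6)
  expect_false(startsWith(one$barcode, "GG"))
})

test_that("an over-constrained barcode request fails informatively", {
  # 6-mers at pairwise distance >= 5: Singleton bound caps the code at 16
  expect_error(
    generate_barcodes(70000, c(6, 6), min_distance = 5, seed = 0,
                      max_rejects = 2000),
    "exhausted.*min_distance")
})

test_that("adapter ratio is proportional to cut-end counts", {
  r <- compute_adapter_ratio(100, 100, 2)
  expect_equal(r$barcode_adapter_parts, 1.0)
  expect_equal(r$common_adapter_parts, 1.0)
  r <- compute_adapter_ratio(1, 19, 20)
  expect_equal(r$barcode_adapter_parts, 1.0)
  expect_equal(r$common_adapter_parts, 19.0)
  # counts from a seeded synthetic genome, checked against the
  # hand-computed proportional split at one decimal
  g <- random_dna(200000, seed = 9, gc = 0.42)
  a <- length(find_cut_sites(g, "EcoRI"))
  b <- length(find_cut_sites(g, "MseI"))
  r <- compute_adapter_ratio(a, b, 15.8)
  expect_equal(r$barcode_adapter_parts, round_half_up(15.8 * a / (a + b), 1))
  expect_equal(r$common_adapter_parts, round_half_up(15.8 * b / (a + b), 1))
  expect_error(compute_adapter_ratio(0, 10, 2), "positive")
})

test_that("demultiplexing assigns on perfect prefix match only", {
  bc <- structure(data.frame(sample_id = c("a", "b"),
                             barcode = c("ACGTAC", "TTTCCC")),
                  class = c("barcode_set", "data.frame"))
  d <- demultiplex(c("ACGTACGGGGA", "ACGAACGGGGA", "TTTCCCAAAA"), bc)
  expect_equal(d$counts$good_barcode_reads, c(1L, 1L))
  expect_equal(d$unassigned, 1L)               # the 1-mismatch read
  expect_equal(d$reads$a$seq, "GGGGA")         # barcode-trimmed
  expect_equal(d$reads$b$seq, "AAAA")
})

test_that("nested barcodes resolve longest-match-first", {
  bc <- structure(data.frame(sample_id = c("short", "long"),
                             barcode = c("ACGT", "ACGTAC")),
                  class = c("barcode_set", "data.frame"))
  d <- demultiplex(c("ACGTACGGG", "ACGTTTGGG"), bc)
  expect_equal(d$assignment, c("long", "short"))
  expect_equal(d$reads$long$seq, "GGG")
  expect_equal(d$reads$short$seq, "TTGGG")
})

test_that("demultiplexing recovers the simulator's truth labels", {
  bc <- generate_barcodes(4, c(6, 9), min_distance = 3, seed = 5)
  set.seed(7)
  truth <- sample(1:4, 1000, replace = TRUE)
  inserts <- vapply(1:1000, function(i)
    paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = ""),
    character(1))
  reads <- paste0(bc$barcode[truth], inserts)
  d <- demultiplex(reads, bc)
  expect_equal(d$counts$good_barcode_reads,
               as.integer(tabulate(truth, 4)))
  # conservation: assigned + unassigned = total
  expect_equal(sum(d$counts$good_barcode_reads) + d$unassigned, 1000L)
})

test_that("per-sample read counts have small CV under symmetric simulation", {
  cfg <- sim_config(genome_length = 3e5, n_samples = 8, mean_depth = 30,
                    abundance_sigma = 0, n_snps = 5, seed = 99)
  sim <- simulate_reads(simulate_genome(cfg), cfg)
  counts <- vapply(sim$reads, nrow, 0L)
  expect_lt(sd(counts) / mean(counts), 0.1)
})

test_that("FASTQ round-trips through write and read, including gzip", {
  reads <- data.frame(id = c("r1", "r2"), seq = c("ACGT", "GGCCA"),
                      qual = c("IIII", "IIIII"))
  for (ext in c(".fq", ".fq.gz")) {
    f <- tempfile(fileext = ext)
    write_fastq(reads, f)
    back <- read_fastq(f)
    expect_equal(back, reads)
  }
})
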