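test_that("cut sites follow the between-base convention", {
  expect_identical(find_cut_sites("GAATTC", "EcoRI"), 1L)
  expect_length(find_cut_sites("ACGTACGT", "EcoRI"), 0)
  # PstI cuts CTGCA/G
  expect_identical(find_cut_sites("AACTGCAGAA", "PstI"), 7L)
  # degenerate ApeKI motif GCWGC matches both W expansions
  expect_identical(find_cut_sites("GCAGCTTGCTGC", "ApeKI"), c(1L, 8L))
  expect_error(restriction_enzyme("bad", "GAXTTC", 1), "IUPAC")
})

test_that("genome ambiguity codes are matched only by motif N", {
  # N run must not create MseI (TTAA) cut sites
  expect_length(find_cut_sites("CCNNNNNNNNCC", "MseI"), 0)
  # motif N matches any genome letter, including ambiguity codes
  enzN <- restriction_enzyme("enzN", "GANTC", 1)
  expect_identical(find_cut_sites("CGARTCC", enzN), 2L)
})

test_that("scanner matches independent oracles on random sequences", {
  seqs <- list(random_dna(20000, seed = 42),
               random_dna(20000, seed = 7, gc = 0.42))
  for (sq in seqs) {
    for (nm in names(ddgbs_enzymes())) {
      e <- ddgbs_enzymes(nm)
      expect_identical(find_cut_sites(sq, e),
                       as.integer(naive_cut_sites(sq, e$recognition,
                                                  e$cut_offset)),
                       info = nm)
    }
  }
  # Biostrings as a second, library-based oracle on a longer sequence
  sq <- random_dna(100000, seed = 42)
  starts <- Biostrings::start(
    Biostrings::matchPattern("TTAA", Biostrings::DNAString(sq)))
  expect_identical(find_cut_sites(sq, "MseI"), as.integer(starts - 1L + 1L))
})

test_that("strand symmetry: cuts map through coordinate reversal", {
  # recognition sites are strand-symmetric, so reverse-complement cuts,
  # mapped back through p -> n - p, are the cuts of the mirrored offset
  # (L - c): a staggered cutter severs the duplex at the same sites but
  # the single between-base coordinate reflects about the site centre
  sq <- random_dna(5000, seed = 3)
  n <- nchar(sq)
  rc <- naive_revcomp(sq)
  for (nm in names(ddgbs_enzymes())) {
    e <- ddgbs_enzymes(nm)
    L <- nchar(e$recognition)
    mirror <- restriction_enzyme(e$name, e$recognition, L - e$cut_offset)
    fwd <- find_cut_sites(sq, e)
    back <- sort(n - find_cut_sites(rc, e))
    expect_identical(as.integer(back), find_cut_sites(sq, mirror), info = nm)
    expect_length(back, length(fwd))
  }
})

test_that("double digestion reproduces hand-worked coordinates", {
  dd <- double_digest(c(chr = "CCGAATTCCCTTAACC"), "EcoRI", "MseI")
  fr <- dd$fragments
  expect_equal(fr$start, c(0, 3, 11))
  expect_equal(fr$end, c(3, 11, 16))
  expect_equal(fr$class, c("terminal", "AB", "terminal"))
  expect_equal(fr$length[2], 8)
  expect_equal(unname(dd$class_counts[c("AB", "AA", "BB")]), c(1L, 0L, 0L))
  # a site-free sequence yields one terminal fragment spanning it
  dd0 <- double_digest(c(chr = strrep("AC", 30)), "EcoRI", "MseI")
  expect_equal(nrow(dd0$fragments), 1)
  expect_equal(dd0$fragments$class, "terminal")
  expect_equal(dd0$fragments$length, 60)
})

test_that("fragments tile each sequence and classes are conserved", {
  g <- c(s1 = random_dna(200000, seed = 11, gc = 0.42),
         s2 = random_dna(80000, seed = 12, gc = 0.42))
  dd <- double_digest(g, "PstI", "MspI")
  fr <- dd$fragments
  for (sq in names(g)) {
    expect_equal(sum(fr$length[fr$seq_name == sq]), nchar(g[[sq]]))
    starts <- fr$start[fr$seq_name == sq]
    ends <- fr$end[fr$seq_name == sq]
    expect_equal(starts[-1], ends[-length(ends)]) # no gaps, no overlaps
  }
  expect_equal(sum(dd$class_counts), nrow(fr))
})

test_that("a coordinate cut by both enzymes is labelled by enzyme A once", {
  enzB <- restriction_enzyme("shift", "AATTCC", 0)
  dd <- double_digest(c(chr = "TTGAATTCCTT"), "EcoRI", enzB)
  # EcoRI cuts at 3; shift matches at start 3 with offset 0 -> also 3
  expect_equal(nrow(dd$fragments), 2)
  expect_equal(dd$fragments$right_end[1], "EcoRI")
  expect_equal(dd$fragments$left_end[2], "EcoRI")
})

test_that("adding an enzyme never decreases fragment count", {
  for (seed in 1:3) {
    g <- c(chr = random_dna(50000, seed = seed, gc = 0.42))
    single <- single_digest(g, "MseI")
    double <- double_digest(g, "EcoRI", "MseI")
    expect_gte(nrow(double$fragments), nrow(single$fragments))
  }
})

test_that("size selection keeps exactly the in-window AB fragments", {
  g <- c(chr = random_dna(300000, seed = 21, gc = 0.42))
  dd <- double_digest(g, "EcoRI", "MseI")
  sel <- size_select(dd, 300, 650)
  # independent recount from the full fragment list
  fr <- dd$fragments
  expected <- sum(fr$class == "AB" & fr$length >= 300 & fr$length <= 650)
  expect_equal(nrow(sel$fragments), expected)
  expect_lte(nrow(sel$fragments), nrow(dd$fragments))
  expect_true(all(sel$fragments$class == "AB"))
  # min_len == max_len retains exactly that length
  L <- fr$length[fr$class == "AB"][1]
  one <- size_select(dd, L, L, ab_only = TRUE)
  expect_true(all(one$fragments$length == L))
  expect_equal(nrow(one$fragments),
               sum(fr$class == "AB" & fr$length == L))
  # empty selection warns but is valid
  expect_warning(empty <- size_select(dd, 1, 2), "no fragments")
  expect_equal(nrow(empty$fragments), 0)
})

test_that("BED export round-trips fragment coordinates", {
  g <- c(chr = random_dna(5000, seed = 5, gc = 0.42))
  dd <- double_digest(g, "EcoRI", "MseI")
  bed <- tempfile(fileext = ".bed")
  write_fragments_bed(dd, bed)
  back <- read.table(bed, sep = "\t")
  expect_equal(back$V2, dd$fragments$start)
  expect_equal(back$V3, dd$fragments$end)
  expect_equal(back$V5, dd$fragments$length)
})
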