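test_that("VCF with GT/DP/GQ loads into a snp_matrix", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Quality\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:DP:GQ\t0/0:12:99\t0/1:7:98",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT:DP:GQ\t1/1:3:45\t./.:0:0",
    "chr2\t50\t.\tG\tA,C\t.\tPASS\t.\tGT:DP:GQ\t0/1:9:99\t0/0:8:99"),
    vcf)
  x <- read_snp_vcf(vcf)
  expect_equal(dim(x), c(3L, 2L))
  expect_equal(unname(x$geno[1, ]), c(0L, 1L))
  expect_equal(unname(x$geno[2, ]), c(2L, NA))
  expect_equal(unname(x$depth[2, 1]), 3)
  expect_equal(unname(x$gq[1, 2]), 98)
  expect_equal(x$sites$alt[3], "A,C")
})

test_that("truth VCF and chip TSV round-trip", {
  x <- toy_snp_matrix(cbind(s1 = c(0L, 1L, 2L), s2 = c(NA, 2L, 0L)))
  v <- tempfile(fileext = ".vcf")
  write_snp_vcf(x, v)
  back <- read_snp_vcf(v)
  expect_equal(back$geno, x$geno)
  expect_equal(back$sites$pos, x$sites$pos)
  t <- tempfile(fileext = ".tsv")
  write_chip_tsv(x, t)
  back2 <- read_chip_tsv(t)
  expect_equal(back2$geno, x$geno)
})

test_that("the SNP filter reproduces a hand-filtered toy matrix", {
  sites <- data.frame(
    chrom = "chr1", pos = c(100, 200, 300, 400, 500, 600),
    ref = "A", alt = c("G", "G,T", "G", "G", "G", "G"))
  geno <- rbind(
    c(0, 1, 1, 2),    # clean site, MAF 0.5
    c(0, 1, 0, 0),    # triallelic -> removed
    c(0, 0, 0, 0),    # monomorphic, MAF 0 -> removed
    c(NA, NA, NA, 1), # call rate 0.25 < 0.6 -> removed
    c(0, 1, 2, 1),    # one low-DP call masked; still MAF >= 0.05
    c(1, 1, 0, 2))    # one low-GQ call masked
  depth <- matrix(10, 6, 4); depth[5, 2] <- 2
  gq <- matrix(99, 6, 4); gq[6, 1] <- 50
  colnames(geno) <- paste0("s", 1:4)
  x <- snp_matrix(sites, geno, depth, gq)
  f <- filter_snps(x, filter_config())
  # hand count: sites 100, 500, 600 survive
  expect_equal(f$sites$pos, c(100, 500, 600))
  expect_true(is.na(f$geno[2, 2]))  # masked low-DP call
  expect_true(is.na(f$geno[3, 1]))  # masked low-GQ call
  smry <- attr(f, "filter_summary")
  expect_equal(unname(smry["sites_multiallelic"]), 1L)
  expect_equal(unname(smry["calls_masked"]), 2L)
  # idempotence
  f2 <- filter_snps(f, filter_config())
  expect_equal(f2$geno, f$geno)
  expect_equal(f2$sites, f$sites)
})

test_that("filtering is monotone in the depth threshold", {
  set.seed(4)
  geno <- matrix(rbinom(200, 2, 0.4), 20, 10,
                 dimnames = list(NULL, paste0("s", 1:10)))
  depth <- matrix(rpois(200, 8), 20, 10)
  x <- toy_snp_matrix(geno, depth = depth, gq = matrix(99, 20, 10))
  n_calls <- function(dp) sum(!is.na(
    filter_snps(x, filter_config(dp_min = dp, maf_min = 0,
                                 site_call_rate_min = 0))$geno))
  expect_gte(n_calls(2), n_calls(5))
  expect_gte(n_calls(5), n_calls(10))
  # a matrix already satisfying every threshold is unchanged
  clean <- toy_snp_matrix(cbind(s1 = c(0L, 1L), s2 = c(1L, 2L),
                                s3 = c(1L, 0L), s4 = c(2L, 1L)),
                          depth = matrix(20, 2, 4),
                          gq = matrix(99, 2, 4))
  expect_equal(filter_snps(clean)$geno, clean$geno)
})

test_that("identical matrices are 100% concordant at every depth", {
  set.seed(8)
  geno <- matrix(rbinom(120, 2, 0.3), 30, 4,
                 dimnames = list(NULL, paste0("s", 1:4)))
  # avoid strand-ambiguous ref/alt so no site is dropped
  x <- toy_snp_matrix(geno, ref = "A", alt = "G",
                      depth = matrix(50, 30, 4))
  chip <- toy_snp_matrix(geno, ref = "A", alt = "G")
  cc <- concordance(x, chip, 2:12)
  expect_true(all(cc$total_pct == 100))
  expect_true(all(cc$homo_pct == 100, na.rm = TRUE))
})

test_that("one planted het error among 20 calls gives 100/90/95", {
  # 5 sites x 4 samples: 10 chip-het and 10 chip-hom calls
  chip_geno <- rbind(c(1, 1, 0, 2), c(1, 1, 0, 2), c(1, 1, 2, 0),
                     c(1, 1, 0, 2), c(1, 1, 2, 0))
  colnames(chip_geno) <- paste0("s", 1:4)
  gbs_geno <- chip_geno
  gbs_geno[1, 1] <- 0  # one het called hom
  gbs <- toy_snp_matrix(gbs_geno, depth = matrix(9, 5, 4))
  chip <- toy_snp_matrix(chip_geno)
  cc <- concordance(gbs, chip, depth_thresholds = 5)
  expect_equal(cc$n_compared, 20)
  expect_equal(cc$homo_pct, 100)
  expect_equal(cc$het_pct, 90)
  expect_equal(cc$total_pct, 95)
})

test_that("allele orientation is harmonized and ambiguous sites dropped", {
  sites_g <- data.frame(chrom = "chr1", pos = c(100, 200, 300),
                        ref = c("A", "C", "A"), alt = c("G", "T", "T"))
  sites_c <- data.frame(chrom = "chr1", pos = c(100, 200, 300),
                        ref = c("G", "C", "A"), alt = c("A", "T", "T"))
  geno <- cbind(s1 = c(0L, 1L, 2L), s2 = c(2L, 0L, 1L))
  gbs <- snp_matrix(sites_g, geno, depth = matrix(9, 3, 2))
  chip <- snp_matrix(sites_c, cbind(s1 = c(2L, 1L, 2L), s2 = c(0L, 0L, 1L)))
  # site 100 has swapped ref/alt (flip), site 300 is A/T ambiguous (drop)
  cc <- concordance(gbs, chip, depth_thresholds = 2)
  expect_equal(attr(cc, "n_sites_ambiguous"), 1L)
  expect_equal(attr(cc, "n_sites_compared"), 2L)
  expect_equal(cc$total_pct, 100)
})

test_that("missing rates match hand counts and the accounting identity", {
  geno <- matrix(0L, 4, 4, dimnames = list(NULL, paste0("s", 1:4)))
  x <- toy_snp_matrix(geno, depth = matrix(10, 4, 4))
  m0 <- missing_rates(x, dp_min = 0)
  expect_true(all(m0$per_site$missing_before == 0))
  expect_true(all(m0$per_sample$missing_after == 0))
  # 3 calls drop below depth 5
  depth <- matrix(10, 4, 4); depth[1, 1] <- 4; depth[2, 3] <- 1; depth[4, 4] <- 0
  x2 <- toy_snp_matrix(geno, depth = depth)
  m <- missing_rates(x2, dp_min = 5)
  expect_equal(m$per_site$missing_after, c(0.25, 0.25, 0, 0.25))
  expect_equal(m$per_sample$missing_after, c(0.25, 0, 0.25, 0.25))
  # accounting identity: both means equal total missing / total calls
  expect_equal(mean(m$per_site$missing_after),
               mean(m$per_sample$missing_after))
  expect_equal(mean(m$per_site$missing_after), m$total_after)
})

test_that("r2 matches the hand-computed dosage correlation", {
  g1 <- c(0, 1, 1, 2); g2 <- c(0, 1, 2, 2)
  x <- toy_snp_matrix(rbind(g1, g2),
                      pos = c(100L, 600L))
  colnames(x$geno) <- paste0("s", 1:4)
  ld <- ld_decay(x, max_distance = 1000, bins = 2)
  expect_equal(sum(ld$n_pairs), 1)
  expect_equal(ld$mean_r2[!is.na(ld$mean_r2)], cor(g1, g2)^2)
  expect_equal(cor(g1, g2)^2, 8 / 11)  # frozen hand value
  # a duplicated site has r2 = 1
  x2 <- toy_snp_matrix(rbind(g1, g1), pos = c(100L, 200L))
  ld2 <- ld_decay(x2, max_distance = 1000, bins = 2)
  expect_equal(ld2$mean_r2[!is.na(ld2$mean_r2)], 1)
})

test_that("r2 is symmetric and invariant to allele-label swap", {
  set.seed(12)
  g1 <- rbinom(50, 2, 0.4); g2 <- rbinom(50, 2, 0.4)
  r2 <- function(a, b) {
    x <- toy_snp_matrix(rbind(a, b), pos = c(10L, 20L))
    ld <- ld_decay(x, max_distance = 100, bins = 1)
    ld$mean_r2[1]
  }
  expect_equal(r2(g1, g2), r2(g2, g1))
  expect_equal(r2(g1, g2), r2(2 - g1, g2))
})

test_that("independent common sites show near-zero r2 at large n", {
  set.seed(2024)
  n <- 10000
  g1 <- rbinom(n, 2, 0.5); g2 <- rbinom(n, 2, 0.5)
  x <- toy_snp_matrix(rbind(g1, g2), pos = c(100L, 300L))
  ld <- ld_decay(x, max_distance = 1000, bins = 1)
  expect_lt(ld$mean_r2[1], 0.01)
  # monomorphic pairs are excluded and counted
  g3 <- rep(1, n)
  x2 <- toy_snp_matrix(rbind(g1, g3, g2), pos = c(100L, 200L, 300L))
  ld2 <- ld_decay(x2, max_distance = 1000, bins = 1)
  expect_equal(attr(ld2, "n_monomorphic_pairs"), 2L)
  expect_equal(sum(ld2$n_pairs), 1L)
})
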