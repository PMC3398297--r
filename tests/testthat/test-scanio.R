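# Dosage/VCF readers, scan driver and results writer.

test_that("text dosage tables round-trip through write and read", {
  dm <- make_dosage_fixture(n_snp = 6, n_sample = 9, na_frac = 0.1)
  path <- withr::local_tempfile(fileext = ".txt")
  write_dosage(dm, path)
  back <- read_dosage_table(path)
  expect_equal(back$snp_ids, dm$snp_ids)
  expect_equal(back$samples, dm$samples)
  expect_equal(back$effect_allele, dm$effect_allele)
  expect_equal(back$dose, dm$dose, tolerance = 1e-6)
  # a second write of the re-read matrix is byte-identical
  path2 <- withr::local_tempfile(fileext = ".txt")
  write_dosage(back, path2)
  expect_identical(readLines(path), readLines(path2))
  # gzip round-trip detected by suffix
  pgz <- withr::local_tempfile(fileext = ".txt.gz")
  write_dosage(dm, pgz)
  expect_equal(read_dosage_table(pgz)$dose, dm$dose, tolerance = 1e-6)
})

test_that("a small fixture file parses to the exact values", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "SNP A1 A2 ind1 ind2 ind3",
    "rs1 A G 0.10 1.25 NA",
    "rs2 C T 2.00 0.00 1.00"
  ), path)
  dm <- read_dosage_table(path)
  expect_equal(dim(dm), c(2L, 3L))
  expect_equal(dm$dose["rs1", ], c(ind1 = 0.1, ind2 = 1.25, ind3 = NA))
  expect_equal(dm$dose["rs2", ], c(ind1 = 2, ind2 = 0, ind3 = 1))
})

test_that("malformed dosage files fail with located diagnostics", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("SNP A1 A2 s1 s2", "rs1 A G 0.5 2.4"), path)
  expect_error(read_dosage_table(path), "line 2.*rs1.*s2")
  writeLines(c("SNP A1 A2 s1 s2", "rs1 A G 0.5 1.0", "rs2 C T 0.5"), path)
  expect_error(read_dosage_table(path), "line 3")
  writeLines(c("SNP A1 A2 s1 s2", "rs1 A G 0.5 1.0", "rs1 C T 0.5 1.0"), path)
  expect_error(read_dosage_table(path), "duplicate SNP")
  writeLines(c("MARKER A1 A2 s1", "rs1 A G 0.5"), path)
  expect_error(read_dosage_table(path), "header")
  writeLines(c("SNP A1 A2 s1 s2", "rs1 A G 0.5 oops"), path)
  expect_error(read_dosage_table(path), "non-numeric")
})

write_vcf_fixture <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    "##FORMAT=<ID=GP,Number=G,Type=Float,Description=\"Genotype probabilities\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3\ts4",
    # DS only
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT:DS\t0/0:0.10\t0/1:1.00\t1/1:1.90\t0/0:0.00",
    # GP only; first sample is the worked example 0.18 + 2*0.01 = 0.20
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT:GP\t0/0:0.81,0.18,0.01\t0/1:0.1,0.8,0.1\t1/1:0,0.05,0.95\t0/0:1,0,0",
    # both present: DS wins
    "1\t300\trs3\tG\tA\t.\tPASS\t.\tGT:DS:GP\t0/1:1.37:0.1,0.8,0.1\t0/0:0.20:0.9,0.1,0\t0/0:0.00:1,0,0\t1/1:2.00:0,0,1",
    # multi-allelic: skipped
    "1\t400\trs4\tA\tG,T\t.\tPASS\t.\tGT:DS\t0/0:0.1\t0/0:0.1\t0/0:0.1\t0/0:0.1",
    # neither DS nor GP: skipped
    "1\t500\trs5\tT\tC\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t0/0"
  ), path)
}

test_that("VCF dosages honour DS precedence and the GP-to-dose formula", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(path)
  expect_warning(expect_warning(dm <- read_vcf_dosages(path),
                                "multi-allelic"),
                 "neither DS nor GP")
  expect_equal(dm$snp_ids, c("rs1", "rs2", "rs3"))
  expect_equal(dm$samples, c("s1", "s2", "s3", "s4"))
  expect_equal(unname(dm$dose["rs1", ]), c(0.10, 1.00, 1.90, 0.00))
  expect_equal(unname(dm$dose["rs2", ]), c(0.20, 1.00, 1.95, 0.00))
  expect_equal(unname(dm$dose["rs3", ]), c(1.37, 0.20, 0.00, 2.00))
  expect_equal(dm$effect_allele, c("G", "T", "A"))
  expect_equal(dm$other_allele, c("A", "C", "G"))
  expect_equal(dm$pos, c(100L, 200L, 300L))
})

make_scan_fixture <- function(n_snp = 20, n = 120, seed = 31) {
  set.seed(seed)
  dose <- matrix(runif(n_snp * n, 0, 2), n_snp, n)
  dm <- dosage_matrix(dose, sprintf("snp%02d", 1:n_snp),
                      rep("A", n_snp), rep("G", n_snp),
                      sprintf("I%03d", 1:n))
  y <- rnorm(n)
  names(y) <- dm$samples
  list(dm = dm, y = y)
}

test_that("the scan equals the single-SNP test applied row by row", {
  fx <- make_scan_fixture()
  recs <- run_scan(fx$dm, fx$y, test = "svlm")
  expect_equal(nrow(recs), 20)
  expect_equal(recs$snp_id, fx$dm$snp_ids)
  for (j in c(1, 7, 20)) {
    single <- svlm_test(fx$y, fx$dm$dose[j, ])
    expect_equal(recs$var_beta[j], single$stage2_beta, tolerance = 1e-12)
    expect_equal(recs$var_p[j], single$stage2_p, tolerance = 1e-12)
    expect_equal(recs$mean_p[j], single$stage1_p, tolerance = 1e-12)
    expect_equal(recs$n_used[j], single$n_used)
  }
  expect_equal(recs$eaf, unname(rowMeans(fx$dm$dose)) / 2, tolerance = 1e-12)
})

test_that("per-SNP failures become statuses instead of aborting the scan", {
  fx <- make_scan_fixture(n_snp = 4)
  fx$dm$dose[2, ] <- 1.0                       # constant dosage
  recs <- run_scan(fx$dm, fx$y, test = "svlm")
  expect_equal(recs$status[2], "monomorphic")
  expect_true(is.na(recs$var_p[2]))
  expect_true(is.na(recs$mean_beta[2]))
  expect_false(is.na(recs$eaf[2]))             # QC fields still populated
  expect_equal(recs$snp_id[2], fx$dm$snp_ids[2])
  expect_true(all(recs$status[-2] %in% c("ok", "low_group_count")))
  # svlm and levene agree on which integral-dosage SNPs are monomorphic
  fx$dm$dose[] <- round(fx$dm$dose)
  fx$dm$dose[2, ] <- 1.0
  r_s <- run_scan(fx$dm, fx$y, test = "svlm")
  r_l <- run_scan(fx$dm, fx$y, test = "levene")
  expect_equal(r_s$status == "monomorphic", r_l$status == "monomorphic")
})

test_that("scan output is invariant to SNP order and sample permutation", {
  fx <- make_scan_fixture(n_snp = 8)
  base <- run_scan(fx$dm, fx$y, test = "svlm")
  perm <- sample(8)
  dm_p <- dosage_matrix(fx$dm$dose[perm, ], fx$dm$snp_ids[perm],
                        fx$dm$effect_allele[perm], fx$dm$other_allele[perm],
                        fx$dm$samples)
  r_p <- run_scan(dm_p, fx$y, test = "svlm")
  expect_equal(r_p[match(base$snp_id, r_p$snp_id), ], base,
               ignore_attr = TRUE)
  sperm <- sample(length(fx$y))
  dm_s <- dosage_matrix(fx$dm$dose[, sperm], fx$dm$snp_ids,
                        fx$dm$effect_allele, fx$dm$other_allele,
                        fx$dm$samples[sperm])
  r_s <- run_scan(dm_s, fx$y, test = "svlm")
  expect_equal(r_s, base, ignore_attr = TRUE)
})

test_that("covariates and the levene route work through the scan", {
  fx <- make_scan_fixture(n_snp = 5, n = 200)
  X <- cbind(age = rnorm(200))
  rownames(X) <- names(fx$y)
  y_adj <- fx$y + 0.5 * X[, "age"]
  recs <- run_scan(fx$dm, y_adj, X = X, test = "svlm")
  single <- svlm_test(y_adj, fx$dm$dose[3, ], X = X)
  expect_equal(recs$var_p[3], single$stage2_p, tolerance = 1e-12)

  recs_l <- run_scan(fx$dm, fx$y, test = "levene",
                     options = list(max_distance = 0.5))
  g <- hard_call(fx$dm$dose[2, ], 0.5)
  lev <- brown_forsythe_levene(fx$y, g)
  expect_equal(recs_l$var_p[2], lev$p_value, tolerance = 1e-12)
  expect_true(all(is.na(recs_l$var_beta)))
})

test_that("null scan rejects at the nominal rate", {
  set.seed(77)
  n <- 500; n_snp <- 1500
  dose <- matrix(as.numeric(rbinom(n_snp * n, 2, 0.5)), n_snp, n)
  dm <- dosage_matrix(dose, sprintf("s%04d", 1:n_snp),
                      rep("A", n_snp), rep("G", n_snp), sprintf("I%03d", 1:n))
  y <- rnorm(n); names(y) <- dm$samples
  recs <- run_scan(dm, y, test = "svlm")
  frac <- mean(recs$var_p <= 0.05, na.rm = TRUE)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n_snp))
})

test_that("scan results round-trip through the TSV writer", {
  fx <- make_scan_fixture(n_snp = 3)
  fx$dm$dose[2, ] <- 0.0                       # monomorphic row
  recs <- run_scan(fx$dm, fx$y, test = "svlm")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(recs, path)
  lines <- readLines(path)
  expect_length(lines, 4L)                     # header + 3 records
  back <- read_results(path)
  expect_equal(back$snp_id, recs$snp_id)
  expect_equal(back$status, recs$status)
  expect_true(is.na(back$var_p[2]) && !is.na(back$eaf[2]))
  reformat <- function(x, fmt) {
    out <- rep(NA_real_, length(x))
    ok <- !is.na(x)
    out[ok] <- as.numeric(sprintf(fmt, x[ok]))
    out
  }
  for (col in c("eaf", "mean_beta", "mean_se", "var_beta", "var_se"))
    expect_equal(back[[col]], reformat(recs[[col]], "%.6g"))
  for (col in c("mean_p", "var_p"))
    expect_equal(back[[col]], reformat(recs[[col]], "%.6e"))
  # re-write of the read-back file reproduces it byte-identically
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_results(back, path2)
  expect_identical(readLines(path2), lines)
})

test_that("sample mismatches are rejected up front", {
  fx <- make_scan_fixture(n_snp = 2)
  y_bad <- fx$y
  names(y_bad) <- paste0("X", names(y_bad))
  expect_error(run_scan(fx$dm, y_bad), "no samples shared")
  expect_error(run_scan(fx$dm, fx$y[1:5]), "at least 10")
})
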