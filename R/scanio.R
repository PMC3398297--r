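# Genome-wide application of the variance tests over a dosage matrix, plus
# readers/writers for the text dosage dialect, VCF dosage fields and scan
# results.

#' Construct a dosage matrix
#'
#' Container for per-SNP expected allele counts across samples: a numeric
#' matrix (SNPs in rows, samples in columns) with values in `[0, 2]` or `NA`,
#' plus effect/other allele labels and optional genomic coordinates.
#'
#' @param dose Numeric matrix, SNPs x samples, entries in `[0, 2]` or `NA`.
#' @param snp_ids Unique SNP identifiers, one per row.
#' @param effect_allele,other_allele Allele labels per SNP; dosages count the
#'   effect allele.
#' @param samples Unique sample identifiers, one per column.
#' @param chrom,pos Optional coordinates per SNP (passed through untouched;
#'   1-based when they come from VCF).
#' @return An object of class `"dosage_matrix"`.
#' @export
dosage_matrix <- function(dose, snp_ids, effect_allele, other_allele, samples,
                          chrom = NULL, pos = NULL) {
  dose <- as.matrix(dose)
  storage.mode(dose) <- "double"
  if (nrow(dose) != length(snp_ids) || ncol(dose) != length(samples))
    vq_config("dose matrix dimensions must match snp_ids x samples")
  if (anyDuplicated(snp_ids)) vq_config("duplicate SNP identifiers")
  if (anyDuplicated(samples)) vq_config("duplicate sample identifiers")
  if (length(effect_allele) != length(snp_ids) ||
      length(other_allele) != length(snp_ids))
    vq_config("allele vectors must have one entry per SNP")
  if (any(dose < 0 | dose > 2, na.rm = TRUE))
    vq_config("dosages must lie in [0, 2]")
  dimnames(dose) <- list(as.character(snp_ids), as.character(samples))
  structure(
    list(dose = dose, snp_ids = as.character(snp_ids),
         effect_allele = as.character(effect_allele),
         other_allele = as.character(other_allele),
         samples = as.character(samples), chrom = chrom, pos = pos),
    class = "dosage_matrix"
  )
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("dosage_matrix: %d SNPs x %d samples\n",
              length(x$snp_ids), length(x$samples)))
  invisible(x)
}

#' @export
dim.dosage_matrix <- function(x) dim(x$dose)

.read_lines_maybe_gz <- function(path) {
  if (!file.exists(path)) vq_config(sprintf("file not found: %s", path))
  con <- if (.is_gz(path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

#' Read a text dosage table
#'
#' Reads the plain dosage dialect: a whitespace-delimited table whose header
#' line is `SNP A1 A2 <sample1> <sample2> ...`, followed by one SNP per row
#' with its identifier, effect allele (`A1`), other allele (`A2`) and one
#' dosage in `[0, 2]` (or `NA`) per sample.  This matches the de-facto
#' MACH/minimac-style layout.  Files ending in `.gz` are decompressed
#' transparently.
#'
#' Malformed input — a bad header, ragged rows, duplicate SNP or sample
#' identifiers, non-numeric or out-of-range dosages — raises an error naming
#' the offending line (and SNP/sample for value errors).
#'
#' @param path Path to the dosage file.
#' @return A [dosage_matrix()].
#' @export
read_dosage_table <- function(path) {
  lines <- .read_lines_maybe_gz(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    vq_config(sprintf("%s: need a header line and at least one SNP row", path))
  toks <- strsplit(trimws(lines), "[ \t]+")
  header <- toks[[1L]]
  if (length(header) < 4L || !identical(header[1:3], c("SNP", "A1", "A2")))
    vq_config(sprintf("%s: malformed header; expected 'SNP A1 A2 <samples...>'", path))
  samples <- header[-(1:3)]
  if (anyDuplicated(samples))
    vq_config(sprintf("%s: duplicate sample identifiers in header", path))
  body <- toks[-1L]
  lens <- lengths(body)
  if (any(lens != length(header))) {
    bad <- which(lens != length(header))[1L]
    vq_config(sprintf("%s: line %d has %d fields, expected %d",
                      path, bad + 1L, lens[bad], length(header)))
  }
  snp_ids <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(snp_ids))
    vq_config(sprintf("%s: duplicate SNP identifier '%s'",
                      path, snp_ids[duplicated(snp_ids)][1L]))
  a1 <- vapply(body, `[[`, "", 2L)
  a2 <- vapply(body, `[[`, "", 3L)
  raw <- matrix(unlist(lapply(body, `[`, -(1:3))), nrow = length(body),
                byrow = TRUE)
  dose <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad_num <- which(is.na(dose) & raw != "NA", arr.ind = TRUE)
  if (nrow(bad_num) > 0L) {
    i <- bad_num[1L, 1L]; j <- bad_num[1L, 2L]
    vq_config(sprintf("%s: line %d: non-numeric dosage '%s' (SNP %s, sample %s)",
                      path, i + 1L, raw[i, j], snp_ids[i], samples[j]))
  }
  out_rng <- which(!is.na(dose) & (dose < 0 | dose > 2), arr.ind = TRUE)
  if (nrow(out_rng) > 0L) {
    i <- out_rng[1L, 1L]; j <- out_rng[1L, 2L]
    vq_config(sprintf("%s: line %d: dosage %s outside [0, 2] (SNP %s, sample %s)",
                      path, i + 1L, format(dose[i, j]), snp_ids[i], samples[j]))
  }
  dosage_matrix(dose, snp_ids, a1, a2, samples)
}

#' Write a dosage matrix in the text dialect
#'
#' Inverse of [read_dosage_table()]: dosages are printed with six decimal
#' places, missing values as `NA`; written atomically, gzip-compressed when
#' the path ends in `.gz`.
#'
#' @param dm A [dosage_matrix()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_dosage <- function(dm, path) {
  if (!inherits(dm, "dosage_matrix")) vq_config("'dm' must be a dosage_matrix")
  .atomic_write(path, function(tmp) {
    con <- if (.is_gz(path)) gzfile(tmp, "wt") else file(tmp, "wt")
    on.exit(close(con))
    writeLines(paste(c("SNP", "A1", "A2", dm$samples), collapse = " "), con)
    vals <- ifelse(is.na(dm$dose), "NA", sprintf("%.6f", dm$dose))
    dim(vals) <- dim(dm$dose)
    rows <- paste(dm$snp_ids, dm$effect_allele, dm$other_allele,
                  apply(vals, 1L, paste, collapse = " "))
    writeLines(rows, con)
  })
}

#' Read allele dosages from a VCF
#'
#' Extracts one dosage per sample and biallelic record from a VCF 4.x file:
#' the `DS` FORMAT field (expected ALT allele count) when the record carries
#' one, otherwise the dosage is assembled from genotype probabilities as
#' `P(het) + 2 P(hom-alt)` using the `GP` FORMAT field.  The effect allele is
#' ALT.  Multi-allelic records, and records with neither `DS` nor `GP`, are
#' skipped with a warning.  Coordinates are carried through unchanged
#' (1-based, as in the VCF).
#'
#' @param path Path to a VCF file (plain or bgzip/gzip).
#' @return A [dosage_matrix()] with `chrom`/`pos` populated.
#' @export
read_vcf_dosages <- function(path) {
  if (!file.exists(path)) vq_config(sprintf("file not found: %s", path))
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) vq_config(sprintf("unreadable VCF %s: %s",
                                                        path, conditionMessage(e))))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  if (n_rec == 0L) vq_config(sprintf("%s: no variant records", path))
  samples <- colnames(vcf@gt)[-1L]
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    warning(sprintf("skipping %d multi-allelic record(s)", sum(multi)))
  ds <- tryCatch(vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  gp <- tryCatch(vcfR::extract.gt(vcf, element = "GP"),
                 error = function(e) NULL)
  keep <- logical(n_rec)
  dose <- matrix(NA_real_, n_rec, length(samples))
  for (i in which(!multi)) {
    if (!is.null(ds) && any(!is.na(ds[i, ]))) {
      dose[i, ] <- ds[i, ]
      keep[i] <- TRUE
    } else if (!is.null(gp) && any(!is.na(gp[i, ]))) {
      probs <- strsplit(gp[i, ], ",", fixed = TRUE)
      dose[i, ] <- vapply(probs, function(p) {
        if (length(p) != 3L) return(NA_real_)
        p <- as.numeric(p)
        p[2L] + 2 * p[3L]
      }, numeric(1))
      keep[i] <- TRUE
    } else {
      warning(sprintf("record %s:%s has neither DS nor GP; skipped",
                      fix[i, "CHROM"], fix[i, "POS"]))
    }
  }
  if (!any(keep)) vq_config(sprintf("%s: no usable dosage records", path))
  ids <- fix[, "ID"]
  miss_id <- is.na(ids) | ids == "."
  ids[miss_id] <- paste0(fix[miss_id, "CHROM"], ":", fix[miss_id, "POS"])
  dose <- pmin(pmax(dose, 0), 2)   # clamp FP noise in GP sums
  dosage_matrix(dose[keep, , drop = FALSE], ids[keep],
                effect_allele = fix[keep, "ALT"], other_allele = fix[keep, "REF"],
                samples = samples,
                chrom = fix[keep, "CHROM"], pos = as.integer(fix[keep, "POS"]))
}

# One NA-filled scan record; filled in as far as the per-SNP test got.
.blank_record <- function(snp_id, effect_allele, test) {
  data.frame(snp_id = snp_id, effect_allele = effect_allele,
             n_used = NA_integer_, eaf = NA_real_,
             mean_beta = NA_real_, mean_se = NA_real_, mean_p = NA_real_,
             var_beta = NA_real_, var_se = NA_real_, var_p = NA_real_,
             test_used = test, status = "ok", stringsAsFactors = FALSE)
}

#' Genome-wide variance-heterogeneity scan
#'
#' Applies the chosen test to every SNP of a dosage matrix against one
#' phenotype, with per-SNP listwise deletion of missing data.  Output rows
#' report both analysis stages: the mean model (`mean_beta`, `mean_se`,
#' `mean_p` — an ordinary GWAS association) and the variance model
#' (`var_beta`, `var_se`, `var_p` — the heterogeneity test; for the
#' Brown-Forsythe test only `var_p` applies).  Per-SNP failures never abort
#' the scan: a monomorphic or degenerate locus yields a row with `status`
#' `"monomorphic"` or `"undefined"` and `NA` statistics.  Loci whose smallest
#' hard-called genotype group is below `options$low_group_count` (default 80)
#' are flagged `status = "low_group_count"` — their results are reported but
#' the squared-residual test is known to turn conservative at such counts.
#'
#' @param dm A [dosage_matrix()].
#' @param y Named numeric phenotype vector; names are sample identifiers and
#'   are matched (intersected) against `dm$samples`.
#' @param X Optional covariate matrix/data frame with sample identifiers as
#'   row names.
#' @param test `"svlm"` (dosage-based, default) or `"levene"`
#'   (Brown-Forsythe on hard calls; dosages are converted via [hard_call()]
#'   with `options$max_distance`).
#' @param options List: `max_distance` (default 0.5), `low_group_count`
#'   (default 80), `robust` (default `FALSE`, SVLM only).
#' @return A data frame of class `"vq_scan"`, one row per SNP in input
#'   order.
#' @export
run_scan <- function(dm, y, X = NULL, test = c("svlm", "levene"),
                     options = list()) {
  test <- match.arg(test)
  if (!inherits(dm, "dosage_matrix")) vq_config("'dm' must be a dosage_matrix")
  if (is.null(names(y))) vq_config("'y' must be a named vector (sample identifiers)")
  opts <- utils::modifyList(
    list(max_distance = 0.5, low_group_count = 80L, robust = FALSE), options)
  ids <- intersect(dm$samples, names(y))
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (is.null(rownames(X))) vq_config("'X' must have sample identifiers as row names")
    ids <- intersect(ids, rownames(X))
  }
  if (length(ids) == 0L) vq_config("no samples shared between dosages and phenotype")
  if (length(ids) < 10L)
    vq_config(sprintf("only %d shared sample(s); at least 10 required", length(ids)))
  yv <- as.numeric(y[ids])
  Xv <- if (is.null(X)) NULL else X[ids, , drop = FALSE]
  records <- vector("list", length(dm$snp_ids))
  for (i in seq_along(dm$snp_ids)) {
    rec <- .blank_record(dm$snp_ids[i], dm$effect_allele[i], test)
    d <- dm$dose[i, ids]
    ok <- !is.na(yv) & !is.na(d)
    if (!is.null(Xv)) ok <- ok & complete.cases(Xv)
    gcall <- NULL
    if (test == "levene") {
      gcall <- hard_call(d, opts$max_distance)
      ok <- ok & !is.na(gcall)
    }
    rec$n_used <- sum(ok)
    if (rec$n_used > 0L) rec$eaf <- mean(d[ok]) / 2
    res <- tryCatch(
      {
        if (test == "svlm") {
          fit <- svlm_test(yv[ok], d[ok], X = if (is.null(Xv)) NULL else Xv[ok, , drop = FALSE],
                           robust = opts$robust)
          rec$n_used <- fit$n_used
          rec$mean_beta <- fit$stage1_beta; rec$mean_se <- fit$stage1_se
          rec$mean_p <- fit$stage1_p
          rec$var_beta <- fit$stage2_beta; rec$var_se <- fit$stage2_se
          rec$var_p <- fit$stage2_p
        } else {
          lev <- brown_forsythe_levene(yv[ok], gcall[ok])
          rec$var_p <- lev$p_value
          Z1 <- cbind(1, gcall[ok], if (is.null(Xv)) NULL else Xv[ok, , drop = FALSE])
          mfit <- .ols_fit(Z1, yv[ok], coef_idx = 2L)
          rec$mean_beta <- mfit$beta; rec$mean_se <- mfit$se; rec$mean_p <- mfit$p
        }
        "ok"
      },
      vq_monomorphic_error = function(e) "monomorphic",
      vq_undefined_error = function(e) "undefined",
      vq_rank_error = function(e) "undefined"
    )
    rec$status <- res
    if (res == "ok") {
      grp <- if (is.null(gcall)) hard_call(d[ok], 0.5) else gcall[ok]
      counts <- table(grp)
      if (min(counts) < opts$low_group_count) rec$status <- "low_group_count"
    }
    records[[i]] <- rec
  }
  out <- do.call(rbind, records)
  class(out) <- c("vq_scan", "data.frame")
  out
}

.scan_cols <- c("snp_id", "effect_allele", "n_used", "eaf",
                "mean_beta", "mean_se", "mean_p",
                "var_beta", "var_se", "var_p", "test_used", "status")

#' Write scan records as TSV
#'
#' One header line and one row per SNP in input order; missing values as
#' `NA`; p-values in scientific notation with six significant digits, other
#' numeric fields with six significant digits.  Written atomically; a `.gz`
#' suffix compresses.
#'
#' @param records A `"vq_scan"` data frame from [run_scan()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_results <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    vq_config("'records' must be a non-empty data frame of scan records")
  if (!all(.scan_cols %in% names(records)))
    vq_config("'records' is missing scan columns")
  fmt_p <- function(x) ifelse(is.na(x), "NA", sprintf("%.6e", x))
  fmt_g <- function(x) ifelse(is.na(x), "NA", sprintf("%.6g", x))
  out <- data.frame(
    snp_id = records$snp_id, effect_allele = records$effect_allele,
    n_used = ifelse(is.na(records$n_used), "NA", as.character(records$n_used)),
    eaf = fmt_g(records$eaf),
    mean_beta = fmt_g(records$mean_beta), mean_se = fmt_g(records$mean_se),
    mean_p = fmt_p(records$mean_p),
    var_beta = fmt_g(records$var_beta), var_se = fmt_g(records$var_se),
    var_p = fmt_p(records$var_p),
    test_used = records$test_used, status = records$status,
    stringsAsFactors = FALSE
  )
  .atomic_write(path, function(tmp) {
    con <- if (.is_gz(path)) gzfile(tmp, "wt") else file(tmp, "wt")
    on.exit(close(con))
    writeLines(paste(.scan_cols, collapse = "\t"), con)
    writeLines(do.call(paste, c(out, sep = "\t")), con)
  })
}

#' Read scan records written by [write_results()]
#'
#' @param path Path to a results TSV (optionally gzipped).
#' @return A `"vq_scan"` data frame.
#' @export
read_results <- function(path) {
  lines <- .read_lines_maybe_gz(path)
  dt <- utils::read.delim(text = lines, sep = "\t", header = TRUE,
                          na.strings = "NA", stringsAsFactors = FALSE)
  if (!all(.scan_cols %in% names(dt)))
    vq_config(sprintf("%s: not a scan results file", path))
  class(dt) <- c("vq_scan", "data.frame")
  dt
}
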