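#' @importFrom stats pf pt median rnorm rbinom rchisq dbinom complete.cases
#' @importFrom utils write.table read.delim
NULL

# Classed errors so callers (and the genome-wide scan) can distinguish
# "nothing to test here" from genuine failures.
vq_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "vq_error", "error"), call = call))
}

vq_monomorphic <- function(msg) vq_stop(msg, "vq_monomorphic_error", sys.call(-1))
vq_undefined   <- function(msg) vq_stop(msg, "vq_undefined_error", sys.call(-1))
vq_rank        <- function(msg) vq_stop(msg, "vq_rank_error", sys.call(-1))
vq_config      <- function(msg) vq_stop(msg, "vq_config_error", sys.call(-1))

.assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    vq_config(sprintf("'%s' must be a single number in [%s, %s]", name, lo, hi))
  invisible(x)
}

# Atomic write: assemble in a temp file next to the target, then rename, so a
# failure mid-write never leaves a truncated output file behind.
.atomic_write <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) vq_config(sprintf("output directory does not exist: %s", dir))
  tmp <- tempfile(tmpdir = dir, fileext = paste0(".", basename(path), ".tmp"))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    vq_config(sprintf("could not write output file: %s", path))
  invisible(path)
}

.is_gz <- function(path) grepl("\\.gz$", path, ignore.case = TRUE)
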