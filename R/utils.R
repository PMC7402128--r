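#' @keywords internal
"_PACKAGE"

#' @importFrom stats anova aov as.formula chisq.test coef cor cor.test lm
#'   lm.fit pchisq pf pt quantile rbinom rlnorm rnorm runif sd setNames var
#' @importFrom utils combn read.delim write.table
NULL

# FNV-1a 32-bit hash of a character scalar; used only to stamp output files
# with a configuration fingerprint so reruns are distinguishable.  Pure
# double arithmetic: R has no unsigned 32-bit integers, so the xor touches
# only the low byte (valid because the byte is < 256) and the modular
# multiply by the FNV prime 16777619 is split to stay below 2^53.
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    hi <- h %/% 65536; lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

config_hash <- function(config) {
  flat <- paste(names(unlist(config)), unlist(config), sep = "=", collapse = ";")
  fnv1a32(flat)
}

# Write a table atomically: write to a temp file in the same directory, then
# rename, so an aborted run never leaves a partially written final table.
write_tsv_atomic <- function(df, path, header_lines = character()) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  con <- file(tmp, open = "wt")
  on.exit(try(close(con), silent = TRUE), add = TRUE)
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

read_tsv_plain <- function(path) {
  read.delim(path, sep = "\t", comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(sprintf(...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
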